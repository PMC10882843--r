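test_that("the default design matches the study layout", {
  des <- generate_design(cohort_config(seed = 3))
  expect_equal(nrow(des), 162)
  expect_equal(sum(des$microbiome_subset), 72)
  expect_equal(sort(unique(des$age_weeks)), c(3, 6, 10, 12, 22, 32, 49, 50, 53))
  expect_equal(length(unique(des$pig_id)), 18)
  # microbiome subset is balanced across cohorts (4 + 4 pigs)
  sub <- unique(des[des$microbiome_subset, c("pig_id", "cohort")])
  expect_equal(unname(table(sub$cohort)), c(4L, 4L), ignore_attr = TRUE)

  one <- generate_design(cohort_config(n_pigs = 1, cohort_sizes = c(1, 0),
                                       microbiome_subset_size = 1,
                                       age_grid = 3))
  expect_equal(nrow(one), 1)
  expect_error(cohort_config(microbiome_subset_size = 30),
               "cannot exceed n_pigs")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_cohort(seed = 9)
  des1 <- generate_design(cfg)
  des2 <- generate_design(cfg)
  expect_identical(des1, des2)
  b1 <- generate_bacterial_counts(des1, cfg)
  b2 <- generate_bacterial_counts(des1, cfg)
  expect_identical(b1, b2)
  expect_identical(generate_amr_observations(des1, cfg),
                   generate_amr_observations(des1, cfg))
  expect_identical(generate_qpcr_observations(des1, cfg),
                   generate_qpcr_observations(des1, cfg))
})

test_that("bacterial counts conserve library sizes and follow the truth labels", {
  cfg <- small_cohort(seed = 4)
  des <- generate_design(cfg)
  gen <- generate_bacterial_counts(des, cfg)
  m <- as.matrix(gen$counts[, -1])
  expect_true(all(m >= 0 & m == round(m)))
  expect_equal(unname(rowSums(m)),
               gen$truth$library_size[match(gen$counts$sample_id,
                                            gen$truth$sample_id)])
  expect_equal(nrow(gen$truth), sum(des$microbiome_subset))

  # deterministic library-size model: every sample sums to the fixed size
  cfg0 <- small_cohort(seed = 4,
                       library_size_meanlog = c(default = log(5000)),
                       library_size_sdlog = c(default = 0))
  gen0 <- generate_bacterial_counts(generate_design(cfg0), cfg0)
  expect_true(all(rowSums(as.matrix(gen0$counts[, -1])) == 5000))
})

test_that("alpha diversity increases with age in the default generator", {
  sh <- numeric(0)
  ages <- numeric(0)
  for (s in 1:2) {
    cfg <- cohort_config(seed = s)
    des <- generate_design(cfg)
    gen <- generate_bacterial_counts(des, cfg)
    a <- dplyr::left_join(alpha_diversity(gen$counts), des, by = "sample_id")
    sh <- c(sh, a$shannon)
    ages <- c(ages, a$age_weeks)
  }
  expect_lt(mean(sh[ages == 3]), mean(sh[ages == 32]))
})

test_that("fungal counts have 291 taxa, huge overdispersion limit, parturition bump", {
  cfg <- cohort_config(seed = 5)
  des <- generate_design(cfg)
  fun <- generate_fungal_counts(des, cfg)
  expect_equal(ncol(fun) - 1, 291)

  # concentration -> infinity: per-sample proportions approach the profile
  cfg_inf <- cohort_config(seed = 5, fungal_concentration = 1e6,
                           candida_bump = 1)
  fun_inf <- generate_fungal_counts(des, cfg_inf)
  p <- as.matrix(fun_inf[, -1]) / rowSums(as.matrix(fun_inf[, -1]))
  expect_lt(max(apply(p, 2, sd)), 0.01)

  # Candida-like mean relative abundance: parturition (50) above week 22
  ra50 <- ra22 <- numeric(0)
  for (s in 1:3) {
    cfg_s <- cohort_config(seed = s)
    des_s <- generate_design(cfg_s)
    f <- generate_fungal_counts(des_s, cfg_s)
    m <- as.matrix(f[, -1])
    ra <- rowSums(m[, grep("^Candida", colnames(m))]) / rowSums(m)
    age <- des_s$age_weeks[match(f$sample_id, des_s$sample_id)]
    ra50 <- c(ra50, ra[age == 50])
    ra22 <- c(ra22, ra[age == 22])
  }
  expect_gt(mean(ra50), mean(ra22))
})

test_that("AMR observations have the enumerated row count and noiseless limit", {
  cfg <- cohort_config(seed = 6)
  des <- generate_design(cfg)
  gen <- generate_amr_observations(des, cfg)
  n_series <- nrow(dplyr::distinct(cfg$amr_curves, bacterium, drug))
  expect_equal(nrow(gen$amr), 162 * n_series)

  # phi irrelevant when both noise scales are zero: values equal the curves
  cfg0 <- cohort_config(seed = 6, ar_sd = 0, noise_sd = 0)
  gen0 <- generate_amr_observations(des, cfg0)
  joined <- dplyr::left_join(gen0$amr, des, by = "sample_id") |>
    dplyr::left_join(cfg0$amr_curves,
                     by = c("bacterium", "drug", "drug_class", "age_weeks"))
  expect_equal(joined$log10_cfu_per_g, joined$mean_log10, tolerance = 1e-12)
})

test_that("within-pig residual correlation matches the configured phi", {
  cfg <- cohort_config(n_pigs = 200, cohort_sizes = c(100, 100),
                       microbiome_subset_size = 8, noise_sd = 0, seed = 8)
  des <- generate_design(cfg)
  gen <- generate_amr_observations(des, cfg)
  one <- dplyr::filter(gen$amr, bacterium == "coliform",
                       drug == "tetracycline") |>
    dplyr::left_join(des, by = "sample_id") |>
    dplyr::left_join(dplyr::filter(cfg$amr_curves, drug == "tetracycline",
                                   bacterium == "coliform"),
                     by = c("bacterium", "drug", "drug_class", "age_weeks"))
  resid <- one$log10_cfu_per_g - one$mean_log10
  # ages 49 and 50 are one week apart: lag-1 correlation ~ phi
  r49 <- resid[one$age_weeks == 49][order(one$pig_id[one$age_weeks == 49])]
  r50 <- resid[one$age_weeks == 50][order(one$pig_id[one$age_weeks == 50])]
  expect_equal(cor(r49, r50), cfg$ar1_phi, tolerance = 0.1)
})

test_that("noiseless qPCR reproduces the week-3 baselines and the standardization identity", {
  cfg <- cohort_config(seed = 2, qpcr_pig_sd = 0, qpcr_noise_sd = 0)
  des <- generate_design(cfg)
  q <- generate_qpcr_observations(des, cfg)
  w3 <- dplyr::left_join(q, des, by = "sample_id") |>
    dplyr::filter(age_weeks == 3)
  expect_equal(mean(log10(w3$copies_per_g[w3$gene == "tetA"])), 7.10,
               tolerance = 1e-10)
  expect_equal(mean(log10(w3$copies_per_g[w3$gene == "blaCTXM"])), 5.35,
               tolerance = 1e-10)

  std <- standardize_gene_copies(q)
  wide <- tidyr::pivot_wider(q, names_from = "gene",
                             values_from = "copies_per_g")
  merged <- dplyr::left_join(dplyr::filter(std, gene == "tetA"), wide,
                             by = "sample_id")
  expect_equal(merged$log10_standardized,
               log10(merged$tetA) - log10(merged$`16S`), tolerance = 1e-12)
})
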