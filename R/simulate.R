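# Synthetic cohort generator: emits count tables, metadata, plate counts and
# qPCR tables with the statistical structure the downstream models assume,
# plus ground-truth labels for parameter-recovery testing.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Enterotype concentration profiles over the bacterial taxa. Each community
# type is anchored by a few named dominant genera (a Rikenellaceae RC9 /
# Prevotella / UCG-002 type for the earliest ages, a Megasphaera /
# Streptococcus type, a Streptococcus / Clostridium / Treponema type, and a
# late Treponema / Clostridium type); the remaining mass decays geometrically
# over filler taxa so profiles are realistic and mutually well separated.
enterotype_profiles <- function(n_taxa = 100) {
  stopifnot(n_taxa >= 20)
  anchors <- c("Rikenellaceae_RC9", "Prevotella", "UCG_002", "Megasphaera",
               "Streptococcus", "Prevotella_9", "Clostridium_ss1", "Treponema")
  fillers <- sprintf("genus_%03d", seq_len(n_taxa - length(anchors)))
  taxa <- c(anchors, fillers)
  anchor_weights <- list(
    E1 = c(Rikenellaceae_RC9 = 0.28, Prevotella = 0.18, UCG_002 = 0.12),
    E2 = c(Megasphaera = 0.25, Streptococcus = 0.18, Prevotella_9 = 0.12),
    E3 = c(Streptococcus = 0.20, Clostridium_ss1 = 0.17, Treponema = 0.15),
    E4 = c(Treponema = 0.30, Clostridium_ss1 = 0.20)
  )
  decay <- 0.97
  base_fill <- decay^seq_along(fillers)
  profiles <- lapply(seq_along(anchor_weights), function(k) {
    w <- anchor_weights[[k]]
    p <- setNames(numeric(n_taxa), taxa)
    p[names(w)] <- w
    # rotate the filler emphasis per component so fillers also differ
    fill <- base_fill[((seq_along(fillers) + (k - 1) * 7) %% length(fillers)) + 1]
    p[fillers] <- (1 - sum(w)) * fill / sum(fill)
    p
  })
  names(profiles) <- names(anchor_weights)
  profiles
}

#' Configuration of the synthetic cohort generator
#'
#' Encodes the study design being emulated: 18 female pigs in two cohorts
#' (6 and 12), each sampled at nine age points from 3 to 53 weeks; an 8-pig
#' (4 + 4 across cohorts) microbiome subset of 72 sequenced samples; a
#' four-enterotype trajectory E1 (weeks 3-6) -> E2 (10-12) -> E3 (22) ->
#' E4 (32 onward), with 2 of the 8 profiled pigs reverting to E3 after estrus
#' and 6 retaining E4; age-increasing alpha diversity via a monotone
#' Dirichlet concentration scale; low-diversity, high-variance fungal counts
#' in two phyla with a parturition bump in Candida-like taxa; drug-specific
#' nonlinear mean log10 CFU/g trajectories with continuous-time AR(1)
#' within-pig errors; and qPCR gene-copy curves anchored at week-3 means of
#' 7.10 log10 copies/g for tet(A) and 5.35 for bla-CTX-M.
#'
#' @param n_pigs,cohort_sizes number of pigs and their split into two cohorts.
#' @param age_grid sampling ages in weeks.
#' @param microbiome_subset_size number of pigs profiled by sequencing
#'   (balanced across cohorts).
#' @param n_bacterial_taxa,n_fungal_taxa taxa counts for the two count tables.
#' @param trajectory_map named numeric vector mapping age (as character) to
#'   the enterotype component sampled at that age for non-reverting pigs.
#' @param n_reverting number of microbiome-subset pigs that transition back
#'   to component 3 at weeks 49-53.
#' @param concentration_by_age named vector: total Dirichlet concentration per
#'   age; larger values give more even communities, inducing the age increase
#'   in alpha diversity without changing profile support.
#' @param library_size_meanlog,library_size_sdlog named vectors of per-age
#'   log-normal library-size parameters (week 3 is set lower, mirroring the
#'   observed read-depth deficit at the earliest age).
#' @param fungal_concentration total concentration of the single-component
#'   fungal Dirichlet-multinomial (small = strong inter-pig overdispersion).
#' @param candida_bump multiplicative boost of Candida-like taxon
#'   concentrations at the parturition age (week 50).
#' @param ar1_phi continuous-time AR(1) correlation per unit week of the
#'   within-pig AMR residual process; `ar_sd` its stationary standard
#'   deviation; `noise_sd` the white-noise standard deviation.
#' @param detection_limit_log10 plate-count detection limit; draws below it
#'   are recorded as no growth (missing log10 CFU).
#' @param qpcr_pig_sd,qpcr_noise_sd pig-intercept and residual standard
#'   deviations of the log10 gene-copy model.
#' @param seed integer seed from which all generator randomness derives.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_pigs = 18,
                          cohort_sizes = c(6, 12),
                          age_grid = study_age_grid(),
                          microbiome_subset_size = 8,
                          n_bacterial_taxa = 100,
                          n_fungal_taxa = 291,
                          trajectory_map = c("3" = 1, "6" = 1, "10" = 2, "12" = 2,
                                             "22" = 3, "32" = 4, "49" = 4,
                                             "50" = 4, "53" = 4),
                          n_reverting = 2,
                          concentration_by_age = c("3" = 30, "6" = 40, "10" = 50,
                                                   "12" = 55, "22" = 70, "32" = 85,
                                                   "49" = 95, "50" = 95, "53" = 95),
                          library_size_meanlog = c("3" = log(5e4),
                                                   default = log(1.5e5)),
                          library_size_sdlog = c("3" = 0.6, default = 0.25),
                          fungal_concentration = 2.5,
                          candida_bump = 4,
                          ar1_phi = 0.85,
                          ar_sd = 0.5,
                          noise_sd = 0.2,
                          detection_limit_log10 = 2,
                          qpcr_pig_sd = 0.25,
                          qpcr_noise_sd = 0.2,
                          seed = 1) {
  if (sum(cohort_sizes) != n_pigs) abort("cohort_sizes must sum to n_pigs")
  if (microbiome_subset_size > n_pigs) {
    abort("microbiome_subset_size cannot exceed n_pigs")
  }
  profiles <- enterotype_profiles(n_bacterial_taxa)
  if (!all(trajectory_map %in% seq_along(profiles))) {
    abort("trajectory_map targets must index an enterotype profile")
  }
  structure(list(
    n_pigs = n_pigs, cohort_sizes = cohort_sizes, age_grid = age_grid,
    microbiome_subset_size = microbiome_subset_size,
    n_bacterial_taxa = n_bacterial_taxa, n_fungal_taxa = n_fungal_taxa,
    profiles = profiles, trajectory_map = trajectory_map,
    n_reverting = n_reverting,
    concentration_by_age = concentration_by_age,
    library_size_meanlog = library_size_meanlog,
    library_size_sdlog = library_size_sdlog,
    fungal_concentration = fungal_concentration,
    candida_bump = candida_bump,
    amr_curves = default_amr_curves(),
    ar1_phi = ar1_phi, ar_sd = ar_sd, noise_sd = noise_sd,
    detection_limit_log10 = detection_limit_log10,
    qpcr_curves = default_qpcr_curves(),
    qpcr_pig_sd = qpcr_pig_sd, qpcr_noise_sd = qpcr_noise_sd,
    seed = seed
  ), class = "cohort_config")
}

age_param <- function(param, age) {
  key <- as.character(age)
  out <- unname(param[key])
  if ("default" %in% names(param)) {
    out[is.na(out)] <- unname(param["default"])
  }
  if (anyNA(out)) abort(paste0("no parameter value for age ", age[is.na(out)][1]))
  out
}

# Mean log10 CFU/g node curves per (bacterium, drug) on the 9-point age grid:
# high at week 3, decline to ~week 10, class-specific rises between weeks 12
# and 32, and smaller gestation/lactation-phase changes. "total" rows are the
# no-antimicrobial plate counts.
default_amr_curves <- function() {
  grid <- study_age_grid()
  rows <- list(
    c("coliform", "none_total",       "total",           7.8, 7.6, 7.5, 7.5, 7.5, 7.6, 7.5, 7.5, 7.4),
    c("coliform", "ampicillin",       "aminopenicillins", 6.5, 5.5, 4.5, 4.5, 5.5, 6.0, 5.8, 5.7, 5.6),
    c("coliform", "gentamicin",       "aminoglycosides",  6.2, 5.3, 4.4, 4.4, 5.3, 5.8, 5.3, 4.9, 4.4),
    c("coliform", "ceftriaxone",      "cephalosporins_3g",4.8, 4.2, 3.5, 3.2, 2.4, 2.5, 2.9, 3.2, 3.2),
    c("coliform", "azithromycin",     "macrolides",       6.0, 5.2, 4.4, 4.4, 5.2, 5.7, 5.6, 5.5, 5.4),
    c("coliform", "chloramphenicol",  "phenicols",        4.5, 4.0, 3.5, 3.4, 3.3, 3.3, 3.7, 4.0, 4.0),
    c("coliform", "sulfamethoxazole", "sulfonamides",     6.4, 5.5, 4.6, 4.6, 5.5, 6.0, 5.5, 5.2, 5.1),
    c("coliform", "tetracycline",     "tetracyclines",    6.8, 5.8, 4.8, 4.8, 5.8, 6.3, 5.8, 5.3, 5.2),
    c("enterococcus", "none_total",   "total",            7.0, 7.2, 7.4, 7.5, 7.7, 7.8, 7.4, 7.0, 6.7),
    c("enterococcus", "gentamicin",   "aminoglycosides",  6.6, 6.2, 5.8, 5.6, 5.1, 4.6, 4.0, 3.9, 3.7),
    c("enterococcus", "lincomycin",   "lincosamides",     6.2, 5.4, 4.6, 4.6, 4.9, 5.6, 5.5, 5.4, 5.3),
    c("enterococcus", "erythromycin", "macrolides",       6.3, 5.4, 4.5, 4.5, 4.8, 5.6, 5.5, 5.0, 5.0),
    c("enterococcus", "nitrofurantoin","nitrofurans",     5.0, 4.7, 4.4, 4.4, 3.8, 3.8, 3.8, 3.8, 3.8),
    c("enterococcus", "penicillin",   "penicillins",      6.5, 6.1, 5.7, 5.5, 5.0, 4.5, 3.9, 3.8, 3.6),
    c("enterococcus", "nalidixic_acid","quinolones",      5.8, 5.1, 4.4, 4.4, 4.6, 5.3, 5.8, 5.8, 5.7),
    c("enterococcus", "tetracycline", "tetracyclines",    6.5, 5.6, 4.7, 4.6, 5.0, 5.8, 5.7, 5.6, 5.5)
  )
  purrr::map_dfr(rows, function(r) {
    tibble(bacterium = r[1], drug = r[2], drug_class = r[3],
           age_weeks = grid, mean_log10 = as.numeric(r[-(1:3)]))
  })
}

# Absolute log10 copies/g node curves: tet(A) starts at 7.10 and bla-CTX-M at
# 5.35 at week 3, both declining through week 10 then partially rebounding;
# 16S is high and near-flat, slightly lower at week 3 so the standardized
# (gene minus 16S) week-3 tet(A) mean is -3.6.
default_qpcr_curves <- function() {
  grid <- study_age_grid()
  tibble(
    gene = rep(c("tetA", "blaCTXM", "16S"), each = length(grid)),
    age_weeks = rep(grid, 3),
    mean_log10 = c(
      7.10, 6.3, 5.6, 5.7, 6.3, 6.1, 6.0, 6.0, 6.2,
      5.35, 4.5, 3.8, 3.9, 4.5, 4.6, 4.5, 4.5, 4.5,
      10.70, 11.0, 11.2, 11.2, 11.3, 11.3, 11.3, 11.3, 11.3
    )
  )
}

#' Generate the longitudinal sampling design
#'
#' One record per pig per age point (162 samples in the default design), with
#' the microbiome-profiling flag set for a cohort-balanced subset of pigs at
#' every age point (72 flagged samples by default). Deterministic given
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return a metadata tibble (see [read_metadata()] for columns).
#' @export
generate_design <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  pigs <- sprintf("P%02d", seq_len(config$n_pigs))
  cohort <- rep(c(1, 2), times = config$cohort_sizes)
  # the profiled subset is split evenly across cohorts (4 + 4 by default)
  half <- floor(config$microbiome_subset_size / 2)
  per_cohort <- c(half, config$microbiome_subset_size - half)
  for (i in 1:2) {
    excess <- max(0, per_cohort[i] - config$cohort_sizes[i])
    per_cohort[i] <- per_cohort[i] - excess
    per_cohort[3 - i] <- per_cohort[3 - i] + excess
  }
  subset_pigs <- with_seed(stage_seed(config$seed, "design"), {
    unlist(lapply(c(1, 2), function(co) {
      pool <- pigs[cohort == co]
      sort(sample(pool, min(per_cohort[co], length(pool))))
    }))
  })
  design <- tidyr::expand_grid(pig_id = pigs, age_weeks = config$age_grid) %>%
    mutate(
      cohort = cohort[match(.data$pig_id, pigs)],
      sample_id = sprintf("%s_w%02d", .data$pig_id, .data$age_weeks),
      stage = stage_for_age(.data$age_weeks),
      microbiome_subset = .data$pig_id %in% subset_pigs,
      raw_read_count = NA_real_
    ) %>%
    select("sample_id", "pig_id", "cohort", "age_weeks", "stage",
           "microbiome_subset", "raw_read_count")
  validate_metadata(design, strict_ages = all(config$age_grid %in% study_age_grid()))
}

# Which pigs revert to component 3 late in life (chosen once, seeded, among
# the microbiome subset so the 6-of-8 / 2-of-8 split is observable).
reverting_pigs <- function(design, config) {
  subset_pigs <- sort(unique(design$pig_id[design$microbiome_subset]))
  if (config$n_reverting == 0 || length(subset_pigs) == 0) return(character(0))
  with_seed(stage_seed(config$seed, "reversion"),
            sort(sample(subset_pigs, min(config$n_reverting, length(subset_pigs)))))
}

true_component <- function(pig_id, age_weeks, config, reverters) {
  k <- unname(config$trajectory_map[as.character(age_weeks)])
  late <- age_weeks >= 49
  ifelse(late & pig_id %in% reverters, 3, k)
}

#' Generate bacterial genus counts with known enterotype truth
#'
#' For each microbiome-subset sample: the enterotype component is looked up in
#' the age trajectory (with late reversion for the configured pigs), a library
#' size is drawn from the age-specific log-normal, and counts are drawn from
#' the Dirichlet-multinomial whose concentration vector is the component
#' profile scaled by the age-dependent total concentration.
#'
#' @param design output of [generate_design()].
#' @param config a [cohort_config()].
#' @return a list: `counts` (count-table tibble), `truth` (tibble with
#'   `sample_id`, `true_component`, `reverting`, `library_size`).
#' @export
generate_bacterial_counts <- function(design, config = cohort_config()) {
  sub <- design %>% filter(.data$microbiome_subset) %>% arrange(.data$sample_id)
  reverters <- reverting_pigs(design, config)
  taxa <- names(config$profiles[[1]])
  with_seed(stage_seed(config$seed, "bacterial"), {
    comp <- true_component(sub$pig_id, sub$age_weeks, config, reverters)
    lib <- pmax(1, round(rlnorm(
      nrow(sub),
      meanlog = age_param(config$library_size_meanlog, sub$age_weeks),
      sdlog = age_param(config$library_size_sdlog, sub$age_weeks)
    )))
    theta <- age_param(config$concentration_by_age, sub$age_weeks)
    m <- matrix(0, nrow(sub), length(taxa), dimnames = list(sub$sample_id, taxa))
    for (i in seq_len(nrow(sub))) {
      alpha <- config$profiles[[comp[i]]] * theta[i]
      p <- rdirichlet1(alpha)
      m[i, ] <- rmultinom(1, lib[i], p)[, 1]
    }
    list(
      counts = matrix_to_count_table(m),
      truth = tibble(sample_id = sub$sample_id, pig_id = sub$pig_id,
                     age_weeks = sub$age_weeks, true_component = comp,
                     reverting = sub$pig_id %in% reverters, library_size = lib)
    )
  })
}

#' Generate fungal ASV counts
#'
#' A single-component Dirichlet-multinomial over 291 taxa split into two
#' phylum groups (the first dominant), with a deliberately small total
#' concentration so communities are low-diversity and highly variable between
#' pigs, and a multiplicative bump in designated Candida-like taxa at the
#' parturition age.
#'
#' @inheritParams generate_bacterial_counts
#' @return a count-table tibble over the microbiome-subset samples.
#' @export
generate_fungal_counts <- function(design, config = cohort_config()) {
  sub <- design %>% filter(.data$microbiome_subset) %>% arrange(.data$sample_id)
  n1 <- round(config$n_fungal_taxa * 0.79)   # dominant phylum group
  n2 <- config$n_fungal_taxa - n1
  candida <- sprintf("Candida_like_%02d", 1:5)
  taxa <- c(candida, sprintf("Ascomycota_%03d", seq_len(n1 - 5)),
            sprintf("Basidiomycota_%03d", seq_len(n2)))
  w1 <- 0.92 * 0.9^seq_len(n1) / sum(0.9^seq_len(n1))
  w2 <- 0.08 * 0.9^seq_len(n2) / sum(0.9^seq_len(n2))
  base <- setNames(c(w1, w2), taxa)
  with_seed(stage_seed(config$seed, "fungal"), {
    m <- matrix(0, nrow(sub), length(taxa), dimnames = list(sub$sample_id, taxa))
    lib <- pmax(1, round(rlnorm(nrow(sub), log(4e4), 0.5)))
    for (i in seq_len(nrow(sub))) {
      prof <- base
      if (sub$age_weeks[i] == 50) prof[candida] <- prof[candida] * config$candida_bump
      alpha <- config$fungal_concentration * prof / sum(prof)
      m[i, ] <- rmultinom(1, lib[i], rdirichlet1(alpha))[, 1]
    }
    matrix_to_count_table(m)
  })
}

# Stationary continuous-time AR(1) path over (possibly irregular) ages.
ar1_path <- function(ages, phi, sd) {
  z <- numeric(length(ages))
  z[1] <- rnorm(1, 0, sd)
  if (length(ages) > 1) {
    for (j in 2:length(ages)) {
      rho <- phi^(ages[j] - ages[j - 1])
      z[j] <- rho * z[j - 1] + rnorm(1, 0, sd * sqrt(max(0, 1 - rho^2)))
    }
  }
  z
}

#' Generate phenotypic AMR plate counts
#'
#' For every pig x age x indicator bacterium x drug, log10 CFU/g equals the
#' configured mean curve plus a within-pig continuous-time AR(1) process
#' (correlation `phi^delta-weeks`) plus white noise. Draws below the detection
#' limit are recorded as no growth (missing value).
#'
#' @inheritParams generate_bacterial_counts
#' @return a list: `amr` (tibble with columns `sample_id`, `bacterium`,
#'   `drug`, `drug_class`, `log10_cfu_per_g`) and `truth` (the mean curves and
#'   the AR(1) parameters used).
#' @export
generate_amr_observations <- function(design, config = cohort_config()) {
  des <- design %>% arrange(.data$pig_id, .data$age_weeks)
  curves <- config$amr_curves
  series <- curves %>% distinct(.data$bacterium, .data$drug, .data$drug_class)
  with_seed(stage_seed(config$seed, "amr"), {
    out <- vector("list", nrow(series))
    pigs <- split(des, des$pig_id)
    for (s in seq_len(nrow(series))) {
      cv <- curves %>%
        filter(.data$bacterium == series$bacterium[s], .data$drug == series$drug[s])
      rows <- purrr::map_dfr(pigs, function(pd) {
        mu <- approx_curve(cv$age_weeks, cv$mean_log10, pd$age_weeks)
        z <- ar1_path(pd$age_weeks, config$ar1_phi, config$ar_sd)
        e <- rnorm(nrow(pd), 0, config$noise_sd)
        tibble(sample_id = pd$sample_id, log10_cfu_per_g = mu + z + e)
      })
      rows$bacterium <- series$bacterium[s]
      rows$drug <- series$drug[s]
      rows$drug_class <- series$drug_class[s]
      out[[s]] <- rows
    }
    amr <- bind_rows(out) %>%
      mutate(log10_cfu_per_g = ifelse(
        .data$log10_cfu_per_g < config$detection_limit_log10,
        NA_real_, .data$log10_cfu_per_g
      )) %>%
      select("sample_id", "bacterium", "drug", "drug_class", "log10_cfu_per_g")
    list(amr = amr,
         truth = list(curves = curves, phi = config$ar1_phi,
                      ar_sd = config$ar_sd, noise_sd = config$noise_sd,
                      detection_limit_log10 = config$detection_limit_log10))
  })
}

#' Generate qPCR gene-copy observations
#'
#' log10 copies/g of tet(A), bla-CTX-M and 16S follow the configured age
#' curves with per-pig random intercepts and white noise; with both standard
#' deviations set to 0 the week-3 absolute means are exactly the configured
#' baselines (7.10 for tet(A), 5.35 for bla-CTX-M). Standardized values
#' (gene minus 16S on the log10 scale) then follow the implied difference
#' curves.
#'
#' @inheritParams generate_bacterial_counts
#' @return a tibble with columns `sample_id`, `gene`, `copies_per_g`.
#' @export
generate_qpcr_observations <- function(design, config = cohort_config()) {
  sub <- design %>% filter(.data$microbiome_subset) %>% arrange(.data$sample_id)
  curves <- config$qpcr_curves
  genes <- unique(curves$gene)
  pigs <- unique(sub$pig_id)
  with_seed(stage_seed(config$seed, "qpcr"), {
    purrr::map_dfr(genes, function(g) {
      cv <- curves %>% filter(.data$gene == g)
      b <- setNames(rnorm(length(pigs), 0, config$qpcr_pig_sd), pigs)
      mu <- approx_curve(cv$age_weeks, cv$mean_log10, sub$age_weeks)
      y <- mu + b[sub$pig_id] + rnorm(nrow(sub), 0, config$qpcr_noise_sd)
      tibble(sample_id = sub$sample_id, gene = g, copies_per_g = 10^unname(y))
    })
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs every generator and assembles the result, copying the drawn library
#' sizes into the metadata `raw_read_count` column. If `outdir` is given,
#' writes `counts.tsv`, `fungal_counts.tsv`, `metadata.tsv`, `amr.tsv`,
#' `qpcr.tsv` and `truth.json` there.
#'
#' @param config a [cohort_config()].
#' @param outdir optional output directory.
#' @return a list: `dataset` (an `analysis_dataset`), `fungal_counts`, and
#'   `truth` (enterotype labels, AMR curve truth, reverting pigs).
#' @export
simulate_cohort <- function(config = cohort_config(), outdir = NULL) {
  design <- generate_design(config)
  bact <- generate_bacterial_counts(design, config)
  fungal <- generate_fungal_counts(design, config)
  amr <- generate_amr_observations(design, config)
  qpcr <- generate_qpcr_observations(design, config)
  design$raw_read_count[match(bact$truth$sample_id, design$sample_id)] <-
    bact$truth$library_size
  ds <- assemble_dataset(bact$counts, design, amr = amr$amr, qpcr = qpcr,
                         strict_ages = all(config$age_grid %in% study_age_grid()))
  truth <- list(enterotypes = bact$truth, amr = amr$truth,
                reverting_pigs = sort(unique(bact$truth$pig_id[bact$truth$reverting])))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_count_table(bact$counts, file.path(outdir, "counts.tsv"))
    write_count_table(fungal, file.path(outdir, "fungal_counts.tsv"))
    readr::write_tsv(design, file.path(outdir, "metadata.tsv"), progress = FALSE)
    readr::write_tsv(amr$amr, file.path(outdir, "amr.tsv"), progress = FALSE)
    readr::write_tsv(qpcr, file.path(outdir, "qpcr.tsv"), progress = FALSE)
    jsonlite::write_json(
      list(enterotypes = bact$truth, reverting_pigs = truth$reverting_pigs,
           amr_curves = amr$truth$curves, phi = amr$truth$phi),
      file.path(outdir, "truth.json"), dataframe = "columns", digits = NA
    )
  }
  list(dataset = ds, fungal_counts = fungal, truth = truth)
}
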