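ra_table <- function(mat, ids) {
  # rows already relative "abundances" in counts; scale to integers
  make_count_table(round(mat * 1000), ids = ids)
}

test_that("first-appearance ages rank within pig with midrank ties", {
  # one pig, 3 genera appearing at weeks 3 / 10 / 22
  md <- toy_metadata(pigs = 1, ages = c(3, 10, 22))
  m <- rbind(c(0.5, 0.001, 0.001),
             c(0.5, 0.5, 0.001),
             c(0.3, 0.3, 0.4))
  colnames(m) <- c("gA", "gB", "gC")
  ranks <- first_appearance_ranks(ra_table(m, md$sample_id), md)
  expect_equal(unname(ranks["P1", ]), c(1, 2, 3))
  expect_equal(unname(attr(ranks, "first_age")["P1", ]), c(3, 10, 22))

  # two genera tied at week 6 receive midranks
  md2 <- toy_metadata(pigs = 1, ages = c(3, 6, 10))
  m2 <- rbind(c(0.9, 0.001, 0.001, 0.001),
              c(0.3, 0.3, 0.3, 0.001),
              c(0.25, 0.25, 0.25, 0.25))
  colnames(m2) <- c("gA", "gB", "gC", "gD")
  r2 <- first_appearance_ranks(ra_table(m2, md2$sample_id), md2)
  expect_equal(unname(r2["P1", ]), c(1, 2.5, 2.5, 4))

  # genus above threshold everywhere for every pig: all ranks tied
  md3 <- toy_metadata(pigs = 2, ages = c(3, 6))
  m3 <- matrix(0.25, 4, 4, dimnames = list(NULL, paste0("g", 1:4)))
  r3 <- first_appearance_ranks(ra_table(m3, md3$sample_id), md3)
  expect_true(all(r3 == 2.5))
})

test_that("Kendall's W is exact on concordant and enumerated cases", {
  R <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  colnames(R) <- paste0("g", 1:4)
  kw <- kendalls_w(R, n_permutations = 200, seed = 1)
  expect_equal(kw$statistic, 1)

  # 3 x 3 instance: package exact enumeration vs brute force over (3!)^3
  R2 <- rbind(c(1, 2, 3), c(2, 1, 3), c(1, 3, 2))
  colnames(R2) <- paste0("g", 1:3)
  kexact <- kendalls_w(R2, exact = TRUE)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  wstat <- function(R) {
    Rj <- colSums(R)
    S <- sum((Rj - mean(Rj))^2)
    12 * S / (nrow(R)^2 * (ncol(R)^3 - ncol(R)))
  }
  ws <- c()
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    ws <- c(ws, wstat(rbind(R2[1, perms[i, ]], R2[2, perms[j, ]],
                            R2[3, perms[k, ]])))
  }
  expect_equal(kexact$n_permutations, 216)
  expect_equal(kexact$p_value, mean(ws >= kexact$statistic - 1e-12))
  expect_equal(kexact$statistic, wstat(R2))

  # independently shuffled ranks: W near zero
  set.seed(8)
  Rbig <- t(replicate(40, sample(1:12)))
  colnames(Rbig) <- paste0("g", 1:12)
  kw0 <- kendalls_w(Rbig, n_permutations = 200, seed = 2)
  expect_lt(kw0$statistic, 0.15)
  expect_gt(kw0$p_value, 0.05)
})

test_that("W is invariant to order-preserving rank relabelings", {
  set.seed(4)
  R <- t(replicate(5, sample(1:6)))
  colnames(R) <- paste0("g", 1:6)
  kw1 <- kendalls_w(R, n_permutations = 50, seed = 9)
  # squash ranks through a monotone map per pig; complete-case re-ranking
  # restores the same ranking
  R2 <- R * 10 + 3
  kw2 <- kendalls_w(R2, n_permutations = 50, seed = 9)
  expect_equal(kw1$statistic, kw2$statistic)
})

test_that("consensus order uses medians with alphabetical tie-break", {
  R <- rbind(c(1, 2, 3, 4),
             c(1, 2, 4, 3),
             c(4, 1, 2, 3))
  colnames(R) <- c("gB", "gA", "gD", "gC")
  cons <- consensus_order(R, n_permutations = 50, seed = 1)
  med <- apply(R, 2, median)
  expect_equal(cons$median_rank,
               unname(med[order(med, colnames(R))]))
  expect_equal(cons$genus[1], "gB")  # median 1 beats gA's 2
  expect_true(!is.null(attr(cons, "kendalls_w")))

  # single pig: consensus equals that pig's own order
  R1 <- matrix(c(2, 1, 3), 1, dimnames = list("P1", c("gA", "gB", "gC")))
  c1 <- suppressWarnings(consensus_order(rbind(R1, R1), n_permutations = 10,
                                         seed = 1))
  expect_equal(c1$genus, c("gB", "gA", "gC"))
})

test_that("maturation scores average consensus ranks of present genera", {
  cons <- tibble::tibble(genus = paste0("g", 1:7), median_rank = 1:7,
                         consensus_rank = 1:7, n_pigs_ranked = 3)
  class(cons) <- c("consensus_ranking", class(cons))
  md <- toy_metadata(pigs = 1, ages = c(3, 6, 10))
  m <- matrix(0.0001, 3, 7, dimnames = list(NULL, paste0("g", 1:7)))
  m[1, 1] <- 0.9                 # only the lowest-ranked genus
  m[2, c(1, 4, 7)] <- 0.3        # ranks {1, 4, 7} -> mean 4
  m[3, ] <- 1 / 7                # everything present -> mean rank 4
  sc <- maturation_scores(cons, ra_table(m, md$sample_id), md)
  expect_equal(sc$score, c(1, 4, 4))
  expect_equal(sc$n_present_genera, c(1L, 3L, 7L))
})

test_that("scores are invariant to genus relabeling and count rescaling", {
  cfg <- small_cohort(seed = 11)
  des <- generate_design(cfg)
  gen <- generate_bacterial_counts(des, cfg)
  ranks <- first_appearance_ranks(gen$counts, des)
  cons <- consensus_order(ranks, n_permutations = 20, seed = 1)
  sc <- maturation_scores(cons, gen$counts, des)

  # multiply all counts of every sample by 3: thresholds are relative
  scaled <- gen$counts
  scaled[, -1] <- scaled[, -1] * 3
  sc2 <- maturation_scores(cons, scaled, des)
  expect_equal(sc$score, sc2$score)

  # relabel genera consistently everywhere
  map <- setNames(paste0("X_", names(gen$counts)[-1]), names(gen$counts)[-1])
  renamed <- gen$counts
  names(renamed)[-1] <- unname(map)
  cons2 <- cons
  cons2$genus <- unname(map[cons$genus])
  sc3 <- maturation_scores(cons2, renamed, des)
  expect_equal(sc$score, sc3$score)
})

test_that("a sample with no present consensus genus is flagged missing", {
  cons <- tibble::tibble(genus = c("gA", "gB"), median_rank = 1:2,
                         consensus_rank = 1:2, n_pigs_ranked = 2)
  md <- toy_metadata(pigs = 1, ages = c(3, 6))
  # second sample: both consensus genera far below the 0.5% threshold
  counts <- make_count_table(rbind(c(6000, 4000, 0), c(1, 1, 10000)),
                             ids = md$sample_id)
  colnames(counts)[-1] <- c("gA", "gB", "gZ")
  expect_warning(sc <- maturation_scores(cons, counts, md), "no present")
  expect_true(is.na(sc$score[2]))
})
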