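two_component_counts <- function(n_per = 12, n_taxa = 12, size = 400, seed = 1) {
  set.seed(seed)
  p1 <- c(rep(8, n_taxa / 2), rep(1, n_taxa / 2))
  p2 <- rev(p1)
  draw <- function(p) {
    t(vapply(seq_len(n_per), function(i) {
      g <- rgamma(n_taxa, shape = p * 10)
      rmultinom(1, size, g / sum(g))[, 1]
    }, numeric(n_taxa)))
  }
  m <- rbind(draw(p1), draw(p2))
  colnames(m) <- sprintf("t%02d", seq_len(n_taxa))
  list(tbl = make_count_table(m), truth = rep(1:2, each = n_per))
}

test_that("the DM log-likelihood is a normalized distribution", {
  expect_equal(dm_log_likelihood(c(0, 0, 0), c(1, 2, 3)), 0)
  expect_equal(dm_log_likelihood(7, 2.5), 0)   # single-taxon degenerate support
  expect_error(dm_log_likelihood(c(1, 1), c(1, -1)), "strictly positive")

  # exhaustive enumeration over all compositions: probabilities sum to one
  compositions <- function(n, s) {
    if (s == 1) return(matrix(n, 1, 1))
    do.call(rbind, lapply(0:n, function(k) {
      cbind(k, compositions(n - k, s - 1))
    }))
  }
  for (n in c(2, 5)) {
    for (s in c(2, 3)) {
      alpha <- seq(0.5, 1.5, length.out = s)
      xs <- compositions(n, s)
      total <- sum(apply(xs, 1, function(x) exp(dm_log_likelihood(x, alpha))))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
})

test_that("K = 1 EM equals the direct single-component ML fit", {
  tbl <- random_count_table(15, 6, lambda = 40, seed = 13)
  fit <- fit_dmm(tbl, 1, n_restarts = 2, seed = 1)
  X <- as.matrix(tbl[, -1])
  # independent oracle: direct optimization from a different start
  negll <- function(la) -sum(apply(X, 1, dm_log_likelihood, alpha = exp(la)))
  opt <- optim(rep(0, 6), negll, method = "L-BFGS-B", lower = -10, upper = 10,
               control = list(maxit = 500))
  expect_equal(fit$log_likelihood, -opt$value, tolerance = 1e-6)
  expect_equal(fit$weights, 1)
})

test_that("well-separated components are recovered and EM is monotone", {
  sim <- two_component_counts(seed = 3)
  fit <- fit_dmm(sim$tbl, 2, n_restarts = 2, seed = 5)
  expect_true(all(diff(fit$trace) >= -1e-6 * abs(fit$log_likelihood)))
  asg <- assign_enterotypes(fit, sim$tbl)
  expect_gte(label_match_accuracy(sim$truth, asg$map_component), 0.95)

  # duplicating every sample doubles the log-likelihood, same parameters
  dup <- dplyr::bind_rows(sim$tbl,
                          dplyr::mutate(sim$tbl,
                                        sample_id = paste0(sample_id, "_b")))
  fit2 <- fit_dmm(dup, 2, n_restarts = 2, seed = 5)
  expect_equal(fit2$log_likelihood, 2 * fit$log_likelihood,
               tolerance = 1e-3 * abs(fit$log_likelihood))
  ord <- order(fit$alpha[, 1])
  ord2 <- order(fit2$alpha[, 1])
  expect_equal(fit2$alpha[ord2, ], fit$alpha[ord, ], tolerance = 0.05)
})

test_that("the analytic Hessian matches central finite differences", {
  set.seed(42)
  X <- matrix(rpois(8 * 3, 20), 8, 3)
  colnames(X) <- c("a", "b", "c")
  tbl <- make_count_table(X)
  fit <- fit_dmm(tbl, 2, n_restarts = 2, seed = 1)
  theta <- enterochron:::theta_from_fit(fit)
  f <- function(th) enterochron:::dmm_negloglik_theta(th, as.matrix(tbl[, -1]), 2)
  d <- length(theta)
  h <- 1e-4
  Hfd <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      e1 <- e2 <- rep(0, d)
      e1[i] <- h
      e2[j] <- h
      Hfd[i, j] <- (f(theta + e1 + e2) - f(theta + e1 - e2) -
                      f(theta - e1 + e2) + f(theta - e1 - e2)) / (4 * h^2)
    }
  }
  Ha <- enterochron:::dmm_hessian(fit, tbl)$hessian
  expect_lt(max(abs(Ha - Hfd)) / max(abs(Hfd)), 1e-3)
})

test_that("the Laplace score penalizes redundant components and ignores taxon order", {
  tbl <- random_count_table(20, 5, lambda = 30, seed = 21)
  fit1 <- fit_dmm(tbl, 1, n_restarts = 2, seed = 2)
  # duplicate the single component: identical likelihood, more parameters
  fit2 <- fit1
  fit2$K <- 2
  fit2$weights <- c(0.5, 0.5)
  fit2$alpha <- rbind(fit1$alpha, fit1$alpha)
  rownames(fit2$alpha) <- c("E1", "E2")
  s1 <- laplace_score(fit1, tbl)
  s2 <- suppressWarnings(laplace_score(fit2, tbl))
  expect_gt(s2, s1)

  # permutation of taxa leaves the score unchanged
  perm <- c(3, 1, 5, 2, 4)
  tblp <- tbl[, c(1, 1 + perm)]
  fitp <- fit1
  fitp$alpha <- fit1$alpha[, perm, drop = FALSE]
  fitp$taxa <- fit1$taxa[perm]
  expect_equal(laplace_score(fitp, tblp), s1, tolerance = 1e-8)
})

test_that("select_k prefers K = 1 for exchangeable data and honours k_range", {
  cfg <- small_cohort(seed = 2)
  # all four profiles identical: no component structure to find
  cfg$profiles <- rep(cfg$profiles[1], 4)
  names(cfg$profiles) <- paste0("E", 1:4)
  des <- generate_design(cfg)
  gen <- generate_bacterial_counts(des, cfg)
  sel <- suppressWarnings(select_k(gen$counts, 1:3, n_restarts = 2, seed = 4))
  expect_equal(sel$selected_k, 1L)

  only3 <- suppressWarnings(select_k(gen$counts, 3, n_restarts = 1, seed = 4))
  expect_equal(only3$selected_k, 3L)
  expect_equal(nrow(only3$scores), 1)
})

test_that("posteriors are normalized, MAP-consistent and confident on clear samples", {
  sim <- two_component_counts(seed = 6)
  fit <- fit_dmm(sim$tbl, 2, n_restarts = 2, seed = 6)
  asg <- assign_enterotypes(fit, sim$tbl)
  post <- as.matrix(asg[, grep("^posterior_", names(asg))])
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-9)
  expect_equal(asg$map_component, unname(apply(post, 1, which.max)))

  # a sample sitting at a component's expected profile is assigned with
  # near-certain posterior
  p1 <- fit$alpha[1, ] / sum(fit$alpha[1, ])
  x <- round(p1 * 2000)
  probe <- make_count_table(matrix(x, 1, dimnames = list("probe", fit$taxa)))
  pa <- assign_enterotypes(fit, probe)
  expect_gt(pa$max_posterior, 0.99)

  f1 <- fit_dmm(sim$tbl, 1, n_restarts = 1, seed = 1)
  a1 <- assign_enterotypes(f1, sim$tbl)
  expect_true(all(a1$posterior_1 == 1))
})

test_that("trajectories count transitions as hand-enumerated", {
  asg <- tibble::tibble(
    sample_id = c("P1_w03", "P1_w06", "P1_w10", "P2_w03", "P2_w06", "P2_w10"),
    map_component = c(1L, 1L, 2L, 1L, 2L, 2L)
  )
  md <- toy_metadata(pigs = 2, ages = c(3, 6, 10))
  tr <- enterotype_trajectories(asg, md)
  # per-age proportions sum to one
  sums <- tapply(tr$proportions$proportion, tr$proportions$age_weeks, sum)
  expect_equal(as.numeric(sums), rep(1, 3))
  expect_equal(tr$proportions$proportion[
    tr$proportions$age_weeks == 3 & tr$proportions$enterotype == 1], 1)
  # transitions: 3->6: {1->1, 1->2}; 6->10: {1->2, 2->2}
  get_n <- function(fa, ta, f, t) {
    r <- tr$transitions[tr$transitions$from_age == fa &
                          tr$transitions$to_age == ta &
                          tr$transitions$from == f & tr$transitions$to == t, ]
    if (nrow(r)) r$n else 0L
  }
  expect_equal(get_n(3, 6, 1, 1), 1L)
  expect_equal(get_n(3, 6, 1, 2), 1L)
  expect_equal(get_n(6, 10, 1, 2), 1L)
  expect_equal(get_n(6, 10, 2, 2), 1L)

  # single-label input: degenerate proportions, no off-diagonal transitions
  asg1 <- dplyr::mutate(asg, map_component = 2L)
  tr1 <- enterotype_trajectories(asg1, md)
  expect_true(all(tr1$proportions$proportion == 1))
  expect_true(all(tr1$transitions$from == tr1$transitions$to))
})
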