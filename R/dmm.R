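# Dirichlet-multinomial mixture (DMM) enterotyping: EM fitting over raw
# genus counts, Laplace-approximation model evidence for choosing the number
# of community types, maximum-posterior assignment, and per-pig trajectories.
#
# The DM likelihood models raw counts, so the input here is the raw genus
# count table, not a normalized one.

#' Dirichlet-multinomial log-likelihood
#'
#' Log probability of a count vector under the Dirichlet-multinomial with
#' concentration `alpha`: `log[ G(A) G(n+1) / G(n+A) * prod_j G(x_j+a_j) /
#' (G(a_j) G(x_j+1)) ]` with `A = sum(alpha)`, `n = sum(x)`, computed with
#' log-gamma throughout. Sums to probability one over all compositions of n.
#'
#' @param x nonnegative integer count vector.
#' @param alpha strictly positive concentration vector, same length.
#' @return the log-likelihood (a scalar).
#' @export
dm_log_likelihood <- function(x, alpha) {
  if (any(alpha <= 0)) abort("alpha must be strictly positive")
  if (length(x) != length(alpha)) abort("x and alpha must have equal length")
  if (any(x < 0) || any(x != round(x))) abort("x must be nonnegative integers")
  n <- sum(x)
  A <- sum(alpha)
  lgamma(A) - lgamma(n + A) + lgamma(n + 1) +
    sum(lgamma(x + alpha) - lgamma(alpha) - lgamma(x + 1))
}

# Vectorized DM log-likelihood of every row of X under one alpha.
# const_i = lgamma(n_i + 1) - sum_j lgamma(x_ij + 1) may be precomputed.
dm_loglik_rows <- function(X, alpha, const = NULL) {
  if (is.null(const)) {
    const <- lgamma(rowSums(X) + 1) - rowSums(lgamma(X + 1))
  }
  n <- rowSums(X)
  A <- sum(alpha)
  const + lgamma(A) - lgamma(n + A) +
    rowSums(lgamma(sweep(X, 2, alpha, "+"))) - sum(lgamma(alpha))
}

# Responsibility-weighted negative DM log-likelihood and gradient in
# log-alpha, for the M-step inner optimizer.
dm_weighted_negll <- function(log_alpha, X, w, const) {
  alpha <- exp(log_alpha)
  -sum(w * dm_loglik_rows(X, alpha, const))
}

dm_weighted_grad <- function(log_alpha, X, w, const) {
  alpha <- exp(log_alpha)
  n <- rowSums(X)
  A <- sum(alpha)
  c1 <- sum(w * (digamma(A) - digamma(n + A)))
  gj <- colSums(w * digamma(sweep(X, 2, alpha, "+"))) - sum(w) * digamma(alpha)
  -(c1 + gj) * alpha
}

# k-means-style initialization on proportion profiles.
dmm_init <- function(X, K, restart) {
  P <- X / pmax(1, rowSums(X))
  if (K == 1) {
    centers <- matrix(colMeans(P), 1)
  } else {
    km <- suppressWarnings(stats::kmeans(P, centers = K, nstart = 1 + restart))
    centers <- km$centers
  }
  alpha <- pmax(centers, 1e-4) * 50
  list(alpha = alpha, weights = rep(1 / K, K))
}

#' Fit a Dirichlet-multinomial mixture by EM
#'
#' E-step responsibilities are proportional to `pi_k * exp(dm loglik)`
#' (log-sum-exp throughout); the M-step sets `pi_k` to the mean
#' responsibility and maximizes each component's responsibility-weighted DM
#' log-likelihood over log-concentrations with a bounded quasi-Newton inner
#' loop, warm-started between iterations. The best of `n_restarts`
#' k-means-seeded starts by final log-likelihood is returned; the recorded
#' log-likelihood trace is non-decreasing.
#'
#' @param counts a raw count-table tibble.
#' @param K number of mixture components (`1 <= K <=` number of samples).
#' @param n_restarts seeded restarts (default 3).
#' @param max_iter maximum EM iterations per restart (default 200).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param seed optional integer seed.
#' @return a `dmm_fit`: list with `K`, `weights`, `alpha` (K x taxa matrix),
#'   `log_likelihood`, `trace`, `converged`, `n_iter`.
#' @export
fit_dmm <- function(counts, K, n_restarts = 3, max_iter = 200, tol = 1e-6,
                    seed = NULL) {
  validate_count_table(counts)
  X <- count_matrix(counts)
  if (K < 1) abort("K must be >= 1")
  if (nrow(X) < K) abort("need at least K samples")
  const <- lgamma(rowSums(X) + 1) - rowSums(lgamma(X + 1))
  run_one <- function(restart) {
    init <- dmm_init(X, K, restart)
    alpha <- log(init$alpha)
    wts <- init$weights
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    L <- matrix(0, nrow(X), K)
    for (iter in seq_len(max_iter)) {
      for (k in seq_len(K)) L[, k] <- dm_loglik_rows(X, exp(alpha[k, ]), const)
      Lw <- sweep(L, 2, log(wts), "+")
      lse <- row_logsumexp(Lw)
      ll <- sum(lse)
      trace <- c(trace, ll)
      if (is.finite(ll_old) && (ll - ll_old) <= tol * abs(ll)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      r <- exp(Lw - lse)
      wts <- pmax(colMeans(r), 1e-10)
      wts <- wts / sum(wts)
      maxit <- if (iter <= 2) 50 else 15
      for (k in seq_len(K)) {
        opt <- stats::optim(
          alpha[k, ], fn = dm_weighted_negll, gr = dm_weighted_grad,
          X = X, w = r[, k], const = const,
          method = "L-BFGS-B", lower = -10, upper = 10,
          control = list(maxit = maxit)
        )
        if (opt$value <= dm_weighted_negll(alpha[k, ], X, r[, k], const)) {
          alpha[k, ] <- opt$par
        }
      }
    }
    list(alpha = exp(alpha), weights = wts, ll = trace[length(trace)],
         trace = trace, converged = converged, n_iter = length(trace))
  }
  fits <- if (is.null(seed)) {
    lapply(seq_len(n_restarts), run_one)
  } else {
    with_seed(seed, lapply(seq_len(n_restarts), run_one))
  }
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
  if (!best$converged) {
    warn(paste0("EM did not converge in ", max_iter, " iterations (K = ", K, ")"))
  }
  alpha <- best$alpha
  dimnames(alpha) <- list(paste0("E", seq_len(K)), colnames(X))
  structure(list(
    K = K, weights = best$weights, alpha = alpha,
    log_likelihood = best$ll, trace = best$trace,
    converged = best$converged, n_iter = best$n_iter,
    n_samples = nrow(X), taxa = colnames(X)
  ), class = "dmm_fit")
}

#' @export
print.dmm_fit <- function(x, ...) {
  cat("Dirichlet-multinomial mixture: K =", x$K,
      "| logLik", format(x$log_likelihood, digits = 8),
      "|", x$n_iter, "EM iterations",
      if (!x$converged) "(not converged)", "\n")
  cat("weights:", format(x$weights, digits = 3), "\n")
  invisible(x)
}

#' @rdname fit_dmm
#' @param x a `dmm_fit`.
#' @param ... unused.
#' @export
#' @method glance dmm_fit
glance.dmm_fit <- function(x, ...) {
  tibble(K = x$K, log_likelihood = x$log_likelihood,
         laplace = if (is.null(x$laplace)) NA_real_ else x$laplace,
         n_iter = x$n_iter, converged = x$converged)
}

#' @rdname fit_dmm
#' @export
#' @method tidy dmm_fit
tidy.dmm_fit <- function(x, ...) {
  purrr::map_dfr(seq_len(x$K), function(k) {
    p <- x$alpha[k, ] / sum(x$alpha[k, ])
    tibble(component = k, weight = x$weights[k], taxon = x$taxa,
           expected_proportion = unname(p), concentration = unname(x$alpha[k, ]))
  })
}

# Full mixture negative log-likelihood at an unconstrained parameter vector
# theta = (eta_2..eta_K, log alpha_1, ..., log alpha_K); weights are
# softmax(0, eta). Used by the Laplace score's finite-difference oracle.
dmm_negloglik_theta <- function(theta, X, K, const = NULL) {
  S <- ncol(X)
  eta <- c(0, theta[seq_len(K - 1)])
  logw <- eta - logsumexp(eta)
  la_part <- if (K > 1) theta[-seq_len(K - 1)] else theta
  la <- matrix(la_part, nrow = K, byrow = TRUE)
  L <- vapply(seq_len(K), function(k) {
    dm_loglik_rows(X, exp(la[k, ]), const)
  }, numeric(nrow(X)))
  -sum(row_logsumexp(sweep(L, 2, logw, "+")))
}

theta_from_fit <- function(model) {
  eta <- log(model$weights) - log(model$weights[1])
  c(eta[-1], as.numeric(t(log(model$alpha))))
}

# Analytic Hessian of the negative mixture log-likelihood at the fitted
# parameters, in the unconstrained (logit-weight, log-concentration)
# parameterization; d = (K - 1) + K * S. Assembled from responsibilities:
# for each sample, sum_k r_ik (second derivative of the component log
# density) plus the outer-product information terms
# sum_k r_ik v v' - (sum_k r_ik v)(sum_k r_ik v)'.
dmm_hessian <- function(model, counts) {
  X <- count_matrix(counts)
  if (!identical(colnames(X), model$taxa)) abort("counts do not match the model's taxa")
  K <- model$K
  S <- ncol(X)
  n <- nrow(X)
  const <- lgamma(rowSums(X) + 1) - rowSums(lgamma(X + 1))
  rowsum_x <- rowSums(X)

  L <- vapply(seq_len(K), function(k) {
    dm_loglik_rows(X, model$alpha[k, ], const)
  }, numeric(n))
  Lw <- sweep(matrix(L, n, K), 2, log(model$weights), "+")
  lse <- row_logsumexp(Lw)
  ll <- sum(lse)
  r <- exp(Lw - lse)

  d_eta <- K - 1
  d_tot <- d_eta + K * S
  H_ll <- matrix(0, d_tot, d_tot)  # Hessian of the log-likelihood
  a_idx <- function(k) d_eta + (k - 1) * S + seq_len(S)

  # per-component log-scale gradients g[i, j] and curvature pieces
  G_list <- vector("list", K)
  for (k in seq_len(K)) {
    alpha <- model$alpha[k, ]
    A <- sum(alpha)
    c1 <- digamma(A) - digamma(rowsum_x + A)          # n-vector
    c2 <- trigamma(A) - trigamma(rowsum_x + A)
    G_alpha <- digamma(sweep(X, 2, alpha, "+"))
    G_alpha <- sweep(G_alpha, 2, digamma(alpha), "-") + c1   # n x S
    Gk <- sweep(G_alpha, 2, alpha, "*")                      # log scale
    G_list[[k]] <- Gk
    d2 <- trigamma(sweep(X, 2, alpha, "+"))
    d2 <- sweep(d2, 2, trigamma(alpha), "-")                 # n x S
    rk <- r[, k]
    # sum_i r_ik [ diag(a) (c2 11' + diag(d2_i)) diag(a) + diag(g_ik) ]
    blk <- sum(rk * c2) * tcrossprod(alpha) +
      diag(alpha^2 * colSums(rk * d2) + colSums(rk * Gk), S)
    H_ll[a_idx(k), a_idx(k)] <- H_ll[a_idx(k), a_idx(k)] + blk
  }

  pi_full <- model$weights
  if (d_eta > 0) {
    p2 <- pi_full[-1]
    H_ll[seq_len(d_eta), seq_len(d_eta)] <-
      -n * (diag(p2, d_eta) - tcrossprod(p2))
  }

  # + sum_{i,k} r_ik v_ik v_ik'  -  sum_i w_i w_i'
  W <- matrix(0, n, d_tot)
  if (d_eta > 0) {
    W[, seq_len(d_eta)] <- sweep(r[, -1, drop = FALSE], 2, pi_full[-1], "-")
  }
  for (k in seq_len(K)) {
    rGk <- r[, k] * G_list[[k]]
    W[, a_idx(k)] <- rGk
    H_ll[a_idx(k), a_idx(k)] <- H_ll[a_idx(k), a_idx(k)] +
      crossprod(G_list[[k]], rGk)
    if (d_eta > 0) {
      pk <- as.numeric(seq_len(K)[-1] == k) - pi_full[-1]
      sk <- colSums(rGk)
      cross <- pk %o% sk
      H_ll[seq_len(d_eta), a_idx(k)] <- H_ll[seq_len(d_eta), a_idx(k)] + cross
      H_ll[a_idx(k), seq_len(d_eta)] <- H_ll[a_idx(k), seq_len(d_eta)] + t(cross)
    }
    if (d_eta > 0) {
      # eta-eta part of sum r v v': sum_k n_k p_k p_k'
      pk <- as.numeric(seq_len(K)[-1] == k) - pi_full[-1]
      H_ll[seq_len(d_eta), seq_len(d_eta)] <-
        H_ll[seq_len(d_eta), seq_len(d_eta)] + sum(r[, k]) * tcrossprod(pk)
    }
  }
  H_ll <- H_ll - crossprod(W)

  H_neg <- -(H_ll + t(H_ll)) / 2   # symmetrize the negative-loglik Hessian
  list(hessian = H_neg, log_likelihood = ll, d = d_tot)
}

#' Laplace approximation to the negative log model evidence
#'
#' Gaussian approximation to the model evidence integral around the fitted
#' mode, in the unconstrained (logit-weight, log-concentration)
#' parameterization with `d = (K - 1) + K * S` free parameters. The Hessian
#' `H` of the negative log-likelihood is assembled analytically from
#' responsibilities. Because many concentration parameters (rare taxa) are
#' barely informed by the data, the evidence is computed under a diffuse
#' normal prior with standard deviation `prior_sd` on each unconstrained
#' parameter, which regularizes the otherwise-improper integral over flat
#' directions:
#' `score = -logL + |theta|^2 / (2 prior_sd^2) + (d/2) log prior_sd^2 +
#'  0.5 log det(H + I / prior_sd^2)`.
#' Lower is better. If the regularized Hessian is not positive definite its
#' negative eigenvalues are floored at zero with a warning.
#'
#' @param model a `dmm_fit`.
#' @param counts the raw count table the model was fitted on.
#' @param prior_sd standard deviation of the diffuse normal prior on the
#'   unconstrained parameters (default 10).
#' @return the negative log evidence (a scalar).
#' @export
laplace_score <- function(model, counts, prior_sd = 10) {
  hess <- dmm_hessian(model, counts)
  theta <- theta_from_fit(model)
  ridge <- 1 / prior_sd^2
  H_reg <- hess$hessian + diag(ridge, hess$d)
  ch <- tryCatch(chol(H_reg), error = function(e) NULL)
  if (is.null(ch)) {
    warn("Hessian not positive definite; flooring negative curvature at zero")
    ev <- eigen(hess$hessian, symmetric = TRUE, only.values = TRUE)$values
    logdet <- sum(log(pmax(ev, 0) + ridge))
  } else {
    logdet <- 2 * sum(log(diag(ch)))
  }
  -hess$log_likelihood + sum(theta^2) * ridge / 2 +
    hess$d / 2 * log(prior_sd^2) + 0.5 * logdet
}

#' Select the number of enterotypes by lowest Laplace score
#'
#' Fits a DMM for each K in `k_range` and returns the full score profile plus
#' the K minimizing the Laplace negative log evidence (ties broken toward the
#' smaller K). Components with negligible weight (< 1e-6) are pruned with a
#' warning and the effective K reported.
#'
#' @inheritParams fit_dmm
#' @param k_range candidate component counts (default 1:7).
#' @return a `dmm_selection`: list with `scores` tibble, `models`, and
#'   `selected_k`.
#' @export
select_k <- function(counts, k_range = 1:7, n_restarts = 3, max_iter = 200,
                     tol = 1e-6, seed = NULL) {
  if (!length(k_range)) abort("k_range must be nonempty")
  k_range <- sort(unique(as.integer(k_range)))
  models <- list()
  scores <- purrr::map_dfr(k_range, function(K) {
    fit <- fit_dmm(counts, K, n_restarts = n_restarts, max_iter = max_iter,
                   tol = tol, seed = if (is.null(seed)) NULL else seed + K)
    keep <- fit$weights > 1e-6
    if (!all(keep)) {
      warn(paste0("pruned ", sum(!keep), " empty component(s) at K = ", K))
      fit$weights <- fit$weights[keep] / sum(fit$weights[keep])
      fit$alpha <- fit$alpha[keep, , drop = FALSE]
      fit$K <- sum(keep)
    }
    fit$laplace <- laplace_score(fit, counts)
    models[[as.character(K)]] <<- fit
    tibble(K = K, effective_K = fit$K, log_likelihood = fit$log_likelihood,
           laplace = fit$laplace, converged = fit$converged)
  })
  selected <- scores$K[which.min(scores$laplace)]
  structure(list(scores = scores, models = models,
                 selected_k = as.integer(selected)),
            class = "dmm_selection")
}

#' @export
print.dmm_selection <- function(x, ...) {
  cat("DMM model selection: K =", x$selected_k, "by lowest Laplace score\n")
  print(as.data.frame(x$scores), row.names = FALSE, digits = 6)
  invisible(x)
}

#' @rdname select_k
#' @param x a `dmm_selection`.
#' @param ... unused.
#' @export
#' @method tidy dmm_selection
tidy.dmm_selection <- function(x, ...) x$scores

#' Assign samples to enterotypes by maximum posterior probability
#'
#' @param model a `dmm_fit`.
#' @param counts raw count table with the model's taxa.
#' @return a tibble with `sample_id`, `map_component`, `max_posterior` and one
#'   `posterior_k` column per component (rows sum to 1).
#' @export
assign_enterotypes <- function(model, counts) {
  X <- count_matrix(counts)
  if (!identical(colnames(X), model$taxa)) {
    abort("counts do not match the model's taxa")
  }
  const <- lgamma(rowSums(X) + 1) - rowSums(lgamma(X + 1))
  L <- vapply(seq_len(model$K), function(k) {
    dm_loglik_rows(X, model$alpha[k, ], const)
  }, numeric(nrow(X)))
  Lw <- sweep(matrix(L, nrow(X), model$K), 2, log(model$weights), "+")
  post <- exp(Lw - row_logsumexp(Lw))
  out <- tibble(
    sample_id = rownames(X),
    map_component = as.integer(apply(post, 1L, which.max)),
    max_posterior = apply(post, 1L, max)
  )
  colnames(post) <- paste0("posterior_", seq_len(model$K))
  dplyr::bind_cols(out, as_tibble(post))
}

#' Enterotype trajectories over age
#'
#' Joins enterotype assignments to metadata and summarizes per-pig
#' age-ordered label sequences, the proportion of samples in each enterotype
#' at each age, and transition counts between consecutive ages.
#'
#' @param assignments output of [assign_enterotypes()].
#' @param metadata metadata tibble covering the assigned samples.
#' @return an `enterotype_trajectories` list: `per_pig`, `proportions`
#'   (summing to 1 within age), `transitions`.
#' @export
enterotype_trajectories <- function(assignments, metadata) {
  md <- validate_metadata(metadata, strict_ages = FALSE)
  joined <- assignments %>%
    select("sample_id", "map_component") %>%
    left_join(md, by = "sample_id") %>%
    arrange(.data$pig_id, .data$age_weeks)
  missing_pigs <- setdiff(unique(md$pig_id[md$microbiome_subset]),
                          unique(joined$pig_id))
  if (length(missing_pigs)) {
    warn(paste0("pig(s) with no assigned samples omitted: ",
                paste(missing_pigs, collapse = ", ")))
  }
  per_pig <- joined %>%
    select("pig_id", "age_weeks", enterotype = "map_component")
  proportions <- per_pig %>%
    group_by(.data$age_weeks, .data$enterotype) %>%
    summarise(n = dplyr::n(), .groups = "drop_last") %>%
    mutate(proportion = .data$n / sum(.data$n)) %>%
    ungroup()
  transitions <- per_pig %>%
    group_by(.data$pig_id) %>%
    arrange(.data$age_weeks, .by_group = TRUE) %>%
    mutate(from = .data$enterotype,
           to = dplyr::lead(.data$enterotype),
           from_age = .data$age_weeks,
           to_age = dplyr::lead(.data$age_weeks)) %>%
    ungroup() %>%
    filter(!is.na(.data$to)) %>%
    dplyr::count(.data$from_age, .data$to_age, .data$from, .data$to, name = "n")
  structure(list(per_pig = per_pig, proportions = proportions,
                 transitions = transitions),
            class = "enterotype_trajectories")
}

#' Best label-matching accuracy between two labelings
#'
#' Mixture labels are identified only up to permutation; this searches all
#' component permutations and returns the highest achievable agreement with
#' the reference labels.
#'
#' @param reference,labels integer label vectors of equal length.
#' @return the best-case proportion of agreeing labels.
#' @export
label_match_accuracy <- function(reference, labels) {
  if (length(reference) != length(labels)) abort("label vectors must align")
  ks <- sort(unique(labels))
  perms <- all_permutations(length(ks))
  best <- 0
  for (row in seq_len(nrow(perms))) {
    mapped <- ks[perms[row, ]][match(labels, ks)]
    best <- max(best, mean(mapped == reference))
  }
  best
}
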