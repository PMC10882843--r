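# Penalized-spline trend models with continuous-time AR(1) errors for log10
# CFU/g plate counts; pointwise first-derivative confidence bands and the
# age windows where they are bounded away from zero; qPCR standardization
# and age models.

# Equally spaced cubic B-spline basis over [lo, hi] (P-spline convention:
# equal knot spacing makes the difference penalty's null space the
# polynomials of degree penalty_order - 1).
pspline_basis <- function(x, lo, hi, n_knots, degree, derivs = 0) {
  inner <- seq(lo, hi, length.out = n_knots)
  h <- if (n_knots > 1) inner[2] - inner[1] else 1
  knots <- c(lo - h * (degree:1), inner, hi + h * (1:degree))
  splines::splineDesign(knots, x, ord = degree + 1,
                        derivs = rep(derivs, length(x)), outer.ok = FALSE)
}

ar1_profile_negll <- function(phi, resid_list, dt_list) {
  # profiled Gaussian -2 loglik (up to constants) of stationary CT-AR(1)
  ss <- 0; logv <- 0; N <- 0
  for (g in seq_along(resid_list)) {
    e <- resid_list[[g]]
    if (!length(e)) next
    v <- 1
    ss <- ss + e[1]^2
    N <- N + length(e)
    if (length(e) > 1) {
      rho <- phi^dt_list[[g]]
      vj <- 1 - rho^2
      ss <- ss + sum((e[-1] - rho * e[-length(e)])^2 / vj)
      logv <- logv + sum(log(vj))
    }
  }
  N * log(ss / N) + logv
}

estimate_ct_ar1 <- function(residuals, pig, age) {
  ord <- order(pig, age)
  e <- residuals[ord]
  if (sd(e) < 1e-10) return(0)
  sp <- split(seq_along(e), pig[ord])
  resid_list <- lapply(sp, function(ii) e[ii])
  dt_list <- lapply(sp, function(ii) diff(age[ord][ii]))
  if (all(lengths(dt_list) == 0)) return(0)
  opt <- optimize(ar1_profile_negll, interval = c(-0.998, 0.998),
                  resid_list = resid_list, dt_list = dt_list)
  opt$minimum
}

# Whitening blocks: per pig, L^-1 with C = L L' and C_jl = phi^|t_j - t_l|.
whiten_by_pig <- function(M, pig, age, phi) {
  out <- M
  for (ii in split(seq_along(pig), pig)) {
    ii <- ii[order(age[ii])]
    C <- phi^abs(outer(age[ii], age[ii], "-"))
    R <- chol(C)
    out[ii, ] <- forwardsolve(t(R), M[ii, , drop = FALSE])
  }
  out
}

#' Penalized-spline trend with continuous-time AR(1) errors
#'
#' Fits `y = f(age) + cohort + error` where `f` is a cubic B-spline on an
#' equally spaced knot grid with a difference penalty (order 2 by default, so
#' heavy smoothing shrinks toward a straight line) and the errors within each
#' pig follow a stationary continuous-time AR(1) with correlation
#' `phi^delta-weeks`. Estimation iterates: penalized fit, profile-likelihood
#' estimate of `phi` from within-pig lagged residuals, generalized
#' least-squares refit on the whitened problem, with the smoothing parameter
#' chosen by GCV on the whitened problem at each pass (tolerance 1e-4 on
#' `phi`, at most 20 passes). The coefficient covariance is
#' `sigma2 (X'X + P)^-1` from the penalized GLS normal equations.
#'
#' @param data data frame of observations; rows with missing outcome
#'   (no-growth plates, left-censored at the detection limit) are dropped.
#' @param outcome,age_col,cohort_col,pig_col column names.
#' @param n_knots,degree,penalty_order spline controls (defaults 9, 3, 2).
#' @param lambda fixed smoothing parameter; `NULL` (default) selects by GCV
#'   over `lambda_grid`.
#' @param lambda_grid candidate smoothing parameters for GCV.
#' @param phi fixed AR(1) correlation per unit week; `NULL` (default)
#'   estimates it by profile likelihood.
#' @return a `trend_fit` with coefficients, covariance, `phi`, `lambda`,
#'   effective degrees of freedom, fitted values and convergence flag.
#' @export
fit_penalized_spline_ar1 <- function(data, outcome = "log10_cfu_per_g",
                                     age_col = "age_weeks",
                                     cohort_col = "cohort",
                                     pig_col = "pig_id",
                                     n_knots = 9, degree = 3,
                                     penalty_order = 2,
                                     lambda = NULL,
                                     lambda_grid = 10^seq(-8, 8, length.out = 45),
                                     phi = NULL) {
  data <- as.data.frame(data)
  keep <- !is.na(data[[outcome]])
  data <- data[keep, , drop = FALSE]
  y <- data[[outcome]]
  age <- data[[age_col]]
  pig <- as.character(data[[pig_col]])
  cohort <- if (!is.null(cohort_col) && cohort_col %in% names(data)) {
    as.factor(data[[cohort_col]])
  } else NULL
  if (length(unique(age)) < 2) abort("ages must span at least 2 distinct values")
  if (length(y) < n_knots + degree + 2) {
    abort("too few observations for the requested basis")
  }
  lo <- min(age); hi <- max(age)
  B <- pspline_basis(age, lo, hi, n_knots, degree)
  nb <- ncol(B)
  Xpar <- if (!is.null(cohort) && nlevels(cohort) > 1) {
    cm <- stats::model.matrix(~cohort)[, -1, drop = FALSE]
    sweep(cm, 2, colMeans(cm))  # centered so the spline carries the intercept
  } else NULL
  X <- cbind(B, Xpar)
  np <- ncol(X)
  D <- diff(diag(nb), differences = penalty_order)
  Pen0 <- matrix(0, np, np)
  Pen0[seq_len(nb), seq_len(nb)] <- crossprod(D)

  fit_at <- function(Xw, yw, lam) {
    A <- crossprod(Xw) + lam * Pen0
    Ainv <- solve(A)
    beta <- Ainv %*% crossprod(Xw, yw)
    fitted_w <- Xw %*% beta
    edf <- sum(Ainv * crossprod(Xw))  # tr[(X'X+P)^-1 X'X]
    list(beta = beta[, 1], Ainv = Ainv, rss = sum((yw - fitted_w)^2), edf = edf)
  }
  select_lambda <- function(Xw, yw) {
    if (!is.null(lambda)) return(lambda)
    n <- length(yw)
    gcv <- vapply(lambda_grid, function(lam) {
      f <- fit_at(Xw, yw, lam)
      denom <- max(n - f$edf, 1e-8)
      n * f$rss / denom^2
    }, numeric(1))
    lambda_grid[which.min(gcv)]
  }

  phi_fixed <- !is.null(phi)
  if (!phi_fixed) phi <- 0
  converged <- FALSE
  lam <- NA_real_
  f <- NULL
  for (pass in seq_len(if (phi_fixed) 1 else 20)) {
    if (phi == 0) {
      Xw <- X; yw <- y
    } else {
      Xw <- whiten_by_pig(X, pig, age, phi)
      yw <- whiten_by_pig(matrix(y), pig, age, phi)[, 1]
    }
    lam <- select_lambda(Xw, yw)
    f <- fit_at(Xw, yw, lam)
    if (phi_fixed) {
      converged <- TRUE
      break
    }
    resid_raw <- y - (X %*% f$beta)[, 1]
    phi_new <- estimate_ct_ar1(resid_raw, pig, age)
    if (abs(phi_new) > 0.999) {
      warn("AR(1) phi estimate clipped to (-0.999, 0.999)")
      phi_new <- sign(phi_new) * 0.999
    }
    if (abs(phi_new - phi) < 1e-4) {
      phi <- phi_new
      converged <- TRUE
      break
    }
    phi <- phi_new
  }
  # final whitened refit at the converged phi
  Xw <- if (phi == 0) X else whiten_by_pig(X, pig, age, phi)
  yw <- if (phi == 0) y else whiten_by_pig(matrix(y), pig, age, phi)[, 1]
  lam <- select_lambda(Xw, yw)
  f <- fit_at(Xw, yw, lam)
  sigma2 <- f$rss / max(length(yw) - f$edf, 1)
  vcov_beta <- sigma2 * f$Ainv
  fitted <- (X %*% f$beta)[, 1]
  structure(list(
    coefficients = f$beta, vcov = vcov_beta, lambda = lam, phi = phi,
    edf = f$edf, sigma2 = sigma2, fitted = fitted, residuals = y - fitted,
    n_obs = length(y), age_range = c(lo, hi), n_knots = n_knots,
    degree = degree, penalty_order = penalty_order, n_basis = nb,
    cohort_levels = if (is.null(cohort)) NULL else levels(cohort),
    converged = converged,
    data = tibble(age = age, y = y, pig = pig)
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "Penalized-spline trend: n = %d | lambda = %.3g | edf = %.2f | AR(1) phi = %.3f%s\n",
    x$n_obs, x$lambda, x$edf, x$phi, if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' @rdname fit_penalized_spline_ar1
#' @param x a `trend_fit`.
#' @param ... unused.
#' @export
#' @method glance trend_fit
glance.trend_fit <- function(x, ...) {
  tibble(lambda = x$lambda, phi = x$phi, edf = x$edf, sigma2 = x$sigma2,
         n_obs = x$n_obs, converged = x$converged)
}

#' Predicted trend on an age grid
#'
#' @param object a `trend_fit`.
#' @param ages age grid within the fitted range.
#' @param level confidence level for the pointwise band.
#' @param ... unused.
#' @return a tibble with `age`, `estimate`, `lower`, `upper`.
#' @export
predict_trend <- function(object, ages, level = 0.95, ...) {
  rng <- object$age_range
  if (any(ages < rng[1] - 1e-9 | ages > rng[2] + 1e-9)) {
    abort("ages outside the fitted range (no extrapolation)")
  }
  B <- pspline_basis(ages, rng[1], rng[2], object$n_knots, object$degree)
  idx <- seq_len(object$n_basis)
  est <- (B %*% object$coefficients[idx])[, 1]
  V <- object$vcov[idx, idx, drop = FALSE]
  se <- sqrt(pmax(rowSums((B %*% V) * B), 0))
  zq <- qnorm(1 - (1 - level) / 2)
  tibble(age = ages, estimate = est, lower = est - zq * se, upper = est + zq * se)
}

#' Pointwise confidence band on the trend's first derivative
#'
#' The derivative is the analytic first derivative of the spline basis times
#' the fitted coefficients; its pointwise variance is the quadratic form with
#' the coefficient covariance, and the band uses the normal quantile at
#' `level` (pointwise, not simultaneous).
#'
#' @param fit a `trend_fit`.
#' @param grid age grid within the fitted range.
#' @param level confidence level (default 0.95).
#' @return a `derivative_band` tibble: `age`, `derivative`, `lower`, `upper`.
#' @export
derivative_band <- function(fit, grid, level = 0.95) {
  rng <- fit$age_range
  if (any(grid < rng[1] - 1e-9 | grid > rng[2] + 1e-9)) {
    abort("grid outside the fitted age range (no extrapolation)")
  }
  Bd <- pspline_basis(grid, rng[1], rng[2], fit$n_knots, fit$degree, derivs = 1)
  idx <- seq_len(fit$n_basis)
  est <- (Bd %*% fit$coefficients[idx])[, 1]
  V <- fit$vcov[idx, idx, drop = FALSE]
  se <- sqrt(pmax(rowSums((Bd %*% V) * Bd), 0))
  zq <- qnorm(1 - (1 - level) / 2)
  out <- tibble(age = grid, derivative = est,
                lower = est - zq * se, upper = est + zq * se)
  class(out) <- c("derivative_band", class(out))
  out
}

#' Windows of significant change
#'
#' Maximal age intervals where the derivative band is bounded away from zero:
#' lower bound positive (increasing) or upper bound negative (decreasing).
#' Window endpoints are interpolated linearly between grid points at the zero
#' crossing of the relevant bound.
#'
#' @param band a [derivative_band()] tibble.
#' @return a tibble with `start_age`, `end_age`, `direction`; zero rows when
#'   the band straddles zero everywhere.
#' @export
significance_windows <- function(band) {
  find_runs <- function(sig, bound) {
    n <- length(sig)
    out <- list()
    i <- 1
    while (i <= n) {
      if (!sig[i]) { i <- i + 1; next }
      j <- i
      while (j < n && sig[j + 1]) j <- j + 1
      start <- band$age[i]
      if (i > 1) {
        b0 <- bound[i - 1]; b1 <- bound[i]
        if (is.finite(b0) && b1 != b0) {
          start <- band$age[i - 1] + (0 - b0) * (band$age[i] - band$age[i - 1]) / (b1 - b0)
        }
      }
      end <- band$age[j]
      if (j < n) {
        b0 <- bound[j]; b1 <- bound[j + 1]
        if (is.finite(b1) && b1 != b0) {
          end <- band$age[j] + (0 - b0) * (band$age[j + 1] - band$age[j]) / (b1 - b0)
        }
      }
      out[[length(out) + 1]] <- c(start, end)
      i <- j + 1
    }
    out
  }
  inc <- find_runs(band$lower > 0, band$lower)
  dec <- find_runs(band$upper < 0, band$upper)
  rows <- c(
    lapply(inc, function(w) tibble(start_age = w[1], end_age = w[2],
                                   direction = "increasing")),
    lapply(dec, function(w) tibble(start_age = w[1], end_age = w[2],
                                   direction = "decreasing"))
  )
  if (!length(rows)) {
    return(tibble(start_age = numeric(0), end_age = numeric(0),
                  direction = character(0)))
  }
  bind_rows(rows) %>% arrange(.data$start_age)
}

#' Standardize qPCR gene copies to the 16S load
#'
#' Per sample and gene, the absolute log10 copies/g and the standardized
#' value `log10(gene copies) - log10(16S copies)` (division by bacterial load
#' on the natural scale). Samples with a missing or zero 16S record are
#' flagged and their standardized value is missing.
#'
#' @param qpcr tibble with `sample_id`, `gene`, `copies_per_g` (including
#'   `16S` rows).
#' @return a tibble: `sample_id`, `gene`, `log10_copies`,
#'   `log10_standardized`, `flag_missing_16s`.
#' @export
standardize_gene_copies <- function(qpcr) {
  required <- c("sample_id", "gene", "copies_per_g")
  if (!all(required %in% names(qpcr))) {
    abort("qpcr table needs sample_id, gene, copies_per_g")
  }
  ssu <- qpcr %>% filter(.data$gene == "16S") %>%
    select("sample_id", ssu_copies = "copies_per_g")
  out <- qpcr %>%
    filter(.data$gene != "16S") %>%
    left_join(ssu, by = "sample_id") %>%
    mutate(
      log10_copies = ifelse(.data$copies_per_g > 0,
                            log10(.data$copies_per_g), NA_real_),
      flag_missing_16s = is.na(.data$ssu_copies) | .data$ssu_copies <= 0,
      log10_standardized = ifelse(.data$flag_missing_16s, NA_real_,
                                  .data$log10_copies - log10(.data$ssu_copies))
    ) %>%
    select("sample_id", "gene", "log10_copies", "log10_standardized",
           "flag_missing_16s")
  out
}

#' Age models for qPCR outcomes
#'
#' Fits [fit_random_intercept_lmm()] with age as categorical contrasts (plus
#' cohort) for each gene and each outcome type (absolute and 16S-standardized
#' log10 copies), mirroring the mixed-model treatment of gene-copy outcomes;
#' smooth-trend models are reserved for the plate-count outcomes.
#'
#' @param qpcr tibble as in [standardize_gene_copies()].
#' @param metadata metadata tibble.
#' @return a tibble of tidied fixed effects with `gene`, `outcome_type`,
#'   `term`, `estimate`, `std_error`, `p_value`; fits attached as attribute
#'   `fits`.
#' @export
qpcr_age_models <- function(qpcr, metadata) {
  md <- validate_metadata(metadata, strict_ages = FALSE)
  std <- standardize_gene_copies(qpcr) %>%
    left_join(select(md, "sample_id", "pig_id", "cohort", "age_weeks"),
              by = "sample_id") %>%
    mutate(age_factor = factor(.data$age_weeks))
  fits <- list()
  rows <- purrr::map_dfr(unique(std$gene), function(g) {
    purrr::map_dfr(c(absolute = "log10_copies",
                     standardized = "log10_standardized"), function(col) {
      dat <- std %>% filter(.data$gene == g, !is.na(.data[[col]]))
      fit <- fit_random_intercept_lmm(dat, col, c("age_factor", "cohort"),
                                      "pig_id")
      fits[[paste(g, col, sep = "_")]] <<- fit
      fit$coefficients %>%
        mutate(gene = g,
               outcome_type = if (col == "log10_copies") "absolute"
                              else "standardized") %>%
        select("gene", "outcome_type", "term", "estimate", "std_error",
               "p_value")
    })
  })
  attr(rows, "fits") <- fits
  rows
}
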