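# Random-intercept linear mixed models by profiled REML, Benjamini-Hochberg
# adjustment, and the per-genus differential-abundance scan.

#' Random-intercept linear mixed model by profiled REML
#'
#' Fits `y = X beta + b[group] + e` with `b ~ N(0, sigma2_b)` and
#' `e ~ N(0, sigma2_e)` by profiling the variance ratio
#' `lambda = sigma2_b / sigma2_e` with one-dimensional bounded optimization of
#' the REML criterion (closed-form per-group inverses make each evaluation
#' O(n)); fixed effects are the GLS estimates at the optimum, with Wald tests
#' against the normal reference. A ratio driven to the lower boundary is
#' reported via `boundary = TRUE` and refitted at exactly `lambda = 0`
#' (ordinary least squares).
#'
#' @param data data frame containing the model variables.
#' @param outcome name of the response column.
#' @param fixed character vector of fixed-effect column names (numeric
#'   columns enter linearly, others as factor contrasts).
#' @param group name of the grouping column for the random intercept.
#' @return an `ri_lmm` object; [tidy()] gives the coefficient table and
#'   [glance()] the variance components.
#' @export
fit_random_intercept_lmm <- function(data, outcome, fixed, group) {
  data <- as.data.frame(data)
  vars <- c(outcome, fixed, group)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    abort(paste0("missing column(s): ", paste(missing_vars, collapse = ", ")))
  }
  data <- data[stats::complete.cases(data[, vars]), , drop = FALSE]
  y <- data[[outcome]]
  X <- stats::model.matrix(stats::reformulate(fixed), data)
  g <- as.factor(data[[group]])
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) abort("need more observations than fixed effects")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    abort(paste0("singular fixed-effect design; drop: ", paste(bad, collapse = ", ")))
  }

  idx <- split(seq_len(n), g)
  sizes <- vapply(idx, length, integer(1))

  crossprods <- function(lambda) {
    XtVX <- matrix(0, p, p)
    XtVy <- numeric(p)
    ytVy <- 0
    for (b in seq_along(idx)) {
      ii <- idx[[b]]
      Xg <- X[ii, , drop = FALSE]
      yg <- y[ii]
      cg <- lambda / (1 + lambda * sizes[b])
      sx <- colSums(Xg)
      sy <- sum(yg)
      XtVX <- XtVX + crossprod(Xg) - cg * tcrossprod(sx)
      XtVy <- XtVy + crossprod(Xg, yg)[, 1] - cg * sx * sy
      ytVy <- ytVy + sum(yg^2) - cg * sy^2
    }
    list(XtVX = XtVX, XtVy = XtVy, ytVy = ytVy)
  }

  reml_crit <- function(loglambda) {
    lambda <- exp(loglambda)
    cp <- crossprods(lambda)
    beta <- solve(cp$XtVX, cp$XtVy)
    rss <- max(cp$ytVy - sum(beta * cp$XtVy), 1e-300)
    sum(log1p(lambda * sizes)) +
      determinant(cp$XtVX, logarithm = TRUE)$modulus[1] +
      (n - p) * log(rss / (n - p))
  }

  opt <- optimize(reml_crit, interval = c(-15, 15))
  boundary <- opt$minimum < -12 || reml_crit(-15) <= opt$objective + 1e-10
  lambda <- if (boundary) 0 else exp(opt$minimum)

  cp <- crossprods(lambda)
  beta <- solve(cp$XtVX, cp$XtVy)
  rss <- max(cp$ytVy - sum(beta * cp$XtVy), 0)
  sigma2 <- rss / (n - p)
  vcov_beta <- sigma2 * solve(cp$XtVX)
  se <- sqrt(diag(vcov_beta))
  z <- beta / se
  coefs <- tibble(
    term = colnames(X),
    estimate = unname(beta),
    std_error = unname(se),
    statistic = unname(z),
    p_value = 2 * stats::pnorm(-abs(unname(z)))
  )
  structure(list(
    coefficients = coefs, vcov = vcov_beta,
    sigma2_between = lambda * sigma2, sigma2_resid = sigma2,
    lambda = lambda, boundary = boundary,
    reml_criterion = if (boundary) reml_crit(-300) else opt$objective,
    n_obs = n, n_groups = length(idx),
    outcome = outcome, fixed = fixed, group = group
  ), class = "ri_lmm")
}

#' @export
print.ri_lmm <- function(x, ...) {
  cat("Random-intercept LMM (REML):", x$outcome, "~",
      paste(x$fixed, collapse = " + "), "+ (1 |", x$group, ")\n")
  cat(sprintf("  n = %d obs, %d groups | var(intercept) = %.4g, var(resid) = %.4g%s\n",
              x$n_obs, x$n_groups, x$sigma2_between, x$sigma2_resid,
              if (x$boundary) " [boundary]" else ""))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname fit_random_intercept_lmm
#' @param x an `ri_lmm`.
#' @param ... unused.
#' @export
#' @method tidy ri_lmm
tidy.ri_lmm <- function(x, ...) x$coefficients

#' @rdname fit_random_intercept_lmm
#' @export
#' @method glance ri_lmm
glance.ri_lmm <- function(x, ...) {
  tibble(sigma2_between = x$sigma2_between, sigma2_resid = x$sigma2_resid,
         lambda = x$lambda, boundary = x$boundary,
         reml_criterion = x$reml_criterion,
         n_obs = x$n_obs, n_groups = x$n_groups)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' The monotone step-up adjustment
#' `q_(i) = min_{j >= i} p_(j) * m / j` over the sorted p-values.
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Per-genus differential-abundance scan over age
#'
#' For each genus passing the mean relative-abundance filter, fits a
#' random-intercept LMM of `log(normalized value + pseudo)` on age and cohort
#' with a per-pig random intercept, where `pseudo` is half the genus's
#' smallest nonzero normalized value. Age p-values are BH-adjusted across
#' genera; a genus is called increased or decreased by the sign of its age
#' coefficient when `p < alpha_p` and `q < alpha_q`, else `ns`.
#'
#' @param norm_counts normalized count-table tibble (see [css_normalize()]).
#' @param metadata metadata tibble with `pig_id`, `cohort`, `age_weeks`.
#' @param min_mean_ra minimum mean relative abundance (default 1e-4, i.e.
#'   0.01%).
#' @param alpha_p,alpha_q significance and FDR thresholds (defaults 0.05 and
#'   0.25).
#' @param age_col,cohort_col,group_col metadata column names.
#' @return a tibble with one row per tested genus: `genus`, `estimate` (age
#'   slope per week on the log scale), `std_error`, `p_value`, `q_value`,
#'   `trend`, `prevalence`, `mean_relative_abundance`.
#' @export
differential_abundance_scan <- function(norm_counts, metadata,
                                        min_mean_ra = 1e-4,
                                        alpha_p = 0.05, alpha_q = 0.25,
                                        age_col = "age_weeks",
                                        cohort_col = "cohort",
                                        group_col = "pig_id") {
  md <- validate_metadata(metadata, strict_ages = FALSE)
  m <- as.matrix(norm_counts[, -1, drop = FALSE])
  rownames(m) <- as.character(norm_counts$sample_id)
  m <- m[rownames(m) %in% md$sample_id, , drop = FALSE]
  info <- md[match(rownames(m), md$sample_id), ]
  ra <- m / pmax(rowSums(m), 1e-300)
  keep <- colMeans(ra) >= min_mean_ra
  genera <- colnames(m)[keep]
  skipped <- character(0)
  rows <- purrr::map_dfr(genera, function(gn) {
    v <- m[, gn]
    nz <- v[v > 0]
    if (!length(nz)) {
      skipped <<- c(skipped, gn)
      return(NULL)
    }
    yv <- log(v + min(nz) / 2)
    if (sd(yv) < 1e-12) {
      skipped <<- c(skipped, gn)
      return(NULL)
    }
    dat <- data.frame(y = yv, age = info[[age_col]],
                      cohort = as.factor(info[[cohort_col]]),
                      pig = info[[group_col]])
    fit <- fit_random_intercept_lmm(dat, "y", c("age", "cohort"), "pig")
    co <- fit$coefficients[fit$coefficients$term == "age", ]
    tibble(genus = gn, estimate = co$estimate, std_error = co$std_error,
           p_value = co$p_value,
           prevalence = mean(v > 0),
           mean_relative_abundance = mean(ra[, gn]))
  })
  if (length(skipped)) {
    warn(paste0("genus constant after transform skipped: ",
                paste(skipped, collapse = ", ")))
  }
  rows$q_value <- bh_adjust(rows$p_value)
  rows$trend <- dplyr::case_when(
    rows$p_value < alpha_p & rows$q_value < alpha_q & rows$estimate > 0 ~ "increased",
    rows$p_value < alpha_p & rows$q_value < alpha_q & rows$estimate < 0 ~ "decreased",
    TRUE ~ "ns"
  )
  rows %>% select("genus", "estimate", "std_error", "p_value", "q_value",
                  "trend", "prevalence", "mean_relative_abundance")
}
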