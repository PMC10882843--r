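# Permutational multivariate ANOVA on a dissimilarity matrix, with sequential
# (Type-I) sums of squares, optional within-strata permutations for repeated
# measures, and exact enumeration of the permutation null when feasible.

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# All label permutations, each row one permutation of 1..n; with strata,
# indices are permuted within strata only.
enumerate_permutations <- function(n, strata = NULL, limit = 300000) {
  if (is.null(strata)) {
    if (factorial(n) > limit) abort("too many permutations to enumerate")
    return(all_permutations(n))
  }
  idx <- split(seq_len(n), strata)
  sizes <- vapply(idx, length, integer(1))
  if (prod(factorial(sizes)) > limit) abort("too many permutations to enumerate")
  block_perms <- lapply(idx, function(ii) {
    matrix(ii[all_permutations(length(ii))], ncol = length(ii))
  })
  out <- matrix(seq_len(n), 1, n)
  for (b in seq_along(idx)) {
    bp <- block_perms[[b]]
    out <- out[rep(seq_len(nrow(out)), each = nrow(bp)), , drop = FALSE]
    out[, idx[[b]]] <- bp[rep_len(seq_len(nrow(bp)), nrow(out)), , drop = FALSE]
  }
  out
}

random_permutation <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  p <- seq_len(n)
  for (ii in split(seq_len(n), strata)) {
    p[ii] <- ii[sample.int(length(ii))]
  }
  p
}

#' PERMANOVA with sequential sums of squares and restricted permutations
#'
#' Partitions the Gower-centered inner-product matrix derived from a
#' dissimilarity matrix over model terms in the order given (Type-I), forms a
#' pseudo-F per term, and obtains p-values by permuting sample labels --
#' within levels of `strata` when given, which accounts for repeated sampling
#' of the same subject. P-values use the +1 correction
#' `(1 + #permuted F >= observed F) / (1 + n_permutations)`; with
#' `complete = TRUE` the null is enumerated exhaustively and the p-value is
#' the exact proportion over all permutations (identity included).
#'
#' @param dist a `dist` object.
#' @param data data frame of covariates; rows are matched to the `dist`
#'   labels via the `sample_id` column when present, else taken in order.
#' @param terms character vector of column names, fitted sequentially.
#' @param strata optional column name whose levels restrict permutations.
#' @param n_permutations number of random permutations (default 10000).
#' @param seed optional integer seed for the permutations.
#' @param complete enumerate all (restricted) permutations instead.
#' @return a `permanova_fit`: tidy with [tidy()] for the per-term table
#'   (`term`, `df`, `sum_sq`, `r_squared`, `pseudo_f`, `p_value`, plus
#'   residual and total rows).
#' @export
permanova <- function(dist, data, terms, strata = NULL,
                      n_permutations = 10000, seed = NULL, complete = FALSE) {
  ids <- attr(dist, "Labels")
  n <- attr(dist, "Size")
  data <- as.data.frame(data)
  if (!is.null(ids) && "sample_id" %in% names(data)) {
    data <- data[match(ids, data$sample_id), , drop = FALSE]
    if (anyNA(data$sample_id)) abort("data must cover every sample in dist")
  }
  if (nrow(data) != n) abort("data rows must align with dist samples")
  missing_terms <- setdiff(c(terms, strata), names(data))
  if (length(missing_terms)) {
    abort(paste0("missing column(s): ", paste(missing_terms, collapse = ", ")))
  }

  D <- as.matrix(dist)
  G <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% G %*% J

  # sequential projection (hat) matrices
  X <- matrix(1, n, 1)
  hats <- list(X %*% solve(crossprod(X), t(X)))
  dfs <- integer(length(terms))
  for (k in seq_along(terms)) {
    v <- data[[terms[k]]]
    mm <- if (is.numeric(v)) matrix(v, ncol = 1) else {
      stats::model.matrix(~ f - 1, data.frame(f = as.factor(v)))
    }
    X <- cbind(X, mm)
    qrX <- qr(X)
    dfs[k] <- qrX$rank - sum(dfs) - 1L
    if (dfs[k] < 1) abort(paste0("term '", terms[k], "' adds no degrees of freedom"))
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    hats[[k + 1]] <- tcrossprod(Q)
  }
  rank_full <- sum(dfs) + 1L
  df_res <- n - rank_full
  if (df_res < 1) abort("more model terms than residual degrees of freedom")

  strata_vec <- if (is.null(strata)) NULL else as.factor(data[[strata]])
  ss_total <- sum(diag(G))

  term_stats <- function(perm) {
    Gp <- G[perm, perm]
    ss <- vapply(seq_along(terms), function(k) {
      sum(hats[[k + 1]] * Gp) - sum(hats[[k]] * Gp)
    }, numeric(1))
    ss_res <- ss_total - sum(ss)
    ms_res <- ss_res / df_res
    if (abs(ms_res) < 1e-12) {
      # 0/0 pseudo-F on degenerate inputs is guarded to 0
      f <- ifelse(ss / dfs > 1e-12, Inf, 0)
    } else {
      f <- (ss / dfs) / ms_res
    }
    list(ss = ss, f = f)
  }

  obs <- term_stats(seq_len(n))
  degenerate <- abs(ss_total) < 1e-12

  if (degenerate) {
    pvals <- rep(1, length(terms))
    nperm_used <- 0L
  } else if (complete) {
    perms <- enumerate_permutations(n, strata_vec)
    fmat <- vapply(seq_len(nrow(perms)), function(r) {
      term_stats(perms[r, ])$f
    }, numeric(length(terms)))
    fmat <- matrix(fmat, nrow = length(terms))
    pvals <- vapply(seq_along(terms), function(k) {
      mean(fmat[k, ] >= obs$f[k] - 1e-12)
    }, numeric(1))
    nperm_used <- nrow(perms)
  } else {
    if (!is.null(seed)) {
      run <- function(expr) with_seed(seed, expr)
    } else {
      run <- identity
    }
    exceed <- run({
      ex <- numeric(length(terms))
      for (b in seq_len(n_permutations)) {
        f <- term_stats(random_permutation(n, strata_vec))$f
        ex <- ex + (f >= obs$f - 1e-12)
      }
      ex
    })
    pvals <- (1 + exceed) / (1 + n_permutations)
    nperm_used <- n_permutations
  }

  ss_res <- ss_total - sum(obs$ss)
  tab <- tibble(
    term = c(terms, "residual", "total"),
    df = c(dfs, df_res, n - 1L),
    sum_sq = c(obs$ss, ss_res, ss_total),
    r_squared = if (degenerate) c(rep(0, length(terms)), 0, 1) else
      c(obs$ss, ss_res, ss_total) / ss_total,
    pseudo_f = c(obs$f, NA, NA),
    p_value = c(pvals, NA, NA)
  )
  structure(list(table = tab, n_permutations = nperm_used,
                 strata = strata, complete = complete),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat("PERMANOVA (sequential SS,", x$n_permutations, "permutations",
      if (!is.null(x$strata)) paste0("within strata '", x$strata, "'"), ")\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname permanova
#' @param x a `permanova_fit`.
#' @param ... unused.
#' @export
#' @method tidy permanova_fit
tidy.permanova_fit <- function(x, ...) x$table

#' Pairwise PERMANOVA between group levels
#'
#' Runs [permanova()] on every pair of group levels and adjusts the p-values
#' across pairs with [bh_adjust()].
#'
#' @inheritParams permanova
#' @param group column of `data` defining the groups to compare pairwise.
#' @return a tibble with one row per pair: `group1`, `group2`, `r_squared`,
#'   `pseudo_f`, `p_value`, `q_value`.
#' @export
pairwise_permanova <- function(dist, data, group, strata = NULL,
                               n_permutations = 999, seed = NULL) {
  data <- as.data.frame(data)
  ids <- attr(dist, "Labels")
  if (!is.null(ids) && "sample_id" %in% names(data)) {
    data <- data[match(ids, data$sample_id), , drop = FALSE]
  }
  levs <- sort(unique(as.character(data[[group]])))
  if (length(levs) < 2) abort("need at least 2 group levels")
  D <- as.matrix(dist)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- purrr::map_dfr(seq_along(pairs), function(j) {
    pr <- pairs[[j]]
    keep <- data[[group]] %in% pr
    sub <- stats::as.dist(D[keep, keep, drop = FALSE])
    fit <- permanova(sub, data[keep, , drop = FALSE], terms = group,
                     strata = strata, n_permutations = n_permutations,
                     seed = if (is.null(seed)) NULL else seed + j)
    row <- fit$table[1, ]
    tibble(group1 = pr[1], group2 = pr[2], r_squared = row$r_squared,
           pseudo_f = row$pseudo_f, p_value = row$p_value)
  })
  rows$q_value <- bh_adjust(rows$p_value)
  rows
}
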