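# Normalization, alpha/beta diversity and shared-feature turnover.

#' Cumulative sum scaling (CSS) normalization
#'
#' Each sample's counts are divided by its cumulative sum up to a quantile and
#' multiplied by a fixed scale constant: the scaling factor of a sample is the
#' sum of its counts that are less than or equal to its own quantile-`q`
#' nonzero count. This damps the influence of a few very abundant features
#' when sequencing depth differs across samples.
#'
#' @param counts a count-table tibble.
#' @param quantile quantile in (0, 1) defining the cumulative sum; default 0.5
#'   (the per-sample median of nonzero counts).
#' @param scale_constant value the normalized counts are rescaled by
#'   (default 1000).
#' @return a tibble shaped like `counts` with normalized values; per-sample
#'   scaling factors are attached as attribute `scaling_factors` and the
#'   constant as `scale_constant`.
#' @export
#' @examples
#' tbl <- tibble::tibble(sample_id = "S1", a = 10, b = 10, c = 10, d = 10)
#' css_normalize(tbl)  # all cells 250: factor 40, constant 1000
css_normalize <- function(counts, quantile = 0.5, scale_constant = 1000) {
  validate_count_table(counts)
  if (quantile <= 0 || quantile >= 1) abort("quantile must lie in (0, 1)")
  m <- count_matrix(counts)
  factors <- vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    nz <- x[x > 0]
    if (!length(nz)) {
      abort(paste0("sample '", rownames(m)[i], "' has no nonzero counts"))
    }
    qv <- stats::quantile(nz, probs = quantile, names = FALSE)
    sum(x[x <= qv])
  }, numeric(1))
  norm <- m / factors * scale_constant
  out <- matrix_to_count_table(norm)
  attr(out, "scaling_factors") <- setNames(factors, rownames(m))
  attr(out, "scale_constant") <- scale_constant
  out
}

#' Alpha diversity
#'
#' Richness (features with nonzero count) and Shannon diversity (natural log)
#' per sample. An all-zero sample gets richness 0 and Shannon 0 by convention.
#'
#' @param counts a count-table tibble (raw or normalized).
#' @return a tibble with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(counts) {
  validate_count_table(counts)
  m <- count_matrix(counts)
  shannon <- apply(m, 1L, function(x) {
    s <- sum(x)
    if (s == 0) return(0)
    p <- x[x > 0] / s
    -sum(p * log(p))
  })
  tibble(
    sample_id = rownames(m),
    richness = as.integer(rowSums(m > 0)),
    shannon = unname(shannon)
  )
}

#' Bray-Curtis dissimilarity
#'
#' `d(a, b) = sum |a_i - b_i| / sum (a_i + b_i)` between per-sample abundance
#' vectors; 0 for identical samples, 1 for disjoint supports.
#'
#' @param table a count-table tibble (raw or normalized values).
#' @return a `dist` object labeled with the sample ids.
#' @export
bray_curtis <- function(table) {
  if (names(table)[1] != "sample_id") {
    abort("expected a table whose first column is `sample_id`")
  }
  m <- as.matrix(table[, -1, drop = FALSE])
  rownames(m) <- as.character(table$sample_id)
  if (nrow(m) < 2) abort("need at least 2 samples")
  if (any(m < 0)) abort("abundances must be nonnegative")
  zero <- rowSums(m) == 0
  if (sum(zero) >= 2) {
    abort(paste0("dissimilarity undefined between all-zero samples: ",
                 paste(rownames(m)[zero], collapse = ", ")))
  }
  vegan::vegdist(m, method = "bray")
}

#' Beta-dispersion: distance to group centroid
#'
#' Embeds the dissimilarity matrix by principal coordinates and measures each
#' sample's distance to its group centroid, with the standard
#' negative-eigenvalue correction (imaginary-axis contributions are
#' subtracted, floored at zero). A singleton group has dispersion 0.
#'
#' @param dist a `dist` object.
#' @param groups vector of group labels aligned with the `dist` labels, or a
#'   data frame with `sample_id` and `group` columns.
#' @return a tibble with per-sample `sample_id`, `group`,
#'   `distance_to_centroid`; per-group means are attached as attribute
#'   `group_means`.
#' @export
beta_dispersion <- function(dist, groups) {
  ids <- attr(dist, "Labels")
  if (is.data.frame(groups)) {
    groups <- setNames(groups$group, groups$sample_id)[ids]
  }
  if (length(groups) != attr(dist, "Size")) {
    abort("groups must label every sample in the distance matrix")
  }
  if (anyNA(groups)) abort("every sample must have a group label")
  bd <- vegan::betadisper(dist, group = as.factor(groups), type = "centroid")
  out <- tibble(
    sample_id = if (is.null(ids)) as.character(seq_along(groups)) else ids,
    group = as.character(groups),
    distance_to_centroid = unname(bd$distances)
  )
  attr(out, "group_means") <- out %>%
    group_by(.data$group) %>%
    summarise(mean_dispersion = mean(.data$distance_to_centroid), .groups = "drop")
  out
}

#' Shared and unique features across groups
#'
#' A feature is present in a group when it has a nonzero count in at least
#' `min_samples` of the group's samples. Returns the number of features in
#' every nonempty presence combination (upset-style: features present in
#' exactly that set of groups), plus per-group totals and the all-groups
#' intersection.
#'
#' @param counts a count-table tibble.
#' @param groups vector of group labels aligned with rows of `counts`, or a
#'   data frame with `sample_id` and `group` columns.
#' @param min_samples presence rule (default 1 sample).
#' @return a list: `combinations` (tibble of `groups` label string, `n`),
#'   `totals` (features present per group), `all_groups_intersection`.
#' @export
shared_features <- function(counts, groups, min_samples = 1) {
  validate_count_table(counts)
  m <- count_matrix(counts)
  if (is.data.frame(groups)) {
    groups <- setNames(groups$group, groups$sample_id)[rownames(m)]
  }
  if (length(groups) != nrow(m) || anyNA(groups)) {
    abort("groups must cover all samples")
  }
  levs <- unique(as.character(groups))
  presence <- vapply(levs, function(g) {
    colSums(m[groups == g, , drop = FALSE] > 0) >= min_samples
  }, logical(ncol(m)))  # taxa x groups
  key <- apply(presence, 1L, function(z) paste(levs[z], collapse = "&"))
  key <- key[key != ""]
  combos <- tibble(groups = names(table(key)), n = as.integer(table(key))) %>%
    arrange(dplyr::desc(.data$n))
  list(
    combinations = combos,
    totals = tibble(group = levs, n = as.integer(colSums(presence))),
    all_groups_intersection = as.integer(sum(rowSums(presence) == length(levs)))
  )
}
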