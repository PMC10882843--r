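# Microbiome maturation score: per-pig genus first-appearance ranking,
# concordance across pigs via Kendall's W with a permutation test, a
# median-rank consensus order, and presence-weighted per-sample scores.

#' Genus first-appearance rank matrix
#'
#' For each pig, a genus "appears" at the earliest age where its within-sample
#' relative abundance exceeds `ra_threshold` (default 0.5%). Genera are then
#' ranked within the pig by first-appearance age, ties receiving midranks.
#' Genera that never appear for a pig are missing for that pig.
#'
#' @param counts genus-level count-table tibble.
#' @param metadata metadata tibble with `pig_id` and `age_weeks`.
#' @param ra_threshold relative-abundance presence threshold (default 0.005).
#' @return a pigs x genera numeric matrix of midranks, `NA` where a genus
#'   never appears; first-appearance ages attached as attribute `first_age`.
#' @export
first_appearance_ranks <- function(counts, metadata, ra_threshold = 0.005) {
  validate_count_table(counts)
  md <- validate_metadata(metadata, strict_ages = FALSE)
  m <- count_matrix(counts)
  keep <- rownames(m) %in% md$sample_id
  m <- m[keep, , drop = FALSE]
  ra <- m / pmax(1, rowSums(m))
  info <- md[match(rownames(m), md$sample_id), ]
  pigs <- sort(unique(info$pig_id))
  n_ages <- table(info$pig_id)
  if (any(n_ages < 2)) {
    abort("each pig needs at least 2 age points for first-appearance ranking")
  }
  first_age <- matrix(NA_real_, length(pigs), ncol(m),
                      dimnames = list(pigs, colnames(m)))
  for (p in pigs) {
    rows <- which(info$pig_id == p)
    rows <- rows[order(info$age_weeks[rows])]
    present <- ra[rows, , drop = FALSE] > ra_threshold
    idx <- apply(present, 2L, function(z) if (any(z)) which(z)[1] else NA_integer_)
    first_age[p, ] <- info$age_weeks[rows][idx]
  }
  empty_pigs <- rownames(first_age)[rowSums(!is.na(first_age)) == 0]
  if (length(empty_pigs)) {
    warn(paste0("pig(s) with no qualifying genus excluded: ",
                paste(empty_pigs, collapse = ", ")))
    first_age <- first_age[!rownames(first_age) %in% empty_pigs, , drop = FALSE]
  }
  ranks <- t(apply(first_age, 1L, function(a) {
    r <- rep(NA_real_, length(a))
    ok <- !is.na(a)
    r[ok] <- rank(a[ok], ties.method = "average")
    r
  }))
  dimnames(ranks) <- dimnames(first_age)
  attr(ranks, "first_age") <- first_age
  ranks
}

kendall_w_stat <- function(R) {
  # R: complete m x n rank matrix (m judges/pigs, n items/genera)
  m <- nrow(R)
  n <- ncol(R)
  Rj <- colSums(R)
  S <- sum((Rj - mean(Rj))^2)
  Tsum <- sum(apply(R, 1L, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * Tsum
  if (denom <= 0) return(NA_real_)
  12 * S / denom
}

#' Kendall's coefficient of concordance with a permutation test
#'
#' Computes W with the standard tie correction on the complete-case submatrix
#' (columns ranked by every row) and a permutation p-value under the null of
#' no concordance, permuting each row's ranks independently:
#' `p = (1 + #permuted W >= W) / (1 + n_permutations)`. With `exact = TRUE`
#' all within-row permutations are enumerated and the p-value is the exact
#' proportion.
#'
#' @param rank_matrix pigs x genera rank matrix (may contain `NA`).
#' @param n_permutations number of permutations (default 10000).
#' @param seed optional integer seed.
#' @param exact enumerate all `(n!)^m` within-row permutations (feasible only
#'   for tiny matrices).
#' @return a list with `statistic` (W), `p_value`, `n_permutations`,
#'   `n_pigs`, `n_genera`.
#' @export
kendalls_w <- function(rank_matrix, n_permutations = 10000, seed = NULL,
                       exact = FALSE) {
  cc <- rank_matrix[, colSums(is.na(rank_matrix)) == 0, drop = FALSE]
  if (nrow(cc) < 2 || ncol(cc) < 2) {
    abort("need at least 2 pigs and 2 complete-case genera")
  }
  # re-rank rows so the complete-case submatrix is itself a ranking
  R <- t(apply(cc, 1L, rank, ties.method = "average"))
  W <- kendall_w_stat(R)
  m <- nrow(R)
  n <- ncol(R)
  if (exact) {
    if (factorial(n)^m > 2e6) abort("exact enumeration infeasible for this size")
    perms <- all_permutations(n)
    grid_idx <- rep(list(seq_len(nrow(perms))), m)
    combos <- as.matrix(expand.grid(grid_idx))
    ws <- apply(combos, 1L, function(rowsel) {
      Rp <- R
      for (i in seq_len(m)) Rp[i, ] <- R[i, perms[rowsel[i], ]]
      kendall_w_stat(Rp)
    })
    p <- mean(ws >= W - 1e-12)
    nperm <- nrow(combos)
  } else {
    perm_w <- function() {
      Rp <- t(apply(R, 1L, sample))
      kendall_w_stat(Rp)
    }
    ws <- if (is.null(seed)) {
      replicate(n_permutations, perm_w())
    } else {
      with_seed(seed, replicate(n_permutations, perm_w()))
    }
    p <- (1 + sum(ws >= W - 1e-12)) / (1 + n_permutations)
    nperm <- n_permutations
  }
  list(statistic = W, p_value = p, n_permutations = nperm,
       n_pigs = m, n_genera = n)
}

#' Consensus genus order from median first-appearance ranks
#'
#' Orders genera by the median of their within-pig first-appearance ranks
#' (missing entries ignored; ties broken alphabetically by genus id), and
#' attaches Kendall's W and its permutation p-value as the concordance of the
#' pigs' rankings.
#'
#' @inheritParams kendalls_w
#' @return a `consensus_ranking`: tibble with `genus`, `median_rank`,
#'   `consensus_rank` (1..G), `n_pigs_ranked`, with attributes `kendalls_w`,
#'   `p_value`, `n_permutations`.
#' @export
consensus_order <- function(rank_matrix, n_permutations = 10000, seed = NULL) {
  all_missing <- colSums(!is.na(rank_matrix)) == 0
  if (any(all_missing)) {
    warn(paste0("genus absent from all pigs excluded: ",
                paste(colnames(rank_matrix)[all_missing], collapse = ", ")))
    rank_matrix <- rank_matrix[, !all_missing, drop = FALSE]
  }
  med <- apply(rank_matrix, 2L, median, na.rm = TRUE)
  ord <- order(med, colnames(rank_matrix))
  out <- tibble(
    genus = colnames(rank_matrix)[ord],
    median_rank = unname(med[ord]),
    consensus_rank = seq_along(ord),
    n_pigs_ranked = unname(colSums(!is.na(rank_matrix))[ord])
  )
  kw <- kendalls_w(rank_matrix, n_permutations = n_permutations, seed = seed)
  attr(out, "kendalls_w") <- kw$statistic
  attr(out, "p_value") <- kw$p_value
  attr(out, "n_permutations") <- kw$n_permutations
  class(out) <- c("consensus_ranking", class(out))
  out
}

#' Per-sample microbiome maturation scores
#'
#' A sample's score is the mean consensus rank of the genera present in it
#' (relative abundance above `ra_threshold`, presence weighted 0/1). Samples
#' dominated by early-appearing (low-rank) genera score low; samples carrying
#' late-appearing genera score high, so the score increases as the community
#' matures. With `abundance_weighted = TRUE` the ranks are weighted by
#' relative abundance instead (non-default variant).
#'
#' @param consensus a `consensus_ranking` from [consensus_order()].
#' @param counts genus-level count-table tibble.
#' @param metadata metadata tibble (used to attach pig and age).
#' @param ra_threshold presence threshold (default 0.005).
#' @param abundance_weighted weight ranks by relative abundance instead of
#'   presence.
#' @return a tibble with `sample_id`, `pig_id`, `age_weeks`, `score`,
#'   `n_present_genera`; samples with no present consensus genus get `NA`
#'   score.
#' @export
maturation_scores <- function(consensus, counts, metadata,
                              ra_threshold = 0.005,
                              abundance_weighted = FALSE) {
  validate_count_table(counts)
  md <- validate_metadata(metadata, strict_ages = FALSE)
  m <- count_matrix(counts)
  genera <- intersect(consensus$genus, colnames(m))
  ranks <- setNames(consensus$consensus_rank, consensus$genus)[genera]
  ra <- m[, genera, drop = FALSE] / pmax(1, rowSums(m))
  score <- vapply(seq_len(nrow(ra)), function(i) {
    w <- if (abundance_weighted) {
      ifelse(ra[i, ] > ra_threshold, ra[i, ], 0)
    } else {
      as.numeric(ra[i, ] > ra_threshold)
    }
    if (sum(w) == 0) return(NA_real_)
    sum(w * ranks) / sum(w)
  }, numeric(1))
  n_present <- rowSums(ra > ra_threshold)
  out <- tibble(sample_id = rownames(m), score = score,
                n_present_genera = as.integer(n_present)) %>%
    left_join(select(md, "sample_id", "pig_id", "age_weeks", "stage"),
              by = "sample_id") %>%
    select("sample_id", "pig_id", "age_weeks", "stage", "score",
           "n_present_genera")
  if (anyNA(out$score)) {
    warn(paste0(sum(is.na(out$score)),
                " sample(s) with no present consensus genus: score missing"))
  }
  out
}
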