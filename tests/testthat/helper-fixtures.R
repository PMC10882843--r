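# Shared fixture builders: everything is generated in code at test time.

make_count_table <- function(m, ids = NULL) {
  if (!is.null(ids)) {
    rownames(m) <- ids
  } else if (is.null(rownames(m))) {
    rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  }
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(as.data.frame(m))
  )
}

random_count_table <- function(n_samples, n_taxa, lambda = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa)
  colnames(m) <- sprintf("t%02d", seq_len(n_taxa))
  make_count_table(m)
}

toy_metadata <- function(pigs = 2, ages = c(3, 6, 10)) {
  grid <- expand.grid(pig_id = sprintf("P%d", seq_len(pigs)),
                      age_weeks = ages, stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = sprintf("%s_w%02d", grid$pig_id, grid$age_weeks),
    pig_id = grid$pig_id,
    cohort = ifelse(as.integer(sub("P", "", grid$pig_id)) %% 2 == 0, 2, 1),
    age_weeks = grid$age_weeks
  )
}

# A small cohort configuration for fast unit tests (the defaults encode the
# full study design and are exercised in the acceptance tests).
small_cohort <- function(seed = 1, ...) {
  cohort_config(n_pigs = 6, cohort_sizes = c(3, 3), microbiome_subset_size = 4,
                n_bacterial_taxa = 40, n_fungal_taxa = 30, seed = seed, ...)
}
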