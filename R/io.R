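#' Study design constants
#'
#' The fixed age grid (weeks) of the study design and the mapping from age to
#' physiological stage: pigs are sampled at 3, 6, 10, 12 and 22 weeks while
#' growing, at 32 weeks at first estrus / artificial insemination, at 49 weeks
#' one week before farrowing, at 50 weeks on the day of parturition and at 53
#' weeks at weaning of the first litter.
#'
#' @return `study_age_grid()` returns the integer age grid;
#'   `stage_for_age(age_weeks)` returns the stage label for each age.
#' @param age_weeks numeric vector of ages in weeks.
#' @export
#' @examples
#' stage_for_age(c(3, 32, 50))
study_age_grid <- function() {
  c(3L, 6L, 10L, 12L, 22L, 32L, 49L, 50L, 53L)
}

#' @rdname study_age_grid
#' @export
stage_for_age <- function(age_weeks) {
  dplyr::case_when(
    age_weeks == 32 ~ "estrus",
    age_weeks == 49 ~ "pre_parturition",
    age_weeks == 50 ~ "parturition",
    age_weeks == 53 ~ "weaning",
    TRUE ~ "growing"
  )
}

# ---- count tables ----------------------------------------------------------

#' Validate a count table
#'
#' A count table is a tibble whose first column, `sample_id`, holds unique
#' sample identifiers and whose remaining columns are uniquely named taxa with
#' nonnegative integer counts (samples as rows: the canonical orientation).
#'
#' @param counts a count-table tibble.
#' @return the validated tibble, invisibly usable in a pipe.
#' @export
validate_count_table <- function(counts) {
  if (!is.data.frame(counts) || names(counts)[1] != "sample_id") {
    abort("a count table must be a data frame whose first column is `sample_id`")
  }
  ids <- as.character(counts$sample_id)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sample_id: ", ids[duplicated(ids)][1]))
  }
  taxa <- names(counts)[-1]
  if (anyDuplicated(taxa)) {
    abort(paste0("duplicate taxon_id: ", taxa[duplicated(taxa)][1]))
  }
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("count cells must be numeric")
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf("missing count at sample '%s', taxon '%s' (encode absence as 0)",
                  ids[idx[1]], taxa[idx[2]]))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative count at sample '%s', taxon '%s'", ids[idx[1]], taxa[idx[2]]))
  }
  if (any(m != round(m))) {
    idx <- which(m != round(m), arr.ind = TRUE)[1, ]
    abort(sprintf("non-integer count %s at sample '%s', taxon '%s'",
                  format(m[idx[1], idx[2]]), ids[idx[1]], taxa[idx[2]]))
  }
  invisible(counts)
}

# Internal: tibble count table -> integer matrix with sample_id rownames.
count_matrix <- function(counts) {
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- as.character(counts$sample_id)
  storage.mode(m) <- "double"
  m
}

# Internal: matrix (samples x taxa, rownames = sample ids) -> count tibble.
matrix_to_count_table <- function(m) {
  dplyr::bind_cols(
    tibble(sample_id = rownames(m)),
    as_tibble(m, .name_repair = "minimal")
  )
}

#' Read and write count tables
#'
#' Count tables are plain TSV (UTF-8, no quoting) with one header row and a
#' leading label column. `orientation` says which way the file is laid out;
#' the returned table is always samples-as-rows.
#'
#' @param path file path to a TSV.
#' @param orientation `"samples_as_rows"` (leading column `sample_id`) or
#'   `"taxa_as_rows"` (leading column `taxon_id`; the file is transposed on
#'   read).
#' @return a validated count-table tibble (see [validate_count_table()]).
#' @export
read_count_table <- function(path, orientation = c("samples_as_rows", "taxa_as_rows")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, name_repair = "minimal")
  if (orientation == "taxa_as_rows") {
    taxa <- as.character(raw[[1]])
    m <- t(as.matrix(raw[, -1, drop = FALSE]))
    colnames(m) <- taxa
    raw <- matrix_to_count_table(m)
  }
  names(raw)[1] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  validate_count_table(raw)
  raw
}

#' @rdname read_count_table
#' @param counts a count-table tibble.
#' @export
write_count_table <- function(counts, path) {
  validate_count_table(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

# ---- metadata --------------------------------------------------------------

#' Read sample metadata
#'
#' Metadata is TSV with required columns `sample_id`, `pig_id`, `cohort`,
#' `age_weeks` and optional `stage`, `microbiome_subset`, `raw_read_count`.
#' When `stage` is absent it is derived from the age via [stage_for_age()].
#'
#' @param path file path to a TSV.
#' @param strict_ages when `TRUE` (default) ages must lie on the study grid
#'   ([study_age_grid()]); set `FALSE` to admit arbitrary age grids.
#' @return a validated metadata tibble.
#' @export
read_metadata <- function(path, strict_ages = TRUE) {
  md <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  validate_metadata(md, strict_ages = strict_ages)
}

#' @rdname read_metadata
#' @param metadata a metadata data frame to validate in-memory.
#' @export
validate_metadata <- function(metadata, strict_ages = TRUE) {
  required <- c("sample_id", "pig_id", "cohort", "age_weeks")
  missing <- setdiff(required, names(metadata))
  if (length(missing)) {
    abort(paste0("metadata is missing column(s): ", paste(missing, collapse = ", ")))
  }
  md <- as_tibble(metadata)
  md$sample_id <- as.character(md$sample_id)
  md$pig_id <- as.character(md$pig_id)
  if (anyDuplicated(md$sample_id)) {
    abort(paste0("duplicate sample_id: ", md$sample_id[duplicated(md$sample_id)][1]))
  }
  key <- paste(md$pig_id, md$age_weeks)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (pig_id, age_weeks): ", key[duplicated(key)][1]))
  }
  if (!all(md$cohort %in% c(1, 2))) abort("cohort must be 1 or 2")
  if (strict_ages && !all(md$age_weeks %in% study_age_grid())) {
    bad <- setdiff(unique(md$age_weeks), study_age_grid())
    abort(paste0("age_weeks off the study grid: ", paste(bad, collapse = ", "),
                 " (use strict_ages = FALSE for other designs)"))
  }
  derived <- stage_for_age(md$age_weeks)
  if (!"stage" %in% names(md)) {
    md$stage <- derived
  } else {
    md$stage <- ifelse(is.na(md$stage), derived, md$stage)
    ok <- !strict_ages | md$stage == derived
    if (!all(ok)) {
      abort(sprintf("stage '%s' inconsistent with age %s weeks",
                    md$stage[!ok][1], md$age_weeks[!ok][1]))
    }
  }
  if (!"microbiome_subset" %in% names(md)) md$microbiome_subset <- TRUE
  md$microbiome_subset <- as.logical(md$microbiome_subset)
  if (!"raw_read_count" %in% names(md)) md$raw_read_count <- NA_real_
  if (any(!is.na(md$raw_read_count) & md$raw_read_count < 0)) {
    abort("raw_read_count must be nonnegative")
  }
  md
}

# ---- AMR and qPCR tables ---------------------------------------------------

#' Read phenotypic AMR plate-count and qPCR gene-copy tables
#'
#' The AMR table holds log10 CFU per gram of wet feces for each sample x
#' indicator bacterium (coliform, enterococcus) x drug; an empty
#' `log10_cfu_per_g` cell means no growth on that plate (left-censored at the
#' detection limit; see [fit_penalized_spline_ar1()]). The qPCR table holds
#' absolute gene copies per gram for `tetA`, `blaCTXM` and `16S`.
#'
#' @param path file path to a TSV.
#' @return a tibble.
#' @export
read_amr_table <- function(path) {
  amr <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  required <- c("sample_id", "bacterium", "drug", "drug_class", "log10_cfu_per_g")
  missing <- setdiff(required, names(amr))
  if (length(missing)) {
    abort(paste0("AMR table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(amr$bacterium %in% c("coliform", "enterococcus"))) {
    abort("bacterium must be 'coliform' or 'enterococcus'")
  }
  amr$sample_id <- as.character(amr$sample_id)
  as_tibble(amr)
}

#' @rdname read_amr_table
#' @export
read_qpcr_table <- function(path) {
  q <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  required <- c("sample_id", "gene", "copies_per_g")
  missing <- setdiff(required, names(q))
  if (length(missing)) {
    abort(paste0("qPCR table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(!is.na(q$copies_per_g) & q$copies_per_g < 0)) {
    abort("copies_per_g must be nonnegative")
  }
  q$sample_id <- as.character(q$sample_id)
  as_tibble(q)
}

# ---- dataset assembly ------------------------------------------------------

#' Assemble a cross-referenced analysis dataset
#'
#' Joins a count table, sample metadata and (optionally) AMR and qPCR tables
#' into one validated object. Every count-table sample must have a metadata
#' record; metadata-only samples are allowed (the culture panel covers all 18
#' pigs while only 8 are sequenced), and AMR/qPCR sample ids must resolve to
#' metadata.
#'
#' @param counts count-table tibble (may be `NULL`).
#' @param metadata metadata tibble (see [read_metadata()]).
#' @param amr,qpcr optional AMR / qPCR tibbles.
#' @param strict_ages passed to [validate_metadata()].
#' @return an object of class `analysis_dataset`: a list with elements
#'   `counts`, `metadata`, `amr`, `qpcr`.
#' @export
assemble_dataset <- function(counts, metadata, amr = NULL, qpcr = NULL,
                             strict_ages = TRUE) {
  metadata <- validate_metadata(metadata, strict_ages = strict_ages)
  if (!is.null(counts)) {
    validate_count_table(counts)
    orphan <- setdiff(counts$sample_id, metadata$sample_id)
    if (length(orphan)) {
      abort(paste0("count-table sample(s) absent from metadata: ",
                   paste(orphan, collapse = ", ")))
    }
  }
  for (nm in c("amr", "qpcr")) {
    tbl <- get(nm)
    if (!is.null(tbl)) {
      orphan <- setdiff(tbl$sample_id, metadata$sample_id)
      if (length(orphan)) {
        abort(paste0(nm, " sample(s) absent from metadata: ",
                     paste(orphan, collapse = ", ")))
      }
    }
  }
  structure(
    list(counts = counts, metadata = metadata, amr = amr, qpcr = qpcr),
    class = "analysis_dataset"
  )
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat("<analysis_dataset>\n")
  cat("  metadata:", nrow(x$metadata), "samples,",
      length(unique(x$metadata$pig_id)), "pigs,",
      length(unique(x$metadata$age_weeks)), "age points\n")
  if (!is.null(x$counts)) {
    cat("  counts:  ", nrow(x$counts), "samples x", ncol(x$counts) - 1, "taxa\n")
  }
  if (!is.null(x$amr)) cat("  amr:     ", nrow(x$amr), "plate counts\n")
  if (!is.null(x$qpcr)) cat("  qpcr:    ", nrow(x$qpcr), "gene-copy records\n")
  invisible(x)
}
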