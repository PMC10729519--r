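#' Assemble a feature table
#'
#' The single currency of the pipeline: a samples-by-features abundance
#' matrix held as a tibble, together with per-sample and per-feature
#' metadata. Missing (undetected) abundances are `NA`.
#'
#' @param abundance Tibble/data frame whose first column is `sample_id` and
#'   whose remaining columns are numeric feature abundances (non-negative;
#'   `NA` marks a missing entry).
#' @param samples Tibble with one row per sample: `sample_id`, `group`
#'   (`"HCC"`, `"HCV"`, `"MC"`, or `NA` for QC pools), `sample_type`
#'   (`"study"` or `"QC"`), and optionally `afp` (ng/mL), `age` (years),
#'   `gender` (`"M"`/`"F"`).
#' @param features Tibble with one row per feature: `feature_id`, `block`
#'   (`"metabolomics"` or `"lipidomics"`), `group_tag` (feature family used
#'   by the synthetic generator, e.g. `"CAR-short"`, `"LPC"`, `"IS"`), and
#'   `is_id` (the internal-standard feature a lipid is normalized against,
#'   `NA` elsewhere).
#'
#' @return An object of class `feature_table`: a list with elements
#'   `abundance`, `samples`, `features`.
#' @export
feature_table <- function(abundance, samples, features) {
  abundance <- tibble::as_tibble(abundance)
  samples <- tibble::as_tibble(samples)
  features <- tibble::as_tibble(features)

  stopifnot(names(abundance)[1] == "sample_id")
  feat_ids <- setdiff(names(abundance), "sample_id")
  if (anyDuplicated(abundance$sample_id)) {
    stop("sample ids must be unique")
  }
  if (anyDuplicated(features$feature_id)) {
    stop("feature ids must be unique")
  }
  if (!setequal(feat_ids, features$feature_id)) {
    stop("abundance columns and feature metadata do not match")
  }
  if (!setequal(abundance$sample_id, samples$sample_id)) {
    stop("abundance rows and sample metadata do not match")
  }
  # align metadata order to the abundance table
  features <- features[match(feat_ids, features$feature_id), ]
  samples <- samples[match(abundance$sample_id, samples$sample_id), ]
  if (!"sample_type" %in% names(samples)) samples$sample_type <- "study"

  structure(
    list(abundance = abundance, samples = samples, features = features),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  n_study <- sum(x$samples$sample_type == "study")
  n_qc <- sum(x$samples$sample_type == "QC")
  blocks <- paste(unique(x$features$block), collapse = ", ")
  cat(sprintf(
    "<feature_table> %d study + %d QC samples x %d features (%s)\n",
    n_study, n_qc, nrow(x$features), blocks
  ))
  grp <- table(x$samples$group[x$samples$sample_type == "study"])
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = " "), "\n")
  n_miss <- sum(is.na(ft_matrix(x)))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", n_miss,
              100 * n_miss / (nrow(x$samples) * nrow(x$features))))
  rep <- attr(x, "preprocess_report")
  if (!is.null(rep)) cat("  preprocessing steps recorded:", nrow(rep), "\n")
  invisible(x)
}

#' Extract the abundance matrix of a feature table
#'
#' @param ft A [feature_table].
#' @return Numeric matrix, samples in rows (rownames = sample ids), features
#'   in columns.
#' @export
ft_matrix <- function(ft) {
  m <- as.matrix(ft$abundance[, -1, drop = FALSE])
  rownames(m) <- ft$abundance$sample_id
  storage.mode(m) <- "double"
  m
}

#' Replace the abundance matrix of a feature table
#'
#' Keeps sample metadata, subsets feature metadata to the matrix columns and
#' carries the preprocessing report along.
#'
#' @param ft A [feature_table].
#' @param m New abundance matrix (same rows as `ft`, columns a subset of or
#'   equal to its features).
#' @return A [feature_table].
#' @export
ft_set_matrix <- function(ft, m) {
  stopifnot(nrow(m) == nrow(ft$abundance))
  ab <- tibble::as_tibble(m)
  ab <- dplyr::bind_cols(ft$abundance[, "sample_id"], ab)
  out <- feature_table(ab, ft$samples, ft$features[ft$features$feature_id %in% colnames(m), ])
  attr(out, "preprocess_report") <- attr(ft, "preprocess_report")
  out
}

ft_is_study <- function(ft) ft$samples$sample_type == "study"
ft_is_qc <- function(ft) ft$samples$sample_type == "QC"

#' Drop QC samples from a feature table
#'
#' QC pools take part in quality filtering but are excluded from any
#' classifier fitting.
#'
#' @param ft A [feature_table].
#' @return A [feature_table] with only study samples.
#' @export
ft_study_only <- function(ft) {
  keep <- ft_is_study(ft)
  out <- feature_table(ft$abundance[keep, ], ft$samples[keep, ], ft$features)
  attr(out, "preprocess_report") <- attr(ft, "preprocess_report")
  out
}

#' Subset a feature table to a set of features
#'
#' @param ft A [feature_table].
#' @param feature_ids Character vector of feature ids to keep.
#' @return A [feature_table].
#' @export
ft_select_features <- function(ft, feature_ids) {
  missing <- setdiff(feature_ids, ft$features$feature_id)
  if (length(missing)) {
    stop("features not present in table: ", paste(missing, collapse = ", "))
  }
  ab <- ft$abundance[, c("sample_id", feature_ids)]
  out <- feature_table(ab, ft$samples, ft$features[match(feature_ids, ft$features$feature_id), ])
  attr(out, "preprocess_report") <- attr(ft, "preprocess_report")
  out
}

#' Long-format view of a feature table
#'
#' @param ft A [feature_table].
#' @return Tibble with columns `sample_id`, `feature_id`, `abundance`, joined
#'   with sample and feature metadata.
#' @export
ft_long <- function(ft) {
  ft$abundance |>
    tidyr::pivot_longer(-"sample_id", names_to = "feature_id",
                        values_to = "abundance") |>
    dplyr::left_join(ft$samples, by = "sample_id") |>
    dplyr::left_join(ft$features, by = "feature_id")
}

append_report <- function(ft, step, ...) {
  entry <- tibble::tibble(step = step, ...)
  rep <- attr(ft, "preprocess_report")
  attr(ft, "preprocess_report") <- dplyr::bind_rows(rep, entry)
  ft
}

#' Preprocessing report of a feature table
#'
#' Each filtering/normalization/imputation step appends one row recording
#' feature counts in/out and cells touched.
#'
#' @param ft A [feature_table] that has passed through preprocessing steps.
#' @return A tibble (possibly empty) with one row per recorded step.
#' @export
preprocess_report <- function(ft) {
  rep <- attr(ft, "preprocess_report")
  if (is.null(rep)) {
    return(tibble::tibble(step = character(), n_features_in = integer(),
                          n_features_out = integer()))
  }
  rep
}

#' Write a cohort to CSV files with a JSON sidecar
#'
#' Writes each block wide (samples x features) and long, plus sample and
#' feature metadata, and a JSON sidecar recording the generating
#' configuration and seed. Missing entries are written as empty fields.
#'
#' @param cohort Named list of [feature_table]s (e.g. the result of
#'   [generate_cohort()]).
#' @param dir Output directory (created if absent).
#' @param config Optional [cohort_config] to record in the sidecar.
#' @param seed Optional seed to record in the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, config = NULL, seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (block in names(cohort)) {
    ft <- cohort[[block]]
    p_wide <- file.path(dir, paste0(block, "_wide.csv"))
    p_long <- file.path(dir, paste0(block, "_long.csv"))
    p_samp <- file.path(dir, paste0(block, "_samples.csv"))
    p_feat <- file.path(dir, paste0(block, "_features.csv"))
    readr::write_csv(ft$abundance, p_wide, na = "")
    readr::write_csv(ft_long(ft)[, c("sample_id", "feature_id", "abundance")],
                     p_long, na = "")
    readr::write_csv(ft$samples, p_samp, na = "")
    readr::write_csv(ft$features, p_feat, na = "")
    paths <- c(paths, p_wide, p_long, p_samp, p_feat)
  }
  sidecar <- file.path(dir, "cohort.json")
  meta <- list(blocks = names(cohort), seed = seed)
  if (!is.null(config)) {
    meta$config <- config[!vapply(config, is.function, logical(1))]
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, sidecar))
}

#' Read a cohort block written by [write_cohort()]
#'
#' @param dir Directory written by [write_cohort()].
#' @param block Block name (e.g. `"metabolomics"`).
#' @return A [feature_table].
#' @export
read_cohort_block <- function(dir, block) {
  ab <- readr::read_csv(file.path(dir, paste0(block, "_wide.csv")),
                        show_col_types = FALSE)
  samples <- readr::read_csv(
    file.path(dir, paste0(block, "_samples.csv")),
    col_types = readr::cols(afp = "d", age = "d", .default = "c")
  )
  features <- readr::read_csv(
    file.path(dir, paste0(block, "_features.csv")),
    col_types = readr::cols(.default = "c")
  )
  feature_table(ab, samples, features)
}
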