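#' Remove features exceeding missingness thresholds
#'
#' A feature is removed iff it is missing in more than `real_threshold` of
#' study ("real") samples OR in more than `qc_threshold` of QC samples;
#' both comparisons are strict ("more than").
#'
#' @param ft A [feature_table] with at least one study and one QC sample.
#' @param real_threshold Maximum tolerated missing fraction among study
#'   samples (default 0.75).
#' @param qc_threshold Maximum tolerated missing fraction among QC samples
#'   (default 0.50).
#' @return The filtered [feature_table]; see [preprocess_report()].
#' @export
filter_missing <- function(ft, real_threshold = 0.75, qc_threshold = 0.50) {
  if (real_threshold < 0 || real_threshold > 1 ||
      qc_threshold < 0 || qc_threshold > 1) {
    stop("thresholds must lie in [0, 1]")
  }
  m <- ft_matrix(ft)
  study <- ft_is_study(ft)
  qc <- ft_is_qc(ft)
  if (!any(study) || !any(qc)) stop("need at least one study and one QC sample")
  miss_study <- colMeans(is.na(m[study, , drop = FALSE]))
  miss_qc <- colMeans(is.na(m[qc, , drop = FALSE]))
  drop <- miss_study > real_threshold | miss_qc > qc_threshold
  out <- ft_set_matrix(ft, m[, !drop, drop = FALSE])
  append_report(out, "filter_missing",
                n_features_in = ncol(m), n_features_out = sum(!drop),
                n_removed = sum(drop))
}

# per-feature CV% (100 * sd / mean) over observed QC values; NA when fewer
# than 2 observations or a zero mean
qc_cv_percent <- function(ft) {
  m <- ft_matrix(ft)[ft_is_qc(ft), , drop = FALSE]
  apply(m, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    mu <- mean(v)
    if (mu == 0) return(NA_real_)
    100 * stats::sd(v) / mu
  })
}

#' Remove features with unstable QC replicates
#'
#' The coefficient of variation (CV%) of each feature over its observed QC
#' values is `100 * sd / mean`; features with CV% above `cv_max` are
#' discarded. Features with fewer than two observed QC values, or a zero QC
#' mean (CV undefined), are also removed and counted separately.
#'
#' @param ft A [feature_table].
#' @param cv_max Maximum tolerated QC CV%, default 30.
#' @return The filtered [feature_table]; the per-feature QC CV% of retained
#'   features is stored in the report row.
#' @export
filter_cv <- function(ft, cv_max = 30) {
  cv <- qc_cv_percent(ft)
  undefined <- is.na(cv)
  drop <- undefined | cv > cv_max
  m <- ft_matrix(ft)
  out <- ft_set_matrix(ft, m[, !drop, drop = FALSE])
  out <- append_report(out, "filter_cv",
                       n_features_in = ncol(m), n_features_out = sum(!drop),
                       n_removed = sum(drop),
                       n_cv_undefined = sum(undefined))
  attr(out, "qc_cv") <- cv[!drop]
  out
}

#' Normalize abundances
#'
#' `total_ion_sum` divides every sample row by its total observed intensity
#' over the retained features, so observed row sums become 1 (the
#' metabolomics convention). `internal_standard` divides each feature
#' sample-wise by its class-specific internal-standard feature and then
#' drops the IS features (the lipidomics convention). `none` is the
#' identity.
#'
#' @param ft A [feature_table].
#' @param mode One of `"total_ion_sum"`, `"internal_standard"`, `"none"`.
#' @return The normalized [feature_table].
#' @export
normalize_abundance <- function(ft, mode = c("total_ion_sum",
                                             "internal_standard", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") {
    return(append_report(ft, "normalize", n_features_in = nrow(ft$features),
                         n_features_out = nrow(ft$features), mode = mode))
  }
  m <- ft_matrix(ft)
  if (mode == "total_ion_sum") {
    rs <- rowSums(m, na.rm = TRUE)
    if (any(rs == 0)) {
      stop("zero total intensity for sample(s): ",
           paste(rownames(m)[rs == 0], collapse = ", "))
    }
    out <- ft_set_matrix(ft, m / rs)
  } else {
    is_id <- ft$features$is_id
    is_features <- unique(is_id[!is.na(is_id)])
    if (any(is.na(is_id))) {
      stop("internal-standard normalization requires every feature to map ",
           "to an IS feature")
    }
    if (!all(is_features %in% colnames(m))) {
      stop("IS feature(s) absent from table: ",
           paste(setdiff(is_features, colnames(m)), collapse = ", "))
    }
    is_mat <- m[, is_id, drop = FALSE] # per-feature IS column, sample-wise
    bad <- which(is.na(is_mat) | is_mat == 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop("zero or missing internal-standard value for sample(s): ",
           paste(unique(rownames(m)[bad[, 1]]), collapse = ", "))
    }
    norm <- m / is_mat
    keep <- !(colnames(m) %in% is_features)
    out <- ft_set_matrix(ft, norm[, keep, drop = FALSE])
  }
  append_report(out, "normalize", n_features_in = ncol(m),
                n_features_out = ncol(ft_matrix(out)), mode = mode)
}

#' Impute missing values as a fraction of the feature minimum
#'
#' Every missing or zero cell of a feature is replaced by
#' `fraction * min(observed positive values of that feature)` — by default
#' one fifth of the feature minimum, the standard left-censoring surrogate
#' for values below the MS detection limit. Zeros are treated as missing
#' (required downstream by the log transform) and counted separately.
#'
#' @param ft A [feature_table].
#' @param fraction Multiple of the per-feature minimum used for replacement
#'   (default 1/5).
#' @return The imputed [feature_table] with no missing cells.
#' @export
impute_min_fraction <- function(ft, fraction = 1 / 5) {
  m <- ft_matrix(ft)
  is_zero <- !is.na(m) & m == 0
  m[is_zero] <- NA_real_
  n_zero <- sum(is_zero)
  n_missing <- sum(is.na(m)) - n_zero
  mins <- apply(m, 2, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (!length(v)) return(NA_real_)
    min(v)
  })
  if (anyNA(mins)) {
    stop("feature(s) with no observed positive value: ",
         paste(colnames(m)[is.na(mins)], collapse = ", "))
  }
  fill <- matrix(rep(fraction * mins, each = nrow(m)), nrow(m))
  m[is.na(m)] <- fill[is.na(m)]
  out <- ft_set_matrix(ft, m)
  append_report(out, "impute_min_fraction",
                n_features_in = ncol(m), n_features_out = ncol(m),
                n_imputed_cells = n_missing + n_zero, n_zero_cells = n_zero)
}

#' Log10-transform abundances
#'
#' @param ft A [feature_table] with strictly positive values (run
#'   [impute_min_fraction()] first).
#' @return The transformed [feature_table].
#' @export
log10_transform <- function(ft) {
  m <- ft_matrix(ft)
  bad <- which(is.na(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("nonpositive or missing value at sample ", rownames(m)[bad[1, 1]],
         ", feature ", colnames(m)[bad[1, 2]])
  }
  out <- ft_set_matrix(ft, log10(m))
  append_report(out, "log10_transform", n_features_in = ncol(m),
                n_features_out = ncol(m))
}

#' Autoscale a matrix
#'
#' Centers each column to mean 0 and scales to unit sample standard
#' deviation (denominator n - 1). Constant columns cannot be autoscaled and
#' are removed with a warning. Supplying `center`/`scale` applies stored
#' training parameters to new data instead of estimating them.
#'
#' @param x Numeric matrix (>= 2 rows).
#' @param center,scale Optional named numeric vectors of stored column
#'   means/SDs to apply.
#' @param quiet Suppress the constant-column warning (used internally when
#'   autoscaling small within-class submatrices).
#' @return The scaled matrix with attributes `center` and `scale` (and
#'   `dropped`, the names of removed constant columns, when estimating).
#' @export
autoscale <- function(x, center = NULL, scale = NULL, quiet = FALSE) {
  x <- as.matrix(x)
  if (!is.null(center) || !is.null(scale)) {
    stopifnot(!is.null(center), !is.null(scale))
    x <- x[, names(center), drop = FALSE]
    out <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
    attr(out, "center") <- center
    attr(out, "scale") <- scale
    return(out)
  }
  if (nrow(x) < 2) stop("autoscaling needs at least 2 rows")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  const <- sdv == 0 | is.na(sdv)
  if (any(const)) {
    if (!quiet) warning("removed ", sum(const), " constant column(s): ",
            paste(utils::head(colnames(x)[const], 5), collapse = ", "))
    x <- x[, !const, drop = FALSE]
    mu <- mu[!const]
    sdv <- sdv[!const]
  }
  out <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  attr(out, "dropped") <- names(const)[const]
  out
}

#' Run the full preprocessing chain on one block
#'
#' Applies, in order: the missingness filter, the QC CV filter,
#' normalization (total ion sum for metabolomics, internal standards for
#' lipidomics), minimum-fraction imputation and the log10 transform.
#' Autoscaling is deliberately left to model fitting so that scaling
#' parameters can be learned on the training partition. Post-normalization
#' QC CV% values are recomputed for the report.
#'
#' @param ft A [feature_table].
#' @param normalization Normalization mode; see [normalize_abundance()].
#' @param real_threshold,qc_threshold Missingness thresholds; see
#'   [filter_missing()].
#' @param cv_max QC CV% cut-off; see [filter_cv()].
#' @param impute_fraction Imputation fraction; see [impute_min_fraction()].
#' @return The preprocessed [feature_table] (log10 scale, no missing
#'   values), with the step-by-step report available via
#'   [preprocess_report()].
#' @export
preprocess <- function(ft,
                       normalization = c("total_ion_sum",
                                         "internal_standard", "none"),
                       real_threshold = 0.75, qc_threshold = 0.50,
                       cv_max = 30, impute_fraction = 1 / 5) {
  normalization <- match.arg(normalization)
  out <- ft |>
    filter_missing(real_threshold, qc_threshold) |>
    filter_cv(cv_max) |>
    normalize_abundance(normalization)
  attr(out, "qc_cv_post_normalization") <- qc_cv_percent(out)
  out |>
    impute_min_fraction(impute_fraction) |>
    log10_transform()
}
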