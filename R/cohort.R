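#' Default class-effect templates for the synthetic cohort
#'
#' Encodes, as per-class log10 offsets, the differential trends reported for
#' the three patient groups: short- and long-chain acylcarnitines and the
#' amino-acid derivatives (ADMA-, methylguanine-, Ile-Pro-like features)
#' elevated in HCC; medium-chain acylcarnitines elevated in HCV;
#' lysophosphatidylcholines (plain and ether-linked) strongly reduced in
#' HCC; phosphatidylcholines mildly elevated in both HCC and HCV relative
#' to MC. Untagged bulk features carry no class effect, and each lipid class
#' has one constant-spike internal standard (IS).
#'
#' @return Tibble with columns `tag`, `block`, `n_features`, and per-class
#'   log10 offsets `hcc`, `hcv`, `mc`.
#' @export
default_effect_templates <- function() {
  tibble::tribble(
    ~tag,          ~block,          ~n_features, ~hcc,  ~hcv,  ~mc,
    "CAR-short",   "metabolomics",  8L,          0.40,  0.00,  0.00,
    "CAR-long",    "metabolomics",  8L,          0.40,  0.00,  0.00,
    "CAR-medium",  "metabolomics",  8L,          0.00,  0.40,  0.00,
    "AA-deriv",    "metabolomics",  6L,          0.45,  0.20,  0.00,
    "LPC",         "lipidomics",   10L,         -0.50, -0.20,  0.00,
    "LPC-O",       "lipidomics",    4L,         -0.50, -0.15,  0.00,
    "PC",          "lipidomics",   10L,          0.25,  0.35,  0.00
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults reproduce the study design: 69 HCC, 23 HCV and 10 MC study
#' samples, pooled QC replicates, ~160 polar metabolites and ~120 lipids,
#' AFP positivity (> 20 ng/mL) fractions of 35/69, 1/23 and 0 per class,
#' and left-censored missingness concentrated at low abundance.
#'
#' @param n_hcc,n_hcv,n_mc Study samples per class.
#' @param n_qc Pooled QC replicates per block.
#' @param n_metabolites,n_lipids Features per block (internal standards for
#'   the lipid block are added on top of `n_lipids`).
#' @param effect_templates Tibble of per-class log10 offsets by feature
#'   family; see [default_effect_templates()].
#' @param base_log10_mean,base_log10_sd Mean and SD of the per-feature base
#'   log10 abundance across features.
#' @param within_sd_log10 Within-group biological + technical SD on the
#'   log10 scale (controls effect size in SD units).
#' @param qc_noise_cv Multiplicative coefficient of variation of QC
#'   replicates around the pooled mean.
#' @param missing_rate_low_abundance Probability that a cell below the
#'   low-abundance quantile is recorded missing.
#' @param low_abundance_quantile Pooled abundance quantile below which
#'   censoring applies.
#' @param afp_positive_fraction Named per-class fractions of AFP > 20 ng/mL.
#' @param afp_missing_groups Classes whose AFP is not determined (recorded
#'   `NA`).
#' @param seed Default seed used by [generate_cohort()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_hcc = 69, n_hcv = 23, n_mc = 10, n_qc = 8,
                          n_metabolites = 160, n_lipids = 120,
                          effect_templates = default_effect_templates(),
                          base_log10_mean = 5, base_log10_sd = 0.6,
                          within_sd_log10 = 0.12,
                          qc_noise_cv = 0.10,
                          missing_rate_low_abundance = 0.35,
                          low_abundance_quantile = 0.15,
                          afp_positive_fraction = c(HCC = 35 / 69,
                                                    HCV = 1 / 23, MC = 0),
                          afp_missing_groups = "MC",
                          seed = 1L) {
  counts <- c(n_hcc = n_hcc, n_hcv = n_hcv, n_mc = n_mc, n_qc = n_qc,
              n_metabolites = n_metabolites, n_lipids = n_lipids)
  if (any(counts < 0)) stop("all counts must be >= 0")
  fracs <- c(qc_noise_cv = qc_noise_cv,
             missing_rate_low_abundance = missing_rate_low_abundance,
             low_abundance_quantile = low_abundance_quantile,
             afp_positive_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  effect_templates <- tibble::as_tibble(effect_templates)
  stopifnot(all(c("tag", "block", "n_features", "hcc", "hcv", "mc") %in%
                  names(effect_templates)))
  # a class referenced with a nonzero effect must have samples to carry it
  class_n <- c(hcc = n_hcc, hcv = n_hcv, mc = n_mc)
  for (cls in names(class_n)) {
    if (class_n[[cls]] == 0 && any(effect_templates[[cls]] != 0)) {
      stop("effect templates reference class '", toupper(cls),
           "' but it has zero samples")
    }
  }
  for (blk in c("metabolomics", "lipidomics")) {
    n_tagged <- sum(effect_templates$n_features[effect_templates$block == blk])
    n_block <- if (blk == "metabolomics") n_metabolites else n_lipids
    if (n_tagged > n_block) {
      stop("effect templates assign more ", blk, " features (", n_tagged,
           ") than the block holds (", n_block, ")")
    }
  }
  structure(
    list(n_hcc = n_hcc, n_hcv = n_hcv, n_mc = n_mc, n_qc = n_qc,
         n_metabolites = n_metabolites, n_lipids = n_lipids,
         effect_templates = effect_templates,
         base_log10_mean = base_log10_mean, base_log10_sd = base_log10_sd,
         within_sd_log10 = within_sd_log10, qc_noise_cv = qc_noise_cv,
         missing_rate_low_abundance = missing_rate_low_abundance,
         low_abundance_quantile = low_abundance_quantile,
         afp_positive_fraction = afp_positive_fraction,
         afp_missing_groups = afp_missing_groups, seed = seed),
    class = "cohort_config"
  )
}

#' Simulate per-sample AFP concentrations
#'
#' Draws alpha-fetoprotein (ng/mL) from a two-component log-normal mixture:
#' with the configured per-class probability a sample is AFP-positive and
#' its value is drawn from a log-normal truncated above the 20 ng/mL
#' clinical threshold; otherwise from a log-normal truncated below it. The
#' expected per-class fraction exceeding 20 ng/mL therefore equals the
#' configured fraction exactly.
#'
#' @param groups Character vector of class labels.
#' @param fractions Named per-class fractions of AFP > 20 ng/mL.
#' @param seed Optional integer seed.
#' @param missing_groups Classes for which AFP is not determined (`NA`
#'   returned), as for MC patients.
#' @param threshold Positivity threshold in ng/mL.
#' @return Numeric vector of AFP values (ng/mL), `NA` for `missing_groups`.
#' @export
generate_afp <- function(groups, fractions, seed = NULL,
                         missing_groups = character(), threshold = 20) {
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(groups)
  afp <- rep(NA_real_, n)
  rtrunc_lnorm <- function(k, meanlog, sdlog, lower = -Inf, upper = Inf) {
    out <- numeric(k)
    need <- seq_len(k)
    while (length(need)) {
      x <- stats::rlnorm(length(need), meanlog, sdlog)
      ok <- x > lower & x <= upper
      out[need[ok]] <- x[ok]
      need <- need[!ok]
    }
    out
  }
  for (cls in unique(groups)) {
    idx <- which(groups == cls)
    if (cls %in% missing_groups) next
    f <- fractions[[cls]]
    if (is.null(f)) stop("no AFP fraction configured for class ", cls)
    pos <- stats::runif(length(idx)) < f
    if (any(pos)) {
      afp[idx[pos]] <- rtrunc_lnorm(sum(pos), log(150), 1.0, lower = threshold)
    }
    if (any(!pos)) {
      afp[idx[!pos]] <- rtrunc_lnorm(sum(!pos), log(8), 0.7, upper = threshold)
    }
  }
  afp
}

# one block of the synthetic cohort; sample_meta is shared across blocks
simulate_block <- function(config, block, sample_meta) {
  templ <- config$effect_templates[config$effect_templates$block == block, ]
  n_block <- if (block == "metabolomics") config$n_metabolites else config$n_lipids
  n_bulk <- n_block - sum(templ$n_features)
  bulk_tag <- if (block == "metabolomics") "MET-bulk" else "LIP-bulk"

  tags <- c(rep(templ$tag, templ$n_features), rep(bulk_tag, n_bulk))
  off_hcc <- c(rep(templ$hcc, templ$n_features), rep(0, n_bulk))
  off_hcv <- c(rep(templ$hcv, templ$n_features), rep(0, n_bulk))
  off_mc <- c(rep(templ$mc, templ$n_features), rep(0, n_bulk))
  # tags are grouped, so per-tag numbering stays aligned with the tag vector
  feature_id <- unlist(lapply(unique(tags), function(tg) {
    sprintf("%s_%02d", tg, seq_len(sum(tags == tg)))
  }), use.names = FALSE)

  is_id <- rep(NA_character_, n_block)
  if (block == "lipidomics") {
    lipid_classes <- unique(tags)
    is_features <- paste0("IS_", gsub("[^A-Za-z0-9]", "", lipid_classes))
    is_id <- is_features[match(tags, lipid_classes)]
    feature_id <- c(feature_id, is_features)
    tags <- c(tags, rep("IS", length(is_features)))
    off_hcc <- c(off_hcc, rep(0, length(is_features)))
    off_hcv <- c(off_hcv, rep(0, length(is_features)))
    off_mc <- c(off_mc, rep(0, length(is_features)))
    is_id <- c(is_id, is_features) # IS maps to itself
  }
  p <- length(feature_id)
  is_is <- tags == "IS"

  study <- sample_meta$sample_type == "study"
  n_study <- sum(study)
  base <- stats::rnorm(p, config$base_log10_mean, config$base_log10_sd)
  offsets <- rbind(HCC = off_hcc, HCV = off_hcv, MC = off_mc)

  log10_study <- matrix(NA_real_, n_study, p)
  grp <- sample_meta$group[study]
  sdlog_qc <- sqrt(log1p(config$qc_noise_cv^2)) / log(10) # CV -> log10-scale SD
  for (j in seq_len(p)) {
    if (is_is[j]) {
      # constant spike with QC-level multiplicative noise only
      log10_study[, j] <- base[j] + stats::rnorm(n_study, 0, sdlog_qc)
    } else {
      log10_study[, j] <- base[j] + offsets[grp, j] +
        stats::rnorm(n_study, 0, config$within_sd_log10)
    }
  }
  ab_study <- 10^log10_study

  # QC pools: per-feature mean over all study samples, multiplicative noise
  n_qc <- sum(!study)
  qc_mean <- colMeans(ab_study)
  ab_qc <- matrix(rep(qc_mean, each = n_qc), n_qc, p) *
    exp(matrix(stats::rnorm(n_qc * p, 0, sqrt(log1p(config$qc_noise_cv^2))),
               n_qc, p))

  ab <- matrix(NA_real_, nrow(sample_meta), p)
  ab[study, ] <- ab_study
  ab[!study, ] <- ab_qc

  # left-censored missingness: cells below the pooled low-abundance quantile
  # (internal standards excluded) go missing with the configured rate
  pool <- ab[, !is_is, drop = FALSE]
  if (length(pool) && config$missing_rate_low_abundance > 0) {
    thr <- stats::quantile(pool, config$low_abundance_quantile, names = FALSE)
    low <- !is_is[col(ab)] & ab < thr
    drop <- low & matrix(stats::runif(length(ab)) <
                           config$missing_rate_low_abundance, nrow(ab))
    ab[drop] <- NA_real_
  }

  colnames(ab) <- feature_id
  abundance <- dplyr::bind_cols(
    tibble::tibble(sample_id = sample_meta$sample_id),
    tibble::as_tibble(ab)
  )
  features <- tibble::tibble(
    feature_id = feature_id, block = block, group_tag = tags, is_id = is_id
  )
  feature_table(abundance, sample_meta, features)
}

#' Generate a synthetic two-block cohort
#'
#' Simulates the study design end to end: study samples in three classes
#' (HCC/HCV/MC) with log-normal feature abundances carrying the class
#' offsets of the effect templates, pooled QC replicates with multiplicative
#' noise, left-censored missingness, clinical covariates (AFP, age, gender)
#' matching the reported marginal distributions, and a metabolomics and a
#' lipidomics block sharing the sample set.
#'
#' @param config A [cohort_config].
#' @param seed Integer seed (defaults to `config$seed`); the same
#'   config + seed always yields identical tables.
#' @return Named list with [feature_table]s `metabolomics` and `lipidomics`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)

  grp <- c(rep("HCC", config$n_hcc), rep("HCV", config$n_hcv),
           rep("MC", config$n_mc))
  n_study <- length(grp)
  sample_id <- c(sprintf("S%03d", seq_len(n_study)),
                 sprintf("QC%02d", seq_len(config$n_qc)))
  sample_type <- c(rep("study", n_study), rep("QC", config$n_qc))

  afp <- generate_afp(grp, config$afp_positive_fraction,
                      missing_groups = config$afp_missing_groups)
  # age / gender marginals follow the reported cohort table:
  # P(age > 65) = 75% HCC, 13% HCV, 60% MC; P(male) = 71%, 61%, 50%
  p_old <- c(HCC = 0.75, HCV = 0.13, MC = 0.60)[grp]
  old <- stats::runif(n_study) < p_old
  age <- ifelse(old, round(stats::runif(n_study, 66, 85)),
                round(stats::runif(n_study, 40, 65)))
  p_male <- c(HCC = 0.71, HCV = 0.61, MC = 0.50)[grp]
  gender <- ifelse(stats::runif(n_study) < p_male, "M", "F")

  sample_meta <- tibble::tibble(
    sample_id = sample_id,
    group = c(grp, rep(NA_character_, config$n_qc)),
    sample_type = sample_type,
    afp = c(afp, rep(NA_real_, config$n_qc)),
    age = c(age, rep(NA_real_, config$n_qc)),
    gender = c(gender, rep(NA_character_, config$n_qc))
  )

  list(
    metabolomics = simulate_block(config, "metabolomics", sample_meta),
    lipidomics = simulate_block(config, "lipidomics", sample_meta)
  )
}
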