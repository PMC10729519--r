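# small in-code fixtures and independent oracles shared across tests

# build a feature table from raw study/QC matrices
make_ft <- function(study, qc = NULL, groups = NULL, block = "metabolomics",
                    group_tag = NULL, is_id = NULL, afp = NULL, age = NULL) {
  study <- as.matrix(study)
  p <- ncol(study)
  if (is.null(colnames(study))) colnames(study) <- sprintf("f%02d", seq_len(p))
  n_s <- nrow(study)
  n_q <- if (is.null(qc)) 0L else nrow(qc)
  ab <- rbind(study, if (!is.null(qc)) {
    qc <- as.matrix(qc)
    colnames(qc) <- colnames(study)
    qc
  })
  sample_id <- c(sprintf("S%02d", seq_len(n_s)),
                 if (n_q) sprintf("QC%02d", seq_len(n_q)))
  samples <- tibble::tibble(
    sample_id = sample_id,
    group = c(groups %||% rep("HCC", n_s), rep(NA_character_, n_q)),
    sample_type = c(rep("study", n_s), rep("QC", n_q)),
    afp = c(afp %||% rep(NA_real_, n_s), rep(NA_real_, n_q)),
    age = c(age %||% rep(NA_real_, n_s), rep(NA_real_, n_q))
  )
  features <- tibble::tibble(
    feature_id = colnames(study), block = block,
    group_tag = group_tag %||% rep("bulk", p),
    is_id = is_id %||% rep(NA_character_, p)
  )
  abundance <- dplyr::bind_cols(tibble::tibble(sample_id = sample_id),
                                tibble::as_tibble(ab))
  feature_table(abundance, samples, features)
}

# three well-separated Gaussian classes in a handful of variables
toy_three_class <- function(n_per = 15, p = 6, sep = 6, seed = 11) {
  set.seed(seed)
  centers <- rbind(A = c(rep(sep, 2), rep(0, p - 2)),
                   B = c(rep(0, 2), rep(sep, 2), rep(0, p - 4)),
                   C = rep(0, p))
  labels <- rep(rownames(centers), each = n_per)
  x <- centers[labels, ] + matrix(rnorm(3 * n_per * p), ncol = p)
  colnames(x) <- paste0("v", seq_len(p))
  rownames(x) <- NULL
  list(x = x, labels = labels)
}

# --- independent oracles -------------------------------------------------

# two-sided Fisher exact p by exhaustive enumeration over fixed margins
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ])            # row-1 margin
  n2 <- sum(tab[2, ])           # row-2 margin
  k <- sum(tab[, 1])            # column-1 margin
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUROC by brute-force concordant-pair counting (ties count half)
auroc_oracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  conc <- 0
  for (sp in pos) for (sn in neg) {
    conc <- conc + (sp > sn) + 0.5 * (sp == sn)
  }
  conc / (length(pos) * length(neg))
}

# naive Kennard-Stone: exhaustive maximin checks at every greedy step
kennard_stone_oracle <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- as.matrix(dist(points))
  best_pair <- NULL
  best_d <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] > best_d) {
      best_d <- d[i, j]
      best_pair <- c(i, j)
    }
  }
  sel <- best_pair
  while (length(sel) < k) {
    cand_best <- NULL
    cand_d <- -Inf
    for (i in setdiff(seq_len(n), sel)) {
      mind <- min(d[i, sel])
      if (mind > cand_d) {
        cand_d <- mind
        cand_best <- i
      }
    }
    sel <- c(sel, cand_best)
  }
  sel
}

# scaled-down effect templates for small test cohorts
small_templates <- function() {
  dplyr::mutate(default_effect_templates(), n_features = 2L)
}
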