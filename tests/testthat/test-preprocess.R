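test_that("missingness filter removes features strictly above thresholds", {
  study <- rbind(c(NA, NA, 1), c(NA, NA, 2), c(NA, 3, 4), c(NA, 5, 6))
  qc <- rbind(c(1, 1, NA), c(2, 2, NA))
  colnames(study) <- c("all_missing", "borderline", "qc_missing")
  ft <- make_ft(study, qc)
  out <- filter_missing(ft)
  kept <- out$features$feature_id
  expect_false("all_missing" %in% kept)   # 4/4 study missing: > 75%
  expect_true("borderline" %in% kept)     # exactly 75% study, 0% QC: kept
  expect_false("qc_missing" %in% kept)    # 2/2 QC missing: > 50%
  rep <- preprocess_report(out)
  expect_equal(rep$n_features_in, 3L)
  expect_equal(rep$n_features_out, 1L)
  expect_error(filter_missing(ft, real_threshold = 1.2), "thresholds")
})

test_that("QC CV filter discards unstable or undefined features", {
  study <- matrix(1, 2, 4, dimnames = list(NULL, c("flat", "wild", "tight",
                                                   "sparse_qc")))
  qc <- rbind(c(10, 1, 9, 5), c(10, 2, 10, NA), c(10, 3, 11, NA))
  ft <- make_ft(study, qc)
  out <- filter_cv(ft, cv_max = 30)
  kept <- out$features$feature_id
  expect_true("flat" %in% kept)        # CV 0%
  expect_false("wild" %in% kept)       # sd 1 / mean 2 = 50%
  expect_true("tight" %in% kept)       # sd 1 / mean 10 = 10%
  expect_false("sparse_qc" %in% kept)  # single QC observation: undefined
  expect_equal(preprocess_report(out)$n_cv_undefined, 1L)
  expect_equal(unname(attr(out, "qc_cv")["tight"]), 10, tolerance = 1e-12)
})

test_that("total-ion-sum normalization rescales rows to unit sum", {
  ft <- make_ft(rbind(c(2, 3, 5), c(4, 6, 10)), qc = rbind(c(1, 1, 2)))
  out <- normalize_abundance(ft, "total_ion_sum")
  m <- ft_matrix(out)
  expect_equal(unname(m[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(rowSums(m)), rep(1, 3), tolerance = 1e-12)
  # scale invariance: proportional rows coincide after normalization
  expect_equal(unname(m[1, ]), unname(m[2, ]))
})

test_that("internal-standard normalization divides by the class IS and drops it", {
  study <- rbind(c(6, 8, 2), c(9, 12, 3))
  colnames(study) <- c("LPC_1", "LPC_2", "IS_LPC")
  ft <- make_ft(study, qc = rbind(c(2, 2, 1)), block = "lipidomics",
                group_tag = c("LPC", "LPC", "IS"),
                is_id = c("IS_LPC", "IS_LPC", "IS_LPC"))
  out <- normalize_abundance(ft, "internal_standard")
  m <- ft_matrix(out)
  expect_equal(colnames(m), c("LPC_1", "LPC_2"))
  expect_equal(unname(m[1, ]), c(3, 4))
  expect_equal(unname(m[2, ]), c(3, 4))

  study0 <- study
  study0[1, 3] <- 0
  ft0 <- make_ft(study0, qc = rbind(c(2, 2, 1)), block = "lipidomics",
                 group_tag = c("LPC", "LPC", "IS"),
                 is_id = c("IS_LPC", "IS_LPC", "IS_LPC"))
  expect_error(normalize_abundance(ft0, "internal_standard"), "S01")
})

test_that("imputation replaces missing and zero cells by min/5", {
  study <- rbind(c(5, 1, 0.5), c(10, 2, NA), c(NA, 3, NA))
  colnames(study) <- c("a", "b", "c")
  ft <- make_ft(study, qc = rbind(c(5, 1, 0.5)))
  out <- impute_min_fraction(ft)
  m <- ft_matrix(out)
  expect_equal(m["S03", "a"], 1.0)          # min 5 -> 1
  expect_equal(unname(m[, "b"]), c(1, 2, 3, 1)) # untouched (incl. QC row)
  expect_equal(unname(m[2:3, "c"]), c(0.1, 0.1))
  expect_equal(preprocess_report(out)$n_imputed_cells[
    preprocess_report(out)$step == "impute_min_fraction"], 3L)

  # zeros are treated as missing
  ftz <- make_ft(rbind(c(0, 1), c(4, 2)), qc = rbind(c(4, 1)))
  mz <- ft_matrix(impute_min_fraction(ftz))
  expect_equal(mz[1, 1], 4 / 5)
})

test_that("log10 transform composes with imputation as expected", {
  ft <- make_ft(rbind(c(1, 100), c(10, 1000)), qc = rbind(c(1, 100)))
  m <- ft_matrix(log10_transform(ft))
  expect_equal(unname(m[1, ]), c(0, 2))
  # impute(min = 5) then log10 leaves 0 in imputed cells
  ft2 <- make_ft(rbind(c(5, 1), c(NA, 2)), qc = rbind(c(5, 1)))
  m2 <- ft_matrix(log10_transform(impute_min_fraction(ft2)))
  expect_equal(m2[2, 1], 0)
  expect_error(log10_transform(make_ft(rbind(c(-1, 1), c(1, 1)),
                                       qc = rbind(c(1, 1)))),
               "nonpositive")
})

test_that("autoscaling yields exact zero means and unit SDs", {
  expect_equal(unname(autoscale(cbind(x = c(1, 2, 3)))[, 1]), c(-1, 0, 1))
  set.seed(4)
  x <- matrix(rnorm(500, sd = 3), 50, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  xs <- autoscale(x)
  expect_true(all(abs(colMeans(xs)) < 1e-10))
  expect_true(all(abs(apply(xs, 2, sd) - 1) < 1e-10))
  # idempotence on already-autoscaled input
  expect_equal(unclass(autoscale(xs))[, ], xs[, ], tolerance = 1e-12)
  # stored parameters reproduce the training scaling on new data
  xs2 <- autoscale(x, center = attr(xs, "center"), scale = attr(xs, "scale"))
  expect_equal(xs2[, ], xs[, ])
  expect_warning(autoscale(cbind(a = c(1, 1, 1), b = c(1, 2, 3))), "constant")
})

test_that("the preprocessing chain runs in the documented order", {
  cohort <- generate_cohort(cohort_config(n_hcc = 10, n_hcv = 6, n_mc = 4,
                                          n_qc = 4, n_metabolites = 40,
                                          n_lipids = 20,
                                          effect_templates = small_templates()),
                            seed = 12)
  out <- preprocess(cohort$metabolomics, "total_ion_sum")
  rep <- preprocess_report(out)
  expect_equal(rep$step, c("filter_missing", "filter_cv", "normalize",
                           "impute_min_fraction", "log10_transform"))
  # counts are additive across the two filters
  expect_equal(rep$n_features_in[1] - rep$n_removed[1], rep$n_features_in[2])
  expect_equal(rep$n_features_in[2] - rep$n_removed[2], rep$n_features_out[2])
  expect_false(anyNA(ft_matrix(out)))
  # every retained feature passed the QC CV gate
  expect_true(all(attr(out, "qc_cv") <= 30))
})
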