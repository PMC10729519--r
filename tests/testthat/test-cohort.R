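test_that("generated cohort matches the configured study design", {
  cfg <- cohort_config(n_qc = 6)
  cohort <- generate_cohort(cfg, seed = 3)
  for (block in c("metabolomics", "lipidomics")) {
    ft <- cohort[[block]]
    expect_equal(sum(ft$samples$sample_type == "study"), 69 + 23 + 10)
    expect_equal(sum(ft$samples$sample_type == "QC"), 6)
    expect_equal(unname(table(ft$samples$group)[c("HCC", "HCV", "MC")]),
                 c(69L, 23L, 10L), ignore_attr = TRUE)
    expect_false(anyDuplicated(ft$samples$sample_id) > 0)
    expect_false(anyDuplicated(ft$features$feature_id) > 0)
  }
  expect_equal(nrow(cohort$metabolomics$features), 160)
  # lipid block: configured features plus one IS spike per lipid class
  lip <- cohort$lipidomics$features
  expect_equal(sum(lip$group_tag != "IS"), 120)
  expect_true(all(!is.na(lip$is_id)))
  expect_true(all(lip$is_id %in% lip$feature_id))
})

test_that("identical config and seed reproduce bit-identical tables", {
  cfg <- cohort_config(n_hcc = 12, n_hcv = 6, n_mc = 4, n_qc = 3,
                       n_metabolites = 30, n_lipids = 20,
                       effect_templates = small_templates())
  a <- generate_cohort(cfg, seed = 99)
  b <- generate_cohort(cfg, seed = 99)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 100)
  expect_false(identical(a$metabolomics$abundance, c$metabolomics$abundance))
})

test_that("QC replicates reflect the configured noise level", {
  cohort <- generate_cohort(cohort_config(qc_noise_cv = 0.10, n_qc = 8),
                            seed = 5)
  ft <- cohort$metabolomics
  m <- ft_matrix(ft)[ft$samples$sample_type == "QC", ]
  cv <- apply(m, 2, function(v) 100 * sd(v, na.rm = TRUE) /
                mean(v, na.rm = TRUE))
  # platform-stability claim: the large majority of features are tight in QC
  expect_gte(mean(cv < 20, na.rm = TRUE), 0.90)
  # the median QC CV tracks the configured multiplicative noise
  expect_lt(abs(median(cv, na.rm = TRUE) - 10), 3)
})

test_that("class effects are recoverable and nulls behave", {
  cohort <- generate_cohort(cohort_config(), seed = 21)
  met <- preprocess(cohort$metabolomics, "total_ion_sum")
  an <- univariate_anova(met)
  tags <- met$features$group_tag[match(an$feature, met$features$feature_id)]
  templ <- default_effect_templates()
  strong <- templ$tag[templ$block == "metabolomics" &
                        abs(templ$hcc - templ$mc) >= 0.36] # >= 3 x within-SD
  sig <- an$p_value[tags %in% strong]
  expect_gte(mean(sig < 0.01), 0.95)

  # zero-effect config: rejection at about the nominal rate
  templ0 <- dplyr::mutate(templ, hcc = 0, hcv = 0, mc = 0)
  null_cohort <- generate_cohort(
    cohort_config(effect_templates = templ0,
                  missing_rate_low_abundance = 0), seed = 22)
  an0 <- univariate_anova(null_cohort$metabolomics)
  expect_lt(mean(an0$p_value < 0.05), 0.12)
})

test_that("a class carrying a nonzero effect cannot be empty", {
  templ <- dplyr::mutate(default_effect_templates(), mc = 0.2)
  expect_error(cohort_config(n_mc = 0, effect_templates = templ),
               "zero samples")
  # default templates use MC as the zero-offset reference, so it may be absent
  expect_silent(cohort_config(n_mc = 0))
  expect_error(cohort_config(n_hcc = -1), "counts")
  expect_error(cohort_config(qc_noise_cv = 1.5), "fractions")
})

test_that("AFP mixture hits the configured exceedance fractions", {
  expect_true(all(generate_afp(rep("MC", 50), c(MC = 0), seed = 1) <= 20))
  expect_true(all(generate_afp(rep("HCV", 50), c(HCV = 1), seed = 2) > 20))
  afp <- generate_afp(rep("HCC", 6900), c(HCC = 35 / 69), seed = 3)
  expect_lt(abs(mean(afp > 20) - 35 / 69), 0.02)
  # AFP not determined for MC
  afp_mc <- generate_afp(c("HCC", "MC"), c(HCC = 0.5, MC = 0), seed = 4,
                         missing_groups = "MC")
  expect_true(is.na(afp_mc[2]) && !is.na(afp_mc[1]))
})

test_that("cohort round-trips through the CSV writer", {
  cfg <- cohort_config(n_hcc = 8, n_hcv = 5, n_mc = 4, n_qc = 2,
                       n_metabolites = 12, n_lipids = 10,
                       effect_templates = small_templates())
  cohort <- generate_cohort(cfg, seed = 8)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir, config = cfg, seed = 8)
  rt <- read_cohort_block(dir, "metabolomics")
  expect_equal(ft_matrix(rt), ft_matrix(cohort$metabolomics))
  expect_equal(rt$features, cohort$metabolomics$features)
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"))
  expect_equal(meta$seed, 8)
})
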