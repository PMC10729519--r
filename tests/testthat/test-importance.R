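test_that("VIP scores obey the normalization identity on every fit", {
  set.seed(91)
  for (rep in 1:5) {
    p <- sample(4:12, 1)
    n <- 30
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    labels <- sample(c("A", "B", "C"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    fit <- fit_plsda(autoscale(x), labels, n_lv = sample(1:3, 1))
    v <- vip_scores(fit)
    expect_equal(sum(v$vip^2), p, tolerance = 1e-8)
    expect_true(all(v$vip >= 0))
    # ranking is stable: ordered by vip desc then feature id
    expect_identical(v$rank, seq_len(p))
    expect_false(is.unsorted(rev(v$vip)))
  }
})

test_that("exchangeable features all get VIP 1", {
  set.seed(92)
  base <- c(rnorm(10), rnorm(10) + 4)
  x <- cbind(a = base, b = base, c = base)
  fit <- fit_plsda(autoscale(x), rep(c("A", "B"), each = 10), n_lv = 1)
  expect_equal(vip_scores(fit)$vip, rep(1, 3), tolerance = 1e-8)
})

test_that("per-feature ANOVA recovers shifts and respects degenerate input", {
  # identical groups: F = 0, p = 1
  x <- cbind(f1 = c(1, 2, 3, 1, 2, 3))
  an <- univariate_anova(x, rep(c("A", "B"), each = 3))
  expect_equal(an$f_statistic, 0, tolerance = 1e-12)
  expect_equal(an$p_value, 1, tolerance = 1e-12)
  # 5-SD shift at n = 10 per group: overwhelming evidence
  set.seed(93)
  x2 <- cbind(f1 = c(rnorm(10), rnorm(10) + 5))
  an2 <- univariate_anova(x2, rep(c("A", "B"), each = 10))
  expect_lt(an2$p_value, 1e-6)
  # zero within-variance with equal means: conventional p = 1, flagged
  x3 <- cbind(f1 = rep(2, 6))
  an3 <- univariate_anova(x3, rep(c("A", "B"), each = 3))
  expect_true(an3$degenerate)
  expect_equal(an3$p_value, 1)
  expect_error(univariate_anova(x3, rep("A", 6)), "2 groups")
})

test_that("age correlation reports exact limiting cases", {
  expect_equal(age_correlation(cbind(f = c(30, 40, 50)), c(30, 40, 50))$r, 1)
  expect_equal(age_correlation(cbind(f = c(1, 2, 3)), c(6, 4, 2))$r, -1)
  set.seed(94)
  null <- age_correlation(cbind(f = rnorm(500)), rnorm(500))
  expect_lt(abs(null$r), 0.15)
  flat <- age_correlation(cbind(f = rep(1, 10)), 1:10)
  expect_true(flat$degenerate)
})

test_that("over-representation matches the hypergeometric by hand", {
  universe <- paste0("m", 1:100)
  sets <- list(S = paste0("m", 1:10))
  selected <- c(paste0("m", 1:5), paste0("m", 50:54))
  res <- over_representation(selected, sets, universe)
  expect_equal(res$enrichment_ratio, 5 / (10 * 10 / 100)) # = 5
  expect_equal(res$p_value,
               phyper(4, 10, 90, 10, lower.tail = FALSE), tolerance = 1e-12)
  # zero overlap
  res0 <- over_representation(paste0("m", 90:99),
                              list(S = paste0("m", 1:10)), universe)
  expect_equal(res0$enrichment_ratio, 0)
  expect_equal(res0$p_value, 1, tolerance = 1e-9)
  # selecting the whole universe trivializes every set
  resU <- over_representation(universe, sets, universe)
  expect_equal(resU$enrichment_ratio, 1)
  expect_equal(resU$p_value, 1)
  expect_error(over_representation("x1", sets, universe), "outside")
  expect_error(over_representation("m1", sets, character()), "empty")
})

test_that("GMT files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tm1\tm2\tm3", "setB\tdesc\tm4"), path)
  sets <- read_gmt(path)
  expect_equal(sets, list(setA = c("m1", "m2", "m3"), setB = "m4"))
})

test_that("reduced refits reproduce the full model and reject bad subsets", {
  cohort <- generate_cohort(cohort_config(n_hcc = 16, n_hcv = 10, n_mc = 6,
                                          n_metabolites = 30, n_lipids = 12,
                                          effect_templates = small_templates()),
                            seed = 95)
  met <- preprocess(cohort$metabolomics, "total_ion_sum")
  sp <- split_per_class(met)
  full <- refit_reduced(met, sp, n_lv = 2)
  same <- refit_reduced(met, sp, subset = met$features$feature_id, n_lv = 2)
  expect_equal(full$model$coefficients, same$model$coefficients)
  expect_equal(full$metrics$accuracy, same$metrics$accuracy)
  expect_error(refit_reduced(met, sp, subset = character()), "empty")
  expect_error(refit_reduced(met, sp, subset = "no_such_feature"),
               "not present")
})

test_that("signal-bearing subsets beat no-signal subsets on test AUROC", {
  cohort <- generate_cohort(cohort_config(), seed = 96)
  met <- preprocess(cohort$metabolomics, "total_ion_sum")
  lip <- preprocess(cohort$lipidomics, "internal_standard")
  sp <- split_per_class(list(metabolomics = met, lipidomics = lip))
  tags <- met$features
  signal <- tags$feature_id[tags$group_tag != "MET-bulk"][1:20]
  noise <- tags$feature_id[tags$group_tag == "MET-bulk"][1:20]
  r_sig <- refit_reduced(met, sp, subset = signal, n_lv = 2)
  r_noise <- refit_reduced(met, sp, subset = noise, n_lv = 2)
  expect_gte(r_sig$roc$auroc, r_noise$roc$auroc)
  expect_gt(r_sig$roc$auroc, 0.9)
})
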