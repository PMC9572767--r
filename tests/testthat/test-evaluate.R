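test_that("confusion metrics match hand counts", {
  perfect <- confusion_and_metrics(rep(0:1, each = 10), rep(0:1, each = 10))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$sensitivity == 1))
  expect_true(all(perfect$per_class$specificity == 1))

  truth <- c(0, 0, 0, 0, 1, 1, 1, 1)
  pred <- c(0, 0, 0, 1, 1, 1, 1, 0)
  ev <- confusion_and_metrics(truth, pred)
  expect_equal(ev$accuracy, 0.75)
  expect_equal(ev$per_class$sensitivity[1], 0.75)
  expect_equal(unname(ev$confusion["0", ]), c(3, 1))

  const <- confusion_and_metrics(rep(0:1, each = 10), rep(0, 20))
  expect_equal(const$accuracy, 0.5)
  expect_equal(const$per_class$sensitivity[2], 0)

  expect_error(confusion_and_metrics(integer(0), integer(0)), "empty")
})

test_that("macro sensitivity behaves for perfect and constant predictors", {
  t3 <- rep(0:2, each = 5)
  expect_equal(confusion_and_metrics(t3, t3)$macro[["sensitivity"]], 1)
  expect_equal(confusion_and_metrics(t3, rep(0, 15))$macro[["sensitivity"]],
               1 / 3)
})

test_that("AUC hits its endpoints and matches the pairwise oracle", {
  truth <- rep(c(1, 0), each = 10)
  expect_equal(roc_auc(truth, c(rep(2, 10), rep(1, 10)), 1)$auc, 1)
  expect_equal(roc_auc(truth, c(rep(1, 10), rep(2, 10)), 1)$auc, 0)
  expect_error(roc_auc(rep(1, 5), rnorm(5), 1), "represented")

  set.seed(81)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    truth <- sample(0:1, n, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(truth)) < 2) truth[1:2] <- 0:1
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    got <- roc_auc(truth, scores, 1)$auc
    expect_equal(got, auc_oracle(truth, scores, 1), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent reference implementation", {
  set.seed(82)
  truth <- sample(0:1, 120, replace = TRUE)
  scores <- rnorm(120) + truth
  ours <- roc_auc(truth, scores, 1)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("random scores give AUC near one half", {
  set.seed(83)
  truth <- rep(0:1, 1000)
  auc <- roc_auc(truth, runif(2000), 1)$auc
  expect_equal(auc, 0.5, tolerance = 0.03 / 0.5)
})

test_that("ROC curves are step-exact with infinite endpoints", {
  r <- roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8), 1)
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[1], 0)
  expect_equal(r$roc$fpr[nrow(r$roc)], 1)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  # trapezoid over the curve equals the Mann-Whitney AUC
  trap <- sum(diff(r$roc$fpr) *
                (head(r$roc$tpr, -1) + tail(r$roc$tpr, -1)) / 2)
  expect_equal(trap, r$auc)
})

test_that("one-vs-rest ROCs cover each class against the others", {
  truth <- rep(0:2, each = 100)
  sc <- matrix(0, 300, 3, dimnames = list(NULL, 0:2))
  for (k in 0:2) sc[truth == k, as.character(k)] <- 1
  ovr <- one_vs_rest_rocs(truth, sc)
  expect_length(ovr$per_class, 3)
  expect_equal(unname(vapply(ovr$per_class, `[[`, numeric(1), "auc")),
               c(1, 1, 1))

  set.seed(85)
  sc2 <- sc
  sc2[, "2"] <- runif(300)  # destroy class-2 information
  ovr2 <- one_vs_rest_rocs(truth, sc2)
  expect_equal(ovr2$per_class[["2"]]$auc, 0.5, tolerance = 0.25)
  expect_equal(ovr2$per_class[["0"]]$auc, 1)
})

test_that("paired t-test matches hand computation and is antisymmetric", {
  tt <- paired_t_test(c(1, 2, 4), c(0, 1, 2))
  expect_equal(tt$t, 4, tolerance = 1e-12)
  expect_equal(tt$dof, 2)

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$undefined)

  set.seed(87)
  a <- rnorm(26); b <- rnorm(26)
  expect_equal(paired_t_test(a, b)$t, -paired_t_test(b, a)$t)
  expect_equal(paired_t_test(a, b)$dof, 25)
})

test_that("per-feature phase comparisons produce a full marked matrix", {
  feats <- shared_features()
  tab <- assemble(feats, "DST", "ir")
  tab9 <- tab[, c("subject_id", "task", "phase", "label",
                  grep("^Nosetip_", names(tab), value = TRUE))]
  attr(tab9, "class") <- class(tab)
  res <- feature_phase_comparison(tab9)
  expect_equal(nrow(res), 9)  # 9 features x 1 phase pair
  expect_true(all(c("stars", "p_holm") %in% names(res)))

  broken <- tab9[-1, ]
  expect_error(feature_phase_comparison(broken), "unbalanced")
})

test_that("phase effects surface in the nose-tip features", {
  cfg <- synth_config(n_subjects = 10, seed = 77,
                      phase_durations = short_durations,
                      glabella_effect = c(BL = 0, Forward = 0, Backward = 0,
                                          ImmR = 0, DelR = 0, Rec = 0),
                      rr_mean = c(BL = 850, Forward = 850, Backward = 850,
                                  ImmR = 850, DelR = 850, Rec = 850),
                      rr_lf_amp = 20, rr_hf_amp = 25)
  feats <- suppressWarnings(extract_features(generate_cohort(cfg)))
  tab <- assemble(feats, "DST", "multimodal")
  res <- feature_phase_comparison(tab)
  sig <- res$feature[!is.na(res$p) & res$p < 0.05]
  expect_gt(sum(startsWith(sig, "Nosetip_")),
            sum(startsWith(sig, "HRV_")))
})

test_that("evaluation reports bundle confusion, metrics and ROC", {
  toy <- make_toy_table(n_subjects = 13, delta = 8)
  plan <- make_group_folds(unique(toy$subject_id), 5, seed = 2)
  cv <- cross_validate(model_spec("logistic_regression"), toy, plan)
  rep2 <- evaluation_report(cv$predictions)
  expect_s3_class(rep2, "mw_report")
  expect_true(rep2$auc >= 0 && rep2$auc <= 1)
  expect_equal(sum(rep2$confusion), nrow(cv$predictions))
})
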