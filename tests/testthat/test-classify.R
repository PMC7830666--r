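zero_features <- setNames(numeric(7), rr_feature_names())

test_that("scorers evaluate the closed-form sigmoid at known points", {
  s1 <- score_model1(zero_features)
  expect_equal(s1$probability, 1 / (1 + exp(0.45)), tolerance = 1e-12)
  expect_equal(s1$label, "healthy")         # 0.389 < 0.46
  s2 <- score_model2(zero_features)
  expect_equal(s2$probability, 1 / (1 + exp(-3.34)), tolerance = 1e-12)
  expect_equal(s2$label, "af")              # 0.966 > 0.48
})

test_that("scorers are monotone in each feature per its coefficient sign", {
  for (sc in list(model1_scorer(), model2_scorer())) {
    for (feat in names(sc$coefficients)) {
      fv_up <- zero_features; fv_up[feat] <- 0.01
      delta <- score(sc, fv_up)$probability - score(sc, zero_features)$probability
      expect_equal(sign(delta), sign(sc$coefficients[[feat]]))
    }
  }
})

test_that("thresholds are strict: boundary probabilities stay negative", {
  # engineer features giving exactly the threshold probability
  sc <- logistic_scorer(log(0.46 / 0.54), c(glle_2 = 1), threshold = 0.46,
                        positive = "pathology", negative = "healthy")
  out <- score(sc, c(glle_2 = 0))
  expect_equal(out$probability, 0.46)
  expect_equal(out$label, "healthy")
  expect_error(score(model1_scorer(), c(glle_2 = 1)), "glle_0.1")
})

test_that("MCC reproduces the worked confusion matrix and its symmetries", {
  conf <- confusion_counts(TP = 19, FP = 4, TN = 40, FN = 6)
  expect_equal(round(mcc(conf), 2), 0.68)
  # class swap symmetry
  swapped <- confusion_counts(TP = 40, FP = 6, TN = 19, FN = 4)
  expect_equal(mcc(conf), mcc(swapped))
  expect_equal(mcc(confusion_counts(TP = 10, FP = 0, TN = 12, FN = 0)), 1)
  # degenerate all-one-class prediction
  expect_equal(mcc(confusion_counts(TP = 5, FP = 7, TN = 0, FN = 0)), 0)
  expect_error(confusion_counts(-1, 0, 0, 2), "non-negative")
})

test_that("precision-recall AUC behaves at the extremes", {
  prc <- prc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(prc$auc, 1)
  # monotone transform invariance
  prc2 <- prc_auc(qlogis(c(0.9, 0.8, 0.3, 0.1)), c(1, 1, 0, 0))
  expect_equal(prc2$auc, prc$auc)
  # label-independent scores: AUC near the positive prevalence
  set.seed(41)
  y <- rbinom(2000, 1, 0.3)
  s <- runif(2000)
  expect_lt(abs(prc_auc(s, y)$auc - 0.3), 0.05)
  expect_error(prc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("bootstrap AUC interval is seeded and covers the point estimate", {
  set.seed(42)
  y <- rbinom(300, 1, 0.4)
  s <- y * 0.3 + runif(300)
  a <- prc_auc(s, y, n_boot = 200, seed = 7)
  b <- prc_auc(s, y, n_boot = 200, seed = 7)
  expect_identical(a$auc_ci, b$auc_ci)
  expect_gte(a$auc, a$auc_ci[1])
  expect_lte(a$auc, a$auc_ci[2])
})

test_that("stepwise fit recovers the scorer's active features and signs", {
  sim <- sim_scorer_features(2000, seed = 43)
  fit <- fit_stepwise_logistic(sim$features, sim$labels)
  sel <- names(fit$coefficients)
  truth <- model1_scorer()$coefficients
  # the strong features must be selected with the right signs
  for (feat in c("glle_0.1", "glle_4", "glle_5")) {
    expect_true(feat %in% sel)
    expect_equal(sign(fit$coefficients[[feat]]), sign(truth[[feat]]))
  }
  # inactive features stay out
  expect_false(any(c("glle_2", "glle_3") %in% sel))
})

test_that("stepwise fit survives separation and constant columns", {
  set.seed(44)
  x <- data.frame(a = c(rnorm(30, -4), rnorm(30, 4)), const = rep(1, 60),
                  b = rnorm(60))
  y <- rep(c(0, 1), each = 30)
  expect_warning(fit <- fit_stepwise_logistic(x, y), "separation|glm.fit")
  expect_true(all(is.finite(unlist(fit$coefficients))))
  expect_false("const" %in% names(fit$coefficients))
  expect_error(fit_stepwise_logistic(x, rep(1, 60)), "both classes")
})

test_that("feature extraction scales the spectrum by 100 in fixed order", {
  s <- simulate_system("logistic", n_samples = 1500, seed = 45)
  fv <- extract_features(s, embedding_params(2, 1))
  expect_named(fv, rr_feature_names())
  expect_equal(unname(fv["glle_2"]) / 100,
               attr(fv, "spectrum")$glle[attr(fv, "spectrum")$p == 2])
  expect_lt(abs(fv[["glle_2"]] - 69), 5)
})

test_that("scorer round-trips through its flat text serialisation", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_scorer(model1_scorer(), f)
  back <- read_scorer(f)
  expect_equal(back$intercept, model1_scorer()$intercept)
  expect_equal(back$coefficients, model1_scorer()$coefficients)
  expect_equal(back$threshold, 0.46)
  expect_equal(back$positive, "pathology")
})
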