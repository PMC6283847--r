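test_that("a noiseless realizable target is fitted almost exactly", {
  ds <- generate_selection_dataset(n = 50, seed = 2, n_informative = 3,
                                   n_noise = 0, sigma = 0)
  fit <- rrv_fit(ds)
  expect_gt(cor(fit$y_ln, fit$fitted_ln), 0.999)
  pred <- predict(fit, ds)
  expect_gt(cor(log(pred), log(ds$raw$rrv)), 0.999)
  expect_true(all(pred > 0 & is.finite(pred)))
})

test_that("degenerate training inputs raise errors", {
  ds <- generate_selection_dataset(n = 20, seed = 3, sigma = 0)
  ds$raw$rrv <- 50
  ds$raw$ln_rrv <- log(50)
  expect_error(rrv_fit(ds), "constant target")
  ds2 <- generate_selection_dataset(n = 20, seed = 3, sigma = 0)
  expect_error(rrv_fit(ds2, features = "md_bogus"), "unknown feature")
})

test_that("the model surface behaves like a classed fit object", {
  ds <- generate_rrv_dataset(n = 40, seed = 11, sigma = 0.2)
  fit <- rrv_fit(ds)
  expect_s3_class(fit, "rrv_fit")
  expect_output(print(fit), "eps-SVR")
  s <- summary(fit)
  expect_output(print(s), "PCC")
  w <- coef(fit)
  expect_equal(names(w)[1], "(Intercept)")
  expect_true(all(fit$features %in% names(w)))
  expect_length(residuals(fit), 40L)
  expect_equal(residuals(fit), fit$y_ln - fit$fitted_ln)
  # prediction on an all-zero-information row stays finite and positive
  row <- ds$raw[1, ]
  row[glycoplan:::.SHIFT_SLOTS] <- 0
  row[ds$md_cols] <- 0
  expect_gt(predict(fit, row), 0)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("perfect and mean predictors pin the metric definitions", {
  obs <- c(10, 100, 1000, 5000, 20000)
  perfect <- glycoplan:::.eval_report(obs, obs, "manual")
  expect_equal(perfect$pcc, 1)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rae, 0)
  expect_equal(perfect$category_accuracy, 1)
  mean_pred <- glycoplan:::.eval_report(obs, rep(mean(obs), 5), "manual")
  expect_equal(mean_pred$rae, 1)  # RAE is exactly 1 for the mean predictor
})

test_that("LOOCV equals n-fold cross-validation", {
  ds <- generate_rrv_dataset(n = 25, seed = 13, sigma = 0.2)
  a <- cv_evaluate(ds, "loocv")
  b <- cv_evaluate(ds, "kfold", k = 25)
  expect_equal(a$predicted, b$predicted)
  expect_equal(a$pcc, b$pcc)
})

test_that("cross-validation refits preprocessing inside each fold", {
  ds <- generate_rrv_dataset(n = 30, seed = 17, sigma = 0.2)
  # a fold-specific encoder must differ from the full-data encoder when the
  # held-out row carries the global extreme of a shift slot
  i_max <- which.max(ds$raw$H1)
  enc_full <- glycoplan:::fit_encoder(ds)
  enc_fold <- glycoplan:::fit_encoder(ds, rows = setdiff(1:30, i_max))
  expect_lt(enc_fold$cs$slots$H1$max, enc_full$cs$slots$H1$max)
  # and rrv_fit(subset=) uses exactly the fold encoder, not the full one
  fit <- rrv_fit(ds, subset = setdiff(1:30, i_max))
  expect_equal(fit$encoder$cs$slots$H1$max, enc_fold$cs$slots$H1$max)
})

test_that("category thresholds reproduce the published bin assignments", {
  expect_equal(as.character(classify_rrv_category(72000)), "high")
  expect_equal(as.character(classify_rrv_category(1462)), "medium")
  expect_equal(as.character(classify_rrv_category(4000)), "medium")
  # boundary convention: 1,000 is low, 15,000 is medium
  expect_equal(as.character(classify_rrv_category(c(1000, 15000))),
               c("low", "medium"))
  expect_equal(as.character(classify_rrv_category(
    c(850, 263, 132, 51, 32, 18.2, 13))), rep("low", 7))
  expect_error(classify_rrv_category(-1), "non-negative")
})

test_that("backward selection keeps informative features and stops sensibly", {
  # 1 informative + 5 pure noise, noiseless: the informative one survives
  ds <- generate_selection_dataset(n = 50, seed = 21, n_informative = 1,
                                   n_noise = 5, sigma = 0)
  sel <- select_features_backward(ds, seed = 1)
  expect_true(ds$truth$informative %in% sel$selected)
  expect_lte(length(sel$selected), 3L)
  # 2 informative features, no noise: neither is dropped
  ds2 <- generate_selection_dataset(n = 50, seed = 22, n_informative = 2,
                                    n_noise = 0, sigma = 0)
  sel2 <- select_features_backward(ds2, seed = 1)
  expect_setequal(sel2$selected, ds2$truth$informative)
})

test_that("duplicated feature columns: exactly one of the pair survives", {
  ds <- generate_selection_dataset(n = 40, seed = 23, n_informative = 2,
                                   n_noise = 0, sigma = 0)
  ds$raw$md_dup1 <- ds$raw$md_inf1   # exact duplicate column
  ds <- rrv_dataset(config = ds$config, data = ds$raw)
  sel <- select_features_backward(ds, seed = 1)
  expect_equal(sum(c("md_inf1", "md_dup1") %in% sel$selected), 1L)
  # the lexicographically-last of the tied pair is the one dropped
  expect_true("md_dup1" %in% sel$selected)
})

test_that("pinned keep-features survive selection", {
  ds <- generate_selection_dataset(n = 40, seed = 25, n_informative = 2,
                                   n_noise = 4, sigma = 0)
  sel <- select_features_backward(ds, seed = 1, keep = "md_noise1")
  expect_true("md_noise1" %in% sel$selected)
})
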