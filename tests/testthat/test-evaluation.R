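test_that("make_grouped_folds deals patients round-robin", {
  plan <- make_grouped_folds(sprintf("p%02d", 1:20), k = 10, seed = 1)
  sizes <- table(plan$assignment)
  expect_equal(as.numeric(sizes), rep(2, 10))
  # every record of a patient inherits its fold
  recs <- rep(sprintf("p%02d", 7), 15)  # 3 visits x 5 images
  expect_equal(length(unique(fold_of(plan, recs))), 1)
  # determinism and seed sensitivity
  expect_identical(plan$assignment,
                   make_grouped_folds(sprintf("p%02d", 1:20), 10,
                                      seed = 1)$assignment)
  expect_false(identical(
    plan$assignment,
    make_grouped_folds(sprintf("p%02d", 1:20), 10, seed = 2)$assignment))
  # uneven counts differ by at most one patient
  p2 <- make_grouped_folds(sprintf("q%02d", 1:23), k = 10, seed = 3)
  expect_lte(diff(range(table(p2$assignment))), 1)
  expect_error(make_grouped_folds(c("a", "b"), k = 10), "at least k")
})

test_that("aggregate_predictions is the median with even-count mean", {
  expect_equal(aggregate_predictions(c(5.0, 5.2, 6.4)), 5.2)
  expect_equal(aggregate_predictions(c(5.0, 6.0)), 5.5)
  expect_equal(aggregate_predictions(c(5.0, 5.0, 99.0)), 5.0)
  expect_equal(aggregate_predictions(7.1), 7.1)
  expect_error(aggregate_predictions(numeric(0)), "no predictions")
})

test_that("regression_metrics reproduces hand-computed values", {
  r <- regression_metrics(c(4, 6, 8), c(5, 6, 7))
  expect_equal(r$mse, 2 / 3)
  expect_equal(r$r2, 0.75)
  expect_equal(r$residual_sd, 1)
  perfect <- regression_metrics(1:5, 1:5)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$residual_sd, 0)
  # constant prediction at the mean gives r2 = 0
  expect_equal(regression_metrics(c(1, 2, 3), rep(2, 3))$r2, 0)
  expect_error(regression_metrics(rep(2, 3), 1:3), "constant")
  expect_error(regression_metrics(1:3, 1:4), "lengths")
  # permutation invariance
  set.seed(1)
  yt <- rnorm(50, 7)
  yp <- yt + rnorm(50, sd = 0.5)
  p <- sample(50)
  expect_equal(regression_metrics(yt, yp),
               regression_metrics(yt[p], yp[p]))
})

test_that("corridor_confusion counts and per-class accuracies", {
  # printed decision-layer worked example
  true <- rep(c("Red", "Yellow", "Yellow", "Yellow", "Green", "Green"),
              c(3, 15, 7, 1, 6, 13))
  pred <- rep(c("Red", "Red", "Yellow", "Green", "Yellow", "Green"),
              c(3, 15, 7, 1, 6, 13))
  cc <- corridor_confusion(true, pred)
  expect_equal(cc$total_correct, 23)
  expect_equal(cc$n, 45)
  expect_equal(unname(cc$confusion["Yellow", "Red"]), 15)
  expect_equal(unname(cc$per_class_accuracy["Red"]), 1)
  # perfect predictions give a diagonal matrix
  all3 <- rep(corridor_levels(), 4)
  cp <- corridor_confusion(all3, all3)
  expect_equal(unname(diag(cp$confusion)), rep(4L, 3))
  expect_equal(unname(cp$per_class_accuracy), rep(1, 3))
  # empty input: all-zero matrix
  ce <- corridor_confusion(character(0), character(0))
  expect_true(all(ce$confusion == 0))
  expect_error(corridor_confusion("Red", c("Red", "Red")),
               "equal length")
})

test_that("type_error_rates follow the corridor definitions", {
  # all predictions inside the true corridor
  hb <- c(3, 5, 7, 8)
  z <- type_error_rates(hb, hb)
  expect_equal(z$type1, 0)
  expect_equal(unname(z$type2), c(0, 0, 0))
  # 10 true-Red cases, one predicted Green
  mh <- rep(4.0, 10)
  ph <- c(7.0, rep(4.0, 9))
  expect_equal(type_error_rates(mh, ph)$type1, 0.1)
  expect_equal(unname(type_error_rates(mh, ph)$type2[["Red"]]), 0.1)
  # no true Red: rate is absent, not zero
  n <- type_error_rates(c(5, 7), c(5, 7))
  expect_true(is.na(n$type1))
  expect_true(is.na(n$type2[["Red"]]))
  # a Yellow predicted Green counts against Yellow's type 2
  y <- type_error_rates(c(5, 5), c(6.5, 5))
  expect_equal(unname(y$type2[["Yellow"]]), 0.5)
})

test_that("f1_scores reproduce the two-class hand computation", {
  f <- f1_scores(c("Red", "Red", "Green", "Green"),
                 c("Red", "Green", "Green", "Green"))
  expect_equal(unname(f$per_class["Red"]), 2 / 3)
  expect_equal(unname(f$per_class["Green"]), 0.8)
  expect_equal(f$f1_macro, (2 / 3 + 0.8) / 2, tolerance = 1e-12)
  expect_equal(f$f1_weighted, (2 / 3 + 0.8) / 2, tolerance = 1e-12)
  # perfect three-class prediction
  all3 <- rep(corridor_levels(), 5)
  fp <- f1_scores(all3, all3)
  expect_equal(fp$f1_macro, 1)
  expect_equal(fp$f1_weighted, 1)
  # a class present in truth but never predicted scores zero
  fz <- f1_scores(c("Red", "Green"), c("Green", "Green"))
  expect_equal(unname(fz$per_class["Red"]), 0)
})

test_that("cross_validate audits leakage and persists fold metrics", {
  cfg <- cohort_config(n_A = 12, n_B = 8, n_C = 12, seed = 21)
  coh <- generate_cohort(cfg)
  imgs <- render_cohort_images(coh, render_params(images_per_visit = 1),
                               seed = 21)
  fs <- build_feature_set(coh, imgs)
  rep <- cross_validate(fs, family = "ridge", modality = "combined",
                        k = 5, n_components = 4, seed = 21)
  expect_true(rep$leakage_checked)
  # explicit audit: no patient appears in two folds of the predictions
  pid <- sub(" .*", "", rep$predictions$entry)
  expect_true(all(tapply(rep$predictions$fold, pid,
                         function(f) length(unique(f))) == 1))
  expect_equal(nrow(rep$folds), 5)
  expect_true(all(c("residual_sd", "mse", "r2") %in% names(rep$folds)))
  # pooled corridor diagnostics exist
  expect_equal(sum(rep$pooled$confusion$confusion),
               nrow(rep$predictions))
  # determinism of the whole protocol
  rep2 <- cross_validate(fs, family = "ridge", modality = "combined",
                         k = 5, n_components = 4, seed = 21)
  expect_equal(rep$pooled$r2, rep2$pooled$r2)
  # single-modality arm aggregates per-image predictions by entry
  repE <- cross_validate(fs, family = "ridge", modality = "eyelid",
                         k = 5, n_components = 4, seed = 21)
  expect_equal(sort(unique(repE$predictions$entry)),
               sort(unique(paste(coh$patient_id, coh$visit_index))))
})

test_that("classification task reports F1 and confusion", {
  cfg <- cohort_config(n_A = 12, n_B = 10, n_C = 12, seed = 22)
  coh <- generate_cohort(cfg)
  imgs <- render_cohort_images(coh, render_params(images_per_visit = 1),
                               seed = 22)
  fs <- build_feature_set(coh, imgs)
  rep <- cross_validate(fs, family = "ridge", task = "classification",
                        modality = "fingernail", k = 5,
                        n_components = 4, seed = 22)
  expect_true(all(c("f1_weighted", "f1_macro") %in% names(rep$folds)))
  expect_equal(sum(rep$pooled$confusion$confusion),
               nrow(rep$predictions))
  expect_true(all(as.character(rep$predictions$prediction) %in%
                    corridor_levels()))
})
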