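test_that("rgb_to_hue reproduces primary hues and flags achromatic pixels", {
  prim <- rbind(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255),
                c(128, 128, 128))
  h <- rgb_to_hue(prim)
  expect_equal(as.numeric(h), c(0, 120, 240, 0))
  expect_equal(attr(h, "achromatic"), c(FALSE, FALSE, FALSE, TRUE))
  expect_error(rgb_to_hue(matrix(c(300, 0, 0), 1)), "\\[0, 255\\]")
})

test_that("hue_histogram normalizes, bins and excludes correctly", {
  # point mass at 5 degrees
  h1 <- structure(rep(5, 50), achromatic = rep(FALSE, 50))
  g <- hue_histogram(h1, bins = 36)
  expect_equal(g$mass[1], 1)
  expect_equal(sum(g$mass), 1)
  expect_equal(g$n_pixels, 50)
  # half at 5, half at 355: first and last bin
  h2 <- structure(c(rep(5, 25), rep(355, 25)),
                  achromatic = rep(FALSE, 50))
  g2 <- hue_histogram(h2, bins = 36)
  expect_equal(g2$mass[c(1, 36)], c(0.5, 0.5))
  # mass conservation and permutation invariance on random hues
  set.seed(1)
  hr <- structure(runif(500, 0, 360), achromatic = rep(FALSE, 500))
  ga <- hue_histogram(hr)
  expect_equal(sum(ga$mass), 1, tolerance = 1e-9)
  hp <- structure(sample(as.numeric(hr)), achromatic = rep(FALSE, 500))
  expect_equal(hue_histogram(hp)$mass, ga$mass)
  # achromatic exclusion and empty-ROI error
  h3 <- structure(rep(0, 10), achromatic = rep(TRUE, 10))
  expect_error(hue_histogram(h3), "empty ROI")
  expect_error(hue_histogram(h1, mask = rep(FALSE, 50)), "empty ROI")
})

test_that("fit_pca recovers a known principal direction", {
  set.seed(3)
  t <- rnorm(200)
  X <- cbind(t / sqrt(2), t / sqrt(2)) +
    matrix(rnorm(400, sd = 0.01), 200, 2)
  m <- fit_pca(X, 1)
  expect_equal(abs(m$components[, 1]), c(1, 1) / sqrt(2),
               tolerance = 1e-2)
  # sign convention: largest-magnitude loading positive
  expect_gt(m$components[which.max(abs(m$components[, 1])), 1], 0)
})

test_that("complete basis reconstructs exactly; duplicates score equally", {
  set.seed(4)
  X <- matrix(rnorm(60), 10, 6)
  m <- fit_pca(X, 6)
  sc <- project_features(X, m)
  rec <- sweep(sc %*% t(m$components), 2, m$mean_vector, "+")
  expect_equal(rec, X, tolerance = 1e-9, ignore_attr = TRUE)
  Xd <- X[c(1, 1, 2:10), ]
  md <- fit_pca(Xd, 3)
  sd_ <- project_features(Xd, md)
  expect_equal(sd_[1, ], sd_[2, ])
})

test_that("fit_pca matches a covariance-eigendecomposition oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(60), 10, 6)
    m <- fit_pca(X, 4)
    # orthonormal loadings
    expect_equal(t(m$components) %*% m$components, diag(4),
                 tolerance = 1e-8, ignore_attr = TRUE)
    ev <- eigen(cov(X))$vectors[, 1:4]
    for (j in 1:4) {
      agree <- min(max(abs(m$components[, j] - ev[, j])),
                   max(abs(m$components[, j] + ev[, j])))
      expect_lt(agree, 1e-6)
    }
  }
})

test_that("fit_pca validates rank and dimensions", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pca(X, 3), "1 <= k")
  expect_error(fit_pca(X[1:2, ], 2), "N > k")
  Xr <- cbind(1:10, 2 * (1:10), rnorm(10) * 0)  # rank 1 after centering
  expect_error(fit_pca(Xr, 2), "rank")
  expect_equal(pca_max_components(Xr), 1L)
})

test_that("projection centers, appends metadata and checks dimensions", {
  set.seed(6)
  X <- matrix(rnorm(80), 20, 4)
  m <- fit_pca(X, 2)
  # the mean vector projects to zero scores
  expect_equal(as.numeric(project_features(m$mean_vector, m)), c(0, 0))
  # brute-force dot-product oracle on a fixed histogram
  hfix <- X[3, ]
  want <- as.numeric(t(m$components) %*% (hfix - m$mean_vector))
  expect_equal(as.numeric(project_features(hfix, m)), want)
  # reconstruction error is non-increasing in k
  errs <- vapply(1:4, function(k) {
    mk <- fit_pca(X, k)
    sck <- project_features(X, mk)
    rec <- sweep(sck %*% t(mk$components), 2, mk$mean_vector, "+")
    sqrt(mean((rec - X)^2))
  }, 0.0)
  expect_true(all(diff(errs) <= 1e-12))
  # metadata pass-through and errors
  withmeta <- project_features(X, m, metadata = cbind(age = 1:20))
  expect_equal(colnames(withmeta), c("score_1", "score_2", "age"))
  expect_error(project_features(X[, 1:3], m), "does not match")
  expect_error(project_features(X, m, metadata = cbind(age = 1:3)),
               "one row per histogram")
})

test_that("first PCA score tracks Hb on synthetic hue histograms", {
  cfg <- cohort_config(n_A = 40, n_B = 25, n_C = 40, seed = 9)
  coh <- generate_cohort(cfg)
  imgs <- render_cohort_images(coh, render_params(images_per_visit = 1),
                               seed = 9)
  fs <- build_feature_set(coh, imgs)
  rows <- fs$info$modality == "fingernail"
  m <- fit_pca(fs$hist[rows, ], 2)
  sc <- project_features(fs$hist[rows, ], m)
  expect_gt(abs(cor(sc[, 1], fs$info$hb_true[rows])), 0.8)
})
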