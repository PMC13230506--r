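test_that("generate_cohort respects counts, thresholds and determinism", {
  cfg <- cohort_config(seed = 42)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 551)
  expect_equal(sum(coh$subgroup %in% c("B", "C")), 367)
  # anemia threshold is respected by construction
  expect_lt(max(coh$hb_true[coh$subgroup == "B"]), 6.21)
  expect_gt(min(coh$hb_true[coh$subgroup == "C"]), 6.21)
  expect_true(all(coh$hb_true > 0))
  # bit-identical rerun
  expect_identical(coh, generate_cohort(cfg))
  # different seed differs
  expect_false(identical(coh$hb_true,
                         generate_cohort(cohort_config(seed = 43))$hb_true))
  # repeated visits share patient_id with distinct visit_index
  expect_false(any(duplicated(paste(coh$patient_id, coh$visit_index))))
})

test_that("empty cohort and invalid configs are handled", {
  expect_equal(nrow(generate_cohort(cohort_config(0, 0, 0))), 0)
  expect_error(cohort_config(n_A = -1), "non-negative")
  expect_error(cohort_config(visit_repeat_prob = 1.5), "\\[0, 1\\]")
  bad <- default_hb_params()
  bad$lower[1] <- bad$upper[1] + 1
  expect_error(cohort_config(hb_params = bad), "ordered")
})

test_that("per-subgroup sample medians hit their configured targets", {
  coh <- generate_cohort(cohort_config(seed = 7))
  targets <- c(A = 8.6, B = 5.2, C = 7.9)
  for (g in names(targets)) {
    expect_lt(abs(median(coh$hb_true[coh$subgroup == g]) - targets[[g]]),
              0.3)
  }
})

test_that("generate_qol links scores to Hb and clips to [0, 100]", {
  link0 <- default_qol_link()
  link0$global_health[["noise_sd"]] <- 0
  link0$fatigue[["noise_sd"]] <- 0
  hb <- seq(4, 9, by = 0.5)
  q <- generate_qol(hb, link0, seed = 1)
  # exact linear link at zero noise
  expect_equal(q$global_health, 8 + 7.5 * hb, tolerance = 1e-12)
  expect_equal(q$fatigue, 95 - 7.5 * hb, tolerance = 1e-12)
  # zero-noise regression recovers the configured slope exactly
  expect_equal(unname(coef(lm(q$global_health ~ hb))[2]), 7.5,
               tolerance = 1e-9)
  # clipping bound at extreme Hb
  expect_equal(generate_qol(20, link0, seed = 1)$global_health, 100)
  # determinism and noisy direction
  qn <- generate_qol(hb, seed = 5)
  expect_identical(qn, generate_qol(hb, seed = 5))
  expect_true(all(qn$global_health >= 0 & qn$global_health <= 100))
  expect_error(generate_qol(-1), "positive")
})

test_that("assign_clinician_label follows the documented escalation rule", {
  expect_equal(assign_clinician_label(7.5, 5), "Green")
  expect_equal(assign_clinician_label(4.0, 10), "Red")
  expect_equal(assign_clinician_label(4.0, 90), "Red")
  # Yellow Hb + low-QoL fatigue band escalates one level
  expect_equal(assign_clinician_label(5.0, 60), "Red")
  expect_equal(assign_clinician_label(5.0, 20), "Yellow")
  expect_equal(assign_clinician_label(5.0, NA), "Yellow")
  # monotone in hb at fixed fatigue
  sev <- function(x) match(x, c("Green", "Yellow", "Red"))
  for (ft in c(0, 20, 45, 80)) {
    labs <- assign_clinician_label(seq(8, 3.5, by = -0.25), ft)
    expect_true(all(diff(sev(labs)) >= 0))
  }
  expect_error(assign_clinician_label(5, 150), "\\[0, 100\\]")
})

test_that("QoL subset size and missingness knobs work", {
  coh <- generate_cohort(cohort_config(qol_subset = 49,
                                       qol_missing_prob = 0.02,
                                       seed = 3))
  pats <- unique(coh$patient_id[!is.na(coh$qol_fatigue) |
                                  !is.na(coh$qol_global_health)])
  expect_lte(length(pats), 49)
  expect_gt(length(pats), 40)
  # clinician labels only where fatigue is observed
  expect_true(all(is.na(coh$clinician_label) | !is.na(coh$qol_fatigue)))
  none <- generate_cohort(cohort_config(qol_subset = 0, seed = 3))
  expect_true(all(is.na(none$qol_fatigue)))
})

test_that("rendered images obey the hue link and mask containment", {
  p0 <- render_params(pixel_hue_sd = 0, image_hue_sd = 0,
                      lighting_gain_sd = 0)
  entry <- list(patient_id = "P1", visit_index = 0L, hb_true = 7)
  imgs <- render_visit_images(entry, p0, seed = 2)
  expect_length(imgs, 2 * p0$images_per_visit)
  for (s in imgs) {
    expect_true(all(s$pixels >= 0 & s$pixels <= 255))
    tm <- s$ground_truth$true_mask
    cm <- s$coarse_mask
    # coarse mask strictly contains the true ROI plus a rim
    expect_true(all(tm[cm == FALSE] == FALSE))
    expect_gt(sum(cm), sum(tm))
    # zero noise: mean ROI hue equals the link value (8-bit quantization)
    h <- rgb_to_hue(s$pixels)
    expect_equal(mean(h[as.vector(tm)]), hue_link(7, p0),
                 tolerance = 0.01)
  }
  # monotone link direction: higher Hb -> lower (red-ward) hue
  lo <- render_visit_images(list(patient_id = "a", visit_index = 0L,
                                 hb_true = 4), p0, seed = 3)[[1]]
  hi <- render_visit_images(list(patient_id = "b", visit_index = 0L,
                                 hb_true = 9), p0, seed = 3)[[1]]
  mh <- function(s) mean(rgb_to_hue(s$pixels)[
    as.vector(s$ground_truth$true_mask)])
  expect_gt(mh(lo), mh(hi))
  # determinism
  expect_identical(render_visit_images(entry, p0, seed = 2), imgs)
  expect_error(render_visit_images(list(patient_id = "x"), p0), "hb_true")
})

test_that("unit conversion round-trips", {
  expect_equal(gdl_to_mmol(mmol_to_gdl(6.21)), 6.21)
  expect_equal(mmol_to_gdl(1.02), 1.64, tolerance = 0.005)
})
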