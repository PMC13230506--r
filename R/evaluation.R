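#' Patient-grouped fold assignment
#'
#' Shuffles the distinct patient IDs with the seeded RNG and deals them
#' round-robin into `k` folds, so fold sizes differ by at most one
#' patient and every record of a patient inherits that patient's fold —
#' the grouping that prevents information leakage between training and
#' validation.
#'
#' @param patient_ids character vector (repeats allowed).
#' @param k number of folds.
#' @param seed integer seed.
#' @return object of class `fold_plan`: `k`, `assignment` (named integer
#'   vector patient -> fold), `seed`.
#' @export
make_grouped_folds <- function(patient_ids, k = 10, seed = 1L) {
  ids <- unique(as.character(patient_ids))
  if (length(ids) < k) {
    stop(sprintf("need at least k = %d distinct patients, got %d",
                 k, length(ids)))
  }
  assignment <- with_seed(substream_seed(seed, "folds"), {
    perm <- sample(ids)
    stats::setNames(rep_len(seq_len(k), length(perm)), perm)
  })
  structure(list(k = as.integer(k), assignment = assignment,
                 seed = as.integer(seed)), class = "fold_plan")
}

#' Fold index of each record
#'
#' @param plan a [make_grouped_folds()] plan.
#' @param patient_ids record-level patient IDs.
#' @return integer fold per record.
#' @export
fold_of <- function(plan, patient_ids) {
  unname(plan$assignment[as.character(patient_ids)])
}

#' Aggregate per-image predictions into one entry-level prediction
#'
#' The median over the available per-image predictions (even counts use
#' the mean of the two central values), robust to single outlier images.
#'
#' @param per_image_preds numeric vector with at least one value.
#' @return single numeric prediction.
#' @export
aggregate_predictions <- function(per_image_preds) {
  if (length(per_image_preds) == 0) stop("no predictions to aggregate")
  median(per_image_preds)
}

#' Regression error metrics
#'
#' `residual_sd` is the standard deviation (denominator `n - 1`) of the
#' residuals `y_pred - y_true`; `mse` the mean squared residual; `r2`
#' the proportion of variance explained, `1 - SSres / SStot` (negative
#' values are possible on validation data and are not clipped).
#'
#' @param y_true,y_pred equal-length numeric vectors, length >= 2.
#' @return list with `residual_sd`, `mse`, `r2`.
#' @export
#' @examples
#' regression_metrics(c(4, 6, 8), c(5, 6, 7))  # mse 2/3, r2 0.75
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("lengths differ")
  if (length(y_true) < 2) stop("need at least 2 pairs")
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("constant y_true: R^2 is undefined")
  resid <- y_pred - y_true
  list(residual_sd = sd(resid), mse = mean(resid^2),
       r2 = 1 - sum(resid^2) / sst)
}

#' Corridor confusion matrix
#'
#' 3 x 3 counts with rows = true and columns = predicted corridor, in
#' severity order Red, Yellow, Green. Per-corridor accuracy is the
#' diagonal count over the row sum (`NA` for empty rows).
#'
#' @param true_corridors,pred_corridors corridor label vectors.
#' @return list with `confusion` (3 x 3 matrix), `per_class_accuracy`,
#'   `total_correct`, `n`.
#' @export
corridor_confusion <- function(true_corridors, pred_corridors) {
  check_corridor(true_corridors, "true_corridors")
  check_corridor(pred_corridors, "pred_corridors")
  if (length(true_corridors) != length(pred_corridors)) {
    stop("label vectors must have equal length")
  }
  lv <- corridor_levels()
  tab <- table(factor(true_corridors, levels = lv),
               factor(pred_corridors, levels = lv))
  conf <- matrix(as.integer(tab), 3, 3, dimnames = list(true = lv,
                                                        predicted = lv))
  rs <- rowSums(conf)
  acc <- ifelse(rs > 0, diag(conf) / rs, NA_real_)
  names(acc) <- lv
  list(confusion = conf, per_class_accuracy = acc,
       total_correct = sum(diag(conf)), n = sum(conf))
}

#' Corridor-level Type-1 and Type-2 error rates
#'
#' Both measured and predicted hemoglobin are discretized with
#' [hb_to_corridor()]. Type 1 is the clinically critical false-negative
#' direction: the fraction of true-Red cases predicted Green. Type 2, per
#' corridor, is the fraction of cases in that corridor predicted strictly
#' less severe (Green < Yellow < Red). Rates with an empty denominator
#' are reported as `NA`, not 0.
#'
#' @param measured_hb,predicted_hb paired hemoglobin values (mmol/L).
#' @return list with `type1` and `type2` (named per corridor).
#' @export
type_error_rates <- function(measured_hb, predicted_hb) {
  if (length(measured_hb) != length(predicted_hb)) stop("lengths differ")
  tc <- hb_to_corridor(measured_hb)
  pc <- hb_to_corridor(predicted_hb)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  type1 <- rate(sum(tc == "Red" & pc == "Green"), sum(tc == "Red"))
  sev_t <- corridor_severity(tc)
  sev_p <- corridor_severity(pc)
  type2 <- vapply(corridor_levels(), function(cl) {
    in_c <- tc == cl
    rate(sum(in_c & sev_p < corridor_severity(cl)), sum(in_c))
  }, 0.0)
  list(type1 = type1, type2 = type2)
}

#' Weighted and macro F1 scores
#'
#' Per-class F1 is `2PR / (P + R)`, with 0 when precision and recall are
#' both zero. Classes absent from both the true and predicted labels are
#' excluded; the macro score is the unweighted mean over the remaining
#' classes and the weighted score is the support-weighted mean.
#'
#' @param true_corridors,pred_corridors corridor label vectors.
#' @return list with `per_class` (named, `NA` for absent classes),
#'   `f1_macro`, `f1_weighted`.
#' @export
f1_scores <- function(true_corridors, pred_corridors) {
  check_corridor(true_corridors, "true_corridors")
  check_corridor(pred_corridors, "pred_corridors")
  if (length(true_corridors) != length(pred_corridors)) {
    stop("label vectors must have equal length")
  }
  lv <- corridor_levels()
  present <- lv[lv %in% c(true_corridors, pred_corridors)]
  per_class <- stats::setNames(rep(NA_real_, 3), lv)
  support <- stats::setNames(rep(0L, 3), lv)
  for (cl in present) {
    tp <- sum(true_corridors == cl & pred_corridors == cl)
    np <- sum(pred_corridors == cl)
    nt <- sum(true_corridors == cl)
    prec <- if (np > 0) tp / np else 0
    rec <- if (nt > 0) tp / nt else 0
    per_class[cl] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec)
                     else 0
    support[cl] <- nt
  }
  f1_macro <- mean(per_class[present])
  w <- support[present]
  f1_weighted <- if (sum(w) > 0) sum(per_class[present] * w) / sum(w)
                 else NA_real_
  list(per_class = per_class, f1_macro = f1_macro,
       f1_weighted = f1_weighted)
}
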