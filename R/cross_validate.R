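#' Build hue-histogram features for a cohort's images
#'
#' Refines each image's ROI (unless pre-refined masks are supplied),
#' converts the ROI pixels to hue and summarizes them as a normalized
#' histogram. Histograms are kept un-compressed here; the principal
#' component step runs inside each cross-validation training fold (see
#' [cross_validate()]) to avoid leakage.
#'
#' @param cohort an [generate_cohort()] cohort.
#' @param images list of `image_sample` objects.
#' @param refined optional list of refinement results ([refine_roi()]);
#'   computed when `NULL`.
#' @param bins histogram bin count.
#' @return object of class `hb_feature_set`: `hist` (N x bins matrix),
#'   `info` (data.frame: patient_id, visit_index, modality, hb_true,
#'   age, sex), `bins`.
#' @export
build_feature_set <- function(cohort, images, refined = NULL, bins = 36) {
  n <- length(images)
  if (is.null(refined)) refined <- lapply(images, refine_roi)
  hist_mat <- matrix(NA_real_, n, bins)
  info <- data.frame(patient_id = character(n),
                     visit_index = integer(n),
                     modality = character(n),
                     hb_true = NA_real_, age = NA_real_,
                     sex = NA_character_)
  key <- paste(cohort$patient_id, cohort$visit_index)
  for (i in seq_len(n)) {
    s <- images[[i]]
    hues <- rgb_to_hue(s$pixels)
    hist_mat[i, ] <- hue_histogram(hues, mask = refined[[i]]$mask,
                                   bins = bins)$mass
    j <- match(paste(s$entry_ref$patient_id, s$entry_ref$visit_index),
               key)
    if (is.na(j)) stop("image refers to an entry missing from the cohort")
    info$patient_id[i] <- s$entry_ref$patient_id
    info$visit_index[i] <- s$entry_ref$visit_index
    info$modality[i] <- s$modality
    info$hb_true[i] <- cohort$hb_true[j]
    info$age[i] <- cohort$age[j]
    info$sex[i] <- cohort$sex[j]
  }
  structure(list(hist = hist_mat, info = info, bins = bins),
            class = "hb_feature_set")
}

# majority label with the conservative severity tie-break, for
# aggregating per-image class predictions to one entry-level label
aggregate_labels <- function(labels) {
  counts <- vapply(corridor_levels(), function(l) sum(labels == l), 0L)
  names(counts)[counts == max(counts)][1L]
}

# Fit per-modality PCA on training rows only and score all rows of that
# modality. The component count is capped at the numerical rank of the
# training matrix (narrow hue distributions occupy few bins).
score_by_modality <- function(hist_u, info_u, val, mods, n_components) {
  out <- list()
  for (m in mods) {
    rows_m <- which(info_u$modality == m)
    tr_hist <- hist_u[rows_m[!val[rows_m]], , drop = FALSE]
    k_m <- min(n_components, pca_max_components(tr_hist))
    pca <- fit_pca(tr_hist, k = k_m)
    sc <- project_features(hist_u[rows_m, , drop = FALSE], pca)
    out[[m]] <- list(rows = rows_m, scores = sc, pca = pca)
  }
  out
}

# entry-level design matrix: per modality, the column-wise median of
# that entry's per-image PCA scores, concatenated; entries missing one
# of the modalities are dropped
combined_entry_features <- function(scored, key, entry_keys,
                                    meta = NULL) {
  feats <- list()
  keep <- character(0)
  for (ek in entry_keys) {
    parts <- list()
    ok <- TRUE
    for (m in names(scored)) {
      pos <- which(key[scored[[m]]$rows] == ek)
      if (length(pos) == 0) { ok <- FALSE; break }
      parts[[m]] <- apply(scored[[m]]$scores[pos, , drop = FALSE], 2,
                          median)
    }
    if (!ok) next
    feats[[ek]] <- unlist(parts)
    keep <- c(keep, ek)
  }
  if (length(feats) == 0) return(list(X = NULL, keys = character(0)))
  X <- do.call(rbind, feats)
  if (!is.null(meta)) {
    X <- cbind(X, meta[match(keep, rownames(meta)), , drop = FALSE])
  }
  list(X = X, keys = keep)
}

#' Patient-grouped cross-validated evaluation
#'
#' Runs the full modelling protocol: patient-grouped `k`-fold splits
#' ([make_grouped_folds()]), per-fold PCA compression of the hue
#' histograms (fitted on training images only, capped at the training
#' matrix rank), model fitting (ridge or gradient-boosted trees),
#' per-image prediction, median aggregation to one prediction per
#' (patient, visit) entry within the validation fold, and the metric
#' suite. A leakage audit asserts on every fold that the train and
#' validation patient sets are disjoint.
#'
#' For the combined modality arm, entry-level features are the
#' concatenation of the per-modality median PCA scores and both fitting
#' and prediction operate at the entry level; single-modality arms fit
#' per image and aggregate predictions afterwards.
#'
#' Metrics are reported twice: pooled over all validation entries, and
#' as the mean of per-fold values (with the fold-level values persisted
#' in `$folds`).
#'
#' @param fset a [build_feature_set()] feature set.
#' @param family `"gbm"` or `"ridge"`.
#' @param task `"regression"` (continuous Hb) or `"classification"`
#'   (direct three-corridor classification).
#' @param modality `"combined"`, `"eyelid"` or `"fingernail"`.
#' @param k fold count.
#' @param n_components PCA components per modality (upper bound).
#' @param seed fold-assignment seed.
#' @param lambda ridge penalty.
#' @param gbm_control named list overriding [fit_gbm()] defaults.
#' @param include_metadata append standardized age and a sex indicator
#'   to the feature vector.
#' @return object of class `hb_eval_report`.
#' @export
cross_validate <- function(fset, family = c("gbm", "ridge"),
                           task = c("regression", "classification"),
                           modality = c("combined", "eyelid",
                                        "fingernail"),
                           k = 10, n_components = 8, seed = 1L,
                           lambda = 1, gbm_control = list(),
                           include_metadata = FALSE) {
  family <- match.arg(family)
  task <- match.arg(task)
  modality <- match.arg(modality)
  stopifnot(inherits(fset, "hb_feature_set"))
  info <- fset$info
  mods <- if (modality == "combined") c("eyelid", "fingernail")
          else modality
  use <- info$modality %in% mods
  info_u <- info[use, , drop = FALSE]
  hist_u <- fset$hist[use, , drop = FALSE]
  plan <- make_grouped_folds(info_u$patient_id, k = k, seed = seed)
  fold_img <- fold_of(plan, info_u$patient_id)
  key <- paste(info_u$patient_id, info_u$visit_index)

  fit_one <- function(X, y) {
    if (task == "classification") {
      do.call(fit_classifier,
              c(list(X = X, corridor_labels = hb_to_corridor(y),
                     family = family),
                if (family == "ridge") list(lambda = lambda)
                else gbm_control))
    } else if (family == "ridge") {
      fit_ridge(X, y, lambda = lambda)
    } else {
      do.call(fit_gbm, c(list(X = X, y = y), gbm_control))
    }
  }

  meta_mat <- NULL
  if (include_metadata) {
    meta_mat <- cbind(age = info_u$age,
                      sex_female = as.numeric(info_u$sex == "female"))
  }

  preds <- list()
  fold_rows <- list()
  for (f in seq_len(plan$k)) {
    val <- fold_img == f
    train_pat <- unique(info_u$patient_id[!val])
    val_pat <- unique(info_u$patient_id[val])
    if (length(intersect(train_pat, val_pat)) > 0) {
      stop("leakage audit failed: patient in both train and validation")
    }
    scored <- score_by_modality(hist_u, info_u, val, mods, n_components)
    meta_sc <- NULL
    if (include_metadata) {
      mu_age <- mean(meta_mat[!val, "age"])
      sd_age <- sd(meta_mat[!val, "age"])
      meta_sc <- cbind(age = (meta_mat[, "age"] - mu_age) /
                         max(sd_age, 1e-12),
                       sex_female = meta_mat[, "sex_female"])
      rownames(meta_sc) <- key
    }

    if (modality == "combined") {
      tr <- combined_entry_features(scored, key, unique(key[!val]),
                                    meta_sc)
      va <- combined_entry_features(scored, key, unique(key[val]),
                                    meta_sc)
      y_of <- function(keys) info_u$hb_true[match(keys, key)]
      model <- fit_one(tr$X, y_of(tr$keys))
      pred <- predict(model, va$X)
      preds[[f]] <- data.frame(fold = f, entry = va$keys,
                               y_true = y_of(va$keys),
                               prediction = I(as.vector(pred)),
                               stringsAsFactors = FALSE)
    } else {
      sc <- scored[[mods]]
      ord_val <- val[sc$rows]
      Xall <- sc$scores
      if (!is.null(meta_sc)) {
        Xall <- cbind(Xall, meta_sc[sc$rows, , drop = FALSE])
      }
      y_all <- info_u$hb_true[sc$rows]
      model <- fit_one(Xall[!ord_val, , drop = FALSE], y_all[!ord_val])
      img_pred <- predict(model, Xall[ord_val, , drop = FALSE])
      va_key <- key[sc$rows][ord_val]
      ek <- unique(va_key)
      agg <- if (task == "classification") {
        vapply(ek, function(e) aggregate_labels(img_pred[va_key == e]),
               character(1))
      } else {
        vapply(ek, function(e)
          aggregate_predictions(img_pred[va_key == e]), 0.0)
      }
      preds[[f]] <- data.frame(fold = f, entry = ek,
                               y_true = info_u$hb_true[match(ek, key)],
                               prediction = I(unname(agg)),
                               stringsAsFactors = FALSE)
    }
    pf <- preds[[f]]
    fold_rows[[f]] <- if (task == "regression") {
      rm_ <- regression_metrics(pf$y_true, as.numeric(pf$prediction))
      data.frame(fold = f, n_entries = nrow(pf),
                 residual_sd = rm_$residual_sd, mse = rm_$mse,
                 r2 = rm_$r2)
    } else {
      fs <- f1_scores(hb_to_corridor(pf$y_true),
                      as.character(pf$prediction))
      data.frame(fold = f, n_entries = nrow(pf),
                 f1_weighted = fs$f1_weighted, f1_macro = fs$f1_macro)
    }
  }

  all_pred <- do.call(rbind, preds)
  folds_df <- do.call(rbind, fold_rows)
  fold_mean <- colMeans(folds_df[, setdiff(names(folds_df),
                                           c("fold", "n_entries")),
                                 drop = FALSE])
  y_true <- all_pred$y_true
  if (task == "regression") {
    y_pred <- as.numeric(all_pred$prediction)
    pooled <- regression_metrics(y_true, y_pred)
    pooled$confusion <- corridor_confusion(hb_to_corridor(y_true),
                                           hb_to_corridor(y_pred))
    pooled$f1 <- f1_scores(hb_to_corridor(y_true),
                           hb_to_corridor(y_pred))
    pooled$type_errors <- type_error_rates(y_true, y_pred)
  } else {
    y_pred <- as.character(all_pred$prediction)
    pooled <- list(confusion = corridor_confusion(hb_to_corridor(y_true),
                                                  y_pred),
                   f1 = f1_scores(hb_to_corridor(y_true), y_pred))
  }
  structure(list(task = task, family = family, modality = modality,
                 k = plan$k, seed = seed, folds = folds_df,
                 fold_mean = as.list(fold_mean), pooled = pooled,
                 predictions = all_pred, fold_plan = plan,
                 leakage_checked = TRUE),
            class = "hb_eval_report")
}

#' @export
print.hb_eval_report <- function(x, ...) {
  cat(sprintf("Cross-validated %s (%s, %s arm, k = %d)\n",
              x$task, x$family, x$modality, x$k))
  if (x$task == "regression") {
    cat(sprintf("  pooled: residual SD %.3f mmol/L, MSE %.3f, R2 %.3f\n",
                x$pooled$residual_sd, x$pooled$mse, x$pooled$r2))
    cat(sprintf("  fold-mean R2 %.3f over %d folds\n",
                x$fold_mean$r2, nrow(x$folds)))
  } else {
    cat(sprintf("  pooled: F1 weighted %.3f, macro %.3f\n",
                x$pooled$f1$f1_weighted, x$pooled$f1$f1_macro))
  }
  invisible(x)
}
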