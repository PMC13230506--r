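#' End-to-end run configuration
#'
#' Bundles the settings of every pipeline stage. `stages` selects which
#' stages run; each stage consumes the in-memory outputs of the previous
#' ones, so the selected stages must form a prefix of
#' simulate, refine, featurize, fit, evaluate, decide.
#'
#' @param cohort a [cohort_config()].
#' @param render a [render_params()].
#' @param modality `"combined"`, `"eyelid"` or `"fingernail"`.
#' @param family `"gbm"` or `"ridge"`.
#' @param task `"regression"` or `"classification"`.
#' @param k,n_components,lambda,gbm_control,include_metadata passed to
#'   [cross_validate()].
#' @param bins histogram bin count.
#' @param seed master seed (also used for fold assignment).
#' @param out_dir output directory for artifacts.
#' @param stages character vector of stages to run.
#' @param write_images write rendered images (PPM), coarse and refined
#'   masks (PGM) and ground-truth sidecars (JSON) to disk.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       render = render_params(),
                       modality = "combined", family = "gbm",
                       task = "regression", k = 10, n_components = 8,
                       lambda = 1, gbm_control = list(),
                       include_metadata = FALSE, bins = 36, seed = 1L,
                       out_dir = tempfile("hbimage_run_"),
                       stages = c("simulate", "refine", "featurize",
                                  "fit", "evaluate", "decide"),
                       write_images = TRUE) {
  all_stages <- c("simulate", "refine", "featurize", "fit", "evaluate",
                  "decide")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!identical(stages, all_stages[seq_along(stages)])) {
    stop("stages must form a prefix of: ",
         paste(all_stages, collapse = ", "))
  }
  modality <- match.arg(modality, c("combined", "eyelid", "fingernail"))
  family <- match.arg(family, c("gbm", "ridge"))
  task <- match.arg(task, c("regression", "classification"))
  structure(list(cohort = cohort, render = render, modality = modality,
                 family = family, task = task, k = k,
                 n_components = n_components, lambda = lambda,
                 gbm_control = gbm_control,
                 include_metadata = include_metadata, bins = bins,
                 seed = as.integer(seed), out_dir = out_dir,
                 stages = stages, write_images = write_images),
            class = "run_config")
}

#' Small demonstration configuration
#'
#' A 60-entry cohort (20 donors, 15 anemic and 25 non-anemic patients)
#' with one image per modality per visit and 5 folds; runs end-to-end in
#' well under a minute.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @return a [run_config()].
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("hbimage_demo_")) {
  run_config(
    cohort = cohort_config(n_A = 20, n_B = 15, n_C = 25,
                           qol_subset = 12, seed = seed),
    render = render_params(images_per_visit = 1),
    k = 5, gbm_control = list(n_trees = 150), seed = seed,
    out_dir = out_dir)
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' simulate -> refine -> featurize -> fit -> evaluate -> decide, writing
#' artifacts (CSV / JSON / PPM / PGM) under `config$out_dir` and a
#' manifest listing every artifact with its MD5 content hash. Identical
#' configuration and seed reproduce identical metric outputs.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  note <- function(name, path) artifacts[[name]] <<- path

  config$cohort$seed <- config$seed
  cohort <- NULL; images <- NULL; refined <- NULL; fset <- NULL
  report <- NULL

  if ("simulate" %in% config$stages) {
    stage_try("simulate", {
      cohort <- generate_cohort(config$cohort)
      images <- render_cohort_images(cohort, config$render, config$seed)
      p <- file.path(out, "cohort.csv")
      write.csv(as.data.frame(cohort), p, row.names = FALSE)
      note("cohort", p)
      if (config$write_images) {
        img_dir <- file.path(out, "images")
        dir.create(img_dir, showWarnings = FALSE)
        for (i in seq_along(images)) {
          s <- images[[i]]
          stem <- sprintf("%s_v%d_%s_%03d", s$entry_ref$patient_id,
                          s$entry_ref$visit_index, s$modality, i)
          write_ppm(s$pixels, file.path(img_dir, paste0(stem, ".ppm")))
          write_pgm(s$coarse_mask,
                    file.path(img_dir, paste0(stem, "_coarse.pgm")))
          gt <- s$ground_truth
          write_json(list(hue = gt$hue, hue_offset = gt$hue_offset,
                          lighting_gain = gt$lighting_gain,
                          geometry = gt$geometry),
                     file.path(img_dir, paste0(stem, "_truth.json")))
        }
        note("images_dir", img_dir)
      }
    })
  }

  if ("refine" %in% config$stages) {
    stage_try("refine", {
      refined <- lapply(images, refine_roi)
      summary <- lapply(seq_along(refined), function(i) {
        r <- refined[[i]]
        list(index = i, modality = images[[i]]$modality,
             method = r$method,
             retained_fraction = r$retained_fraction,
             circle = if (!is.null(r$circle) && isTRUE(r$circle$found)) {
               list(row = r$circle$row, col = r$circle$col,
                    radius = r$circle$radius, score = r$circle$score)
             })
      })
      p <- file.path(out, "refinement.json")
      write_json(summary, p)
      note("refinement", p)
      if (config$write_images) {
        img_dir <- file.path(out, "images")
        for (i in seq_along(refined)) {
          s <- images[[i]]
          stem <- sprintf("%s_v%d_%s_%03d", s$entry_ref$patient_id,
                          s$entry_ref$visit_index, s$modality, i)
          write_pgm(refined[[i]]$mask,
                    file.path(img_dir, paste0(stem, "_refined.pgm")))
        }
      }
    })
  }

  if ("featurize" %in% config$stages) {
    stage_try("featurize", {
      fset <- build_feature_set(cohort, images, refined,
                                bins = config$bins)
      # exploratory whole-data PCA for the feature table; the evaluation
      # stage refits PCA inside each training fold
      tabs <- list()
      for (m in unique(fset$info$modality)) {
        rows <- fset$info$modality == m
        k_m <- min(config$n_components,
                   pca_max_components(fset$hist[rows, , drop = FALSE]))
        pca <- fit_pca(fset$hist[rows, , drop = FALSE], k = k_m)
        sc <- project_features(fset$hist[rows, , drop = FALSE], pca)
        tabs[[m]] <- cbind(fset$info[rows, c("patient_id",
                                             "visit_index",
                                             "modality")],
                           as.data.frame(sc))
        write_json(list(modality = m, mean = pca$mean_vector,
                        components = pca$components),
                   file.path(out, sprintf("pca_%s.json", m)))
      }
      # modalities can have different usable component counts; pad the
      # union of score columns with NA
      cols <- unique(unlist(lapply(tabs, names)))
      tab <- do.call(rbind, lapply(tabs, function(t) {
        for (cn in setdiff(cols, names(t))) t[[cn]] <- NA_real_
        t[, cols]
      }))
      p <- file.path(out, "features.csv")
      write.csv(tab, p, row.names = FALSE)
      note("features", p)
    })
  }

  if ("fit" %in% config$stages) {
    stage_try("fit", {
      # final full-data model at the entry level of the configured arm
      mods <- if (config$modality == "combined")
        c("eyelid", "fingernail") else config$modality
      use <- fset$info$modality %in% mods
      info_u <- fset$info[use, , drop = FALSE]
      hist_u <- fset$hist[use, , drop = FALSE]
      key <- paste(info_u$patient_id, info_u$visit_index)
      scored <- score_by_modality(hist_u, info_u,
                                  rep(FALSE, nrow(info_u)), mods,
                                  config$n_components)
      ce <- combined_entry_features(scored, key, unique(key))
      y <- info_u$hb_true[match(ce$keys, key)]
      model <- if (config$family == "ridge") {
        fit_ridge(ce$X, y, lambda = config$lambda)
      } else {
        do.call(fit_gbm, c(list(X = ce$X, y = y), config$gbm_control))
      }
      p <- file.path(out, "model.json")
      if (config$family == "ridge") {
        write_json(list(family = "ridge", weights = model$weights,
                        lambda = model$lambda), p)
      } else {
        write_json(list(family = "gbm",
                        hyperparameters = model$hyperparameters,
                        init = model$fit$init,
                        trees = lapply(model$fit$trees,
                                       function(t) apply(t, 1, c,
                                                         simplify = FALSE))),
                   p)
      }
      note("model", p)
    })
  }

  if ("evaluate" %in% config$stages) {
    stage_try("evaluate", {
      report <- cross_validate(fset, family = config$family,
                               task = config$task,
                               modality = config$modality, k = config$k,
                               n_components = config$n_components,
                               seed = config$seed,
                               lambda = config$lambda,
                               gbm_control = config$gbm_control,
                               include_metadata = config$include_metadata)
      p <- file.path(out, "evaluation.json")
      rep_out <- list(task = report$task, family = report$family,
                      modality = report$modality, k = report$k,
                      folds = report$folds, fold_mean = report$fold_mean,
                      pooled = report$pooled)
      write_json(rep_out, p)
      note("evaluation", p)
      if (report$task == "regression") {
        cm <- report$pooled$confusion$confusion
        write.csv(as.data.frame(cm), file.path(out, "confusion.csv"))
        note("confusion", file.path(out, "confusion.csv"))
        sc <- data.frame(measured = report$predictions$y_true,
                         predicted = as.numeric(
                           report$predictions$prediction),
                         corridor = hb_to_corridor(
                           report$predictions$y_true))
        write.csv(sc, file.path(out, "scatter.csv"), row.names = FALSE)
        note("scatter", file.path(out, "scatter.csv"))
      }
    })
  }

  if ("decide" %in% config$stages) {
    stage_try("decide", {
      # decision layer on out-of-fold Hb predictions joined with QoL
      key_c <- paste(cohort$patient_id, cohort$visit_index)
      pred_hb <- if (!is.null(report) && report$task == "regression") {
        as.numeric(report$predictions$prediction)[
          match(key_c, report$predictions$entry)]
      } else {
        rep(NA_real_, nrow(cohort))
      }
      dt <- decide_table(data.frame(
        patient_id = cohort$patient_id,
        visit_index = cohort$visit_index,
        predicted_hb = pred_hb,
        global_health = cohort$qol_global_health,
        fatigue = cohort$qol_fatigue,
        clinician_label = cohort$clinician_label))
      p <- file.path(out, "decision.csv")
      write.csv(dt$table, p, row.names = FALSE)
      note("decision", p)
      if (!is.null(dt$concordance)) {
        write_json(list(agreement = dt$concordance$agreement,
                        n = dt$concordance$n,
                        confusion = dt$concordance$confusion$confusion),
                   file.path(out, "concordance.json"))
        note("concordance", file.path(out, "concordance.json"))
      }
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hbimage")),
    seed = config$seed,
    modality = config$modality, family = config$family,
    task = config$task, k = config$k,
    stages = config$stages,
    cohort_config = config$cohort[setdiff(names(config$cohort),
                                          "hb_params")],
    render_params = unclass(config$render),
    artifacts = lapply(artifacts, function(p) {
      if (dir.exists(p)) list(path = p, files = length(list.files(p)))
      else list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  write_json(manifest, file.path(out, "manifest.json"))
  invisible(manifest)
}

#' Apply the corridor decision layer to a prediction table
#'
#' Maps predicted Hb and the two EORTC scores to corridors, aggregates
#' them with [majority_vote()] (rows with no component at all get `NA`),
#' and, when clinician labels are present, reports the concordance.
#'
#' @param df data.frame with columns `predicted_hb`, `global_health`,
#'   `fatigue` and optionally `clinician_label` (plus any identifier
#'   columns, which are passed through).
#' @return list with `table` (input plus `hb_corridor`, `gh_corridor`,
#'   `fatigue_corridor`, `aggregated_label`) and `concordance` (`NULL`
#'   without clinician labels).
#' @export
decide_table <- function(df) {
  stopifnot(all(c("predicted_hb", "global_health", "fatigue") %in%
                  names(df)))
  df$hb_corridor <- hb_to_corridor(df$predicted_hb)
  df$gh_corridor <- qol_to_corridor(df$global_health, "global_health")
  df$fatigue_corridor <- qol_to_corridor(df$fatigue, "fatigue")
  any_comp <- !(is.na(df$hb_corridor) & is.na(df$gh_corridor) &
                  is.na(df$fatigue_corridor))
  df$aggregated_label <- NA_character_
  if (any(any_comp)) {
    df$aggregated_label[any_comp] <- majority_vote(
      df$hb_corridor[any_comp], df$gh_corridor[any_comp],
      df$fatigue_corridor[any_comp])
  }
  concordance <- NULL
  if ("clinician_label" %in% names(df)) {
    ok <- !is.na(df$clinician_label) & !is.na(df$aggregated_label)
    if (any(ok)) {
      concordance <- concordance_report(df$aggregated_label[ok],
                                        df$clinician_label[ok])
    }
  }
  list(table = df, concordance = concordance)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `refine`, `featurize`, `fit`, `evaluate`,
#' `decide`, `all`. Each subcommand runs the pipeline up to and
#' including that stage (`all` = everything). `decide` with `--input`
#' instead applies the decision layer to an existing CSV
#' (columns predicted_hb, global_health, fatigue, optional
#' clinician_label) and writes the labeled CSV plus a concordance JSON.
#'
#' Options: `--config <json>` (overrides for [run_config()] fields),
#' `--seed <int>`, `--out <dir>`, `--input <csv>`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status 0, invisibly.
#' @export
hbimage_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages_all <- c("simulate", "refine", "featurize", "fit", "evaluate",
                  "decide")
  if (length(args) == 0) {
    stop("usage: hbimage <", paste(c(stages_all, "all"), collapse = "|"),
         "> [--config cfg.json] [--seed N] [--out dir] [--input csv]")
  }
  cmd <- args[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character",
                            default = NULL),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--out", type = "character",
                            default = "hbimage_out"),
      optparse::make_option("--input", type = "character",
                            default = NULL))),
    args = args[-1])

  if (cmd == "decide" && !is.null(opts$input)) {
    df <- read.csv(opts$input, stringsAsFactors = FALSE)
    dt <- decide_table(df)
    dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
    write.csv(dt$table, file.path(opts$out, "decision.csv"),
              row.names = FALSE)
    if (!is.null(dt$concordance)) {
      write_json(list(agreement = dt$concordance$agreement,
                      n = dt$concordance$n,
                      confusion = dt$concordance$confusion$confusion),
                 file.path(opts$out, "concordance.json"))
    }
    return(invisible(0L))
  }

  overrides <- if (!is.null(opts$config)) {
    jsonlite::read_json(opts$config, simplifyVector = TRUE)
  } else list()
  cfg_args <- list(seed = opts$seed, out_dir = opts$out)
  for (nm in intersect(names(overrides),
                       c("modality", "family", "task", "k",
                         "n_components", "lambda", "bins",
                         "include_metadata"))) {
    cfg_args[[nm]] <- overrides[[nm]]
  }
  if (!is.null(overrides$cohort)) {
    cfg_args$cohort <- do.call(cohort_config, overrides$cohort)
  }
  if (!is.null(overrides$render)) {
    cfg_args$render <- do.call(render_params, overrides$render)
  }
  if (!is.null(overrides$gbm_control)) {
    cfg_args$gbm_control <- overrides$gbm_control
  }
  stages <- if (cmd == "all") stages_all
            else if (cmd %in% stages_all) {
              stages_all[seq_len(match(cmd, stages_all))]
            } else stop("unknown subcommand: ", cmd)
  cfg_args$stages <- stages
  config <- do.call(run_config, cfg_args)
  run_pipeline(config)
  invisible(0L)
}
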