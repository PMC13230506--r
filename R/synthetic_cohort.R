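#' Default per-subgroup hemoglobin sampling parameters
#'
#' One row per study subgroup: A (healthy blood donors), B (hematologic
#' malignancy with anemia, Hb < 6.21 mmol/L), C (hematologic malignancy
#' without anemia, Hb > 6.21 mmol/L). Hb is drawn from a normal
#' distribution centered on the subgroup median and truncated to the
#' subgroup range; the scale is a quarter of the range so the truncation
#' sits near +/- 2 SD and the sample median stays close to the target.
#'
#' @return data.frame with columns subgroup, location, scale, lower,
#'   upper.
#' @export
default_hb_params <- function() {
  data.frame(
    subgroup = c("A", "B", "C"),
    location = c(8.6, 5.2, 7.9),
    scale    = c((11.4 - 6.5) / 4, (6.2 - 3.4) / 4, (11.3 - 6.3) / 4),
    lower    = c(6.5, 3.4, 6.3),
    upper    = c(11.4, 6.2, 11.3)
  )
}

default_age_params <- function() {
  data.frame(
    subgroup = c("A", "B", "C"),
    location = c(39, 62, 59),
    scale    = c(15, 15, 15),
    lower    = c(18, 21, 21),
    upper    = c(78, 83, 81)
  )
}

# fraction of female participants per subgroup
default_sex_params <- function() c(A = 89 / 184, B = 51 / 101, C = 114 / 266)

#' Default link between hemoglobin and EORTC scores
#'
#' Linear links used by the generator: Global Health increases with Hb,
#' Fatigue decreases. Slopes of +/- 7.5 points per mmol/L place a
#' severely anemic patient (Hb ~ 4) near Global Health 38 / Fatigue 65
#' and a healthy donor (Hb ~ 9) near 75 / 28, spanning the low-to-high
#' QoL strata. Noise SD 12 gives the loose, visibly monotone scatter
#' typical of QoL-vs-Hb data.
#'
#' @return named list with `global_health` and `fatigue`, each a numeric
#'   vector `c(intercept, slope, noise_sd)`.
#' @export
default_qol_link <- function() {
  list(global_health = c(intercept = 8, slope = 7.5, noise_sd = 12),
       fatigue = c(intercept = 95, slope = -7.5, noise_sd = 12))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study structure: 184 healthy donors (subgroup
#' A), 101 anemic patients (B) and 266 non-anemic patients (C), 551
#' entries in total; QoL questionnaires for 49 randomly chosen patients
#' with a 2% per-score missingness rate (so about 47 have pairwise
#' complete scores); a 10% chance that a patient entry is a repeat visit
#' of an earlier patient.
#'
#' @param n_A,n_B,n_C entry counts per subgroup (non-negative).
#' @param hb_params data.frame as [default_hb_params()].
#' @param visit_repeat_prob probability in `[0, 1]` that a patient entry
#'   is a repeat visit of an already-enrolled patient.
#' @param qol_link list as [default_qol_link()].
#' @param qol_subset number of patients handed the QoL questionnaire.
#' @param qol_missing_prob per-score missingness probability.
#' @param seed integer master seed; split into per-stage substreams.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_A = 184, n_B = 101, n_C = 266,
                          hb_params = default_hb_params(),
                          visit_repeat_prob = 0.1,
                          qol_link = default_qol_link(),
                          qol_subset = 49,
                          qol_missing_prob = 0.02,
                          seed = 1L) {
  counts <- c(n_A, n_B, n_C)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("subgroup counts must be non-negative integers")
  }
  stopifnot(is.data.frame(hb_params),
            all(c("subgroup", "location", "scale", "lower", "upper") %in%
                  names(hb_params)))
  if (any(hb_params$lower >= hb_params$upper)) {
    stop("hb_params range bounds must be ordered (lower < upper)")
  }
  if (any(hb_params$scale <= 0)) stop("hb_params scale must be positive")
  if (visit_repeat_prob < 0 || visit_repeat_prob > 1) {
    stop("visit_repeat_prob must lie in [0, 1]")
  }
  sds <- vapply(qol_link, function(l) l[["noise_sd"]], 0)
  if (any(sds < 0)) stop("qol_link noise sds must be >= 0")
  if (qol_missing_prob < 0 || qol_missing_prob > 1) {
    stop("qol_missing_prob must lie in [0, 1]")
  }
  structure(list(n_A = as.integer(n_A), n_B = as.integer(n_B),
                 n_C = as.integer(n_C), hb_params = hb_params,
                 visit_repeat_prob = visit_repeat_prob,
                 qol_link = qol_link, qol_subset = as.integer(qol_subset),
                 qol_missing_prob = qol_missing_prob,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic study cohort
#'
#' Produces one row per (patient, visit) entry. Subgroup A entries are
#' single-visit healthy donors; subgroup B/C entries are patient visits,
#' where with probability `visit_repeat_prob` an entry is a repeat visit
#' of an already-enrolled patient (whose subgroup on that day is set by
#' the entry, so a patient can move between B and C as their Hb changes).
#' Hb respects the 6.21 mmol/L anemia threshold by construction of the
#' truncated sampling ranges. EORTC scores are generated for a random
#' patient subset via the configured linear links, and clinician triage
#' labels are assigned wherever Fatigue is observed (see
#' [assign_clinician_label()]).
#'
#' @param config a [cohort_config()] object.
#' @return data.frame of class `hb_cohort` with columns patient_id,
#'   visit_index, subgroup, age, sex, hb_true, qol_global_health,
#'   qol_fatigue, clinician_label.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_A = 5, n_B = 3, n_C = 4, seed = 7))
#' table(coh$subgroup)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  hbp <- config$hb_params
  agep <- default_age_params()
  sexp <- default_sex_params()

  cohort <- with_seed(substream_seed(config$seed, "cohort"), {
    rows <- list()
    # healthy donors: one visit each
    if (config$n_A > 0) {
      p <- hbp[hbp$subgroup == "A", ]
      a <- agep[agep$subgroup == "A", ]
      n <- config$n_A
      rows[["A"]] <- data.frame(
        patient_id = sprintf("D%04d", seq_len(n)),
        visit_index = 0L,
        subgroup = "A",
        age = round(r_truncnorm(n, a$location, a$scale, a$lower, a$upper)),
        sex = ifelse(runif(n) < sexp[["A"]], "female", "male"),
        hb_true = r_truncnorm(n, p$location, p$scale, p$lower, p$upper))
    }
    # patient entries: subgroup B then C, with repeat visits drawn from
    # the shared patient pool
    pool <- character(0)
    pool_age <- numeric(0)
    pool_sex <- character(0)
    next_id <- 1L
    visit_count <- integer(0)
    patient_rows <- list()
    for (g in c("B", "C")) {
      n <- if (g == "B") config$n_B else config$n_C
      if (n == 0) next
      p <- hbp[hbp$subgroup == g, ]
      a <- agep[agep$subgroup == g, ]
      hb <- r_truncnorm(n, p$location, p$scale, p$lower, p$upper)
      for (i in seq_len(n)) {
        repeat_visit <- length(pool) > 0 &&
          runif(1) < config$visit_repeat_prob
        if (repeat_visit) {
          j <- sample.int(length(pool), 1)
          pid <- pool[j]
          age <- pool_age[j]
          sex <- pool_sex[j]
          visit_count[pid] <- visit_count[pid] + 1L
          vi <- visit_count[pid]
        } else {
          pid <- sprintf("P%04d", next_id)
          next_id <- next_id + 1L
          age <- round(r_truncnorm(1, a$location, a$scale, a$lower, a$upper))
          sex <- if (runif(1) < sexp[[g]]) "female" else "male"
          pool <- c(pool, pid)
          pool_age <- c(pool_age, age)
          pool_sex <- c(pool_sex, sex)
          visit_count[pid] <- 0L
          vi <- 0L
        }
        patient_rows[[length(patient_rows) + 1L]] <- data.frame(
          patient_id = pid, visit_index = vi, subgroup = g,
          age = age, sex = sex, hb_true = hb[i])
      }
    }
    do.call(rbind, c(rows, patient_rows))
  })
  rownames(cohort) <- NULL

  cohort$qol_global_health <- NA_real_
  cohort$qol_fatigue <- NA_real_
  cohort$clinician_label <- NA_character_

  patients <- unique(cohort$patient_id[cohort$subgroup %in% c("B", "C")])
  if (length(patients) > 0 && config$qol_subset > 0) {
    qseed <- substream_seed(config$seed, "qol")
    selected <- with_seed(qseed, {
      sample(patients, min(config$qol_subset, length(patients)))
    })
    sel_rows <- which(cohort$patient_id %in% selected)
    if (length(sel_rows) > 0) {
      qol <- generate_qol(cohort$hb_true[sel_rows], config$qol_link,
                          seed = qseed + 1L)
      miss <- with_seed(qseed + 2L, {
        matrix(runif(2 * length(sel_rows)) < config$qol_missing_prob,
               ncol = 2)
      })
      qol$global_health[miss[, 1]] <- NA_real_
      qol$fatigue[miss[, 2]] <- NA_real_
      cohort$qol_global_health[sel_rows] <- qol$global_health
      cohort$qol_fatigue[sel_rows] <- qol$fatigue
      has_f <- sel_rows[!is.na(qol$fatigue)]
      cohort$clinician_label[has_f] <- assign_clinician_label(
        cohort$hb_true[has_f], cohort$qol_fatigue[has_f])
    }
  }
  class(cohort) <- c("hb_cohort", "data.frame")
  cohort
}

#' Generate EORTC Global Health and Fatigue scores from hemoglobin
#'
#' Linear link plus Gaussian noise, clipped to `[0, 100]`. Global Health
#' increases and Fatigue decreases with Hb on average.
#'
#' @param hb positive hemoglobin values (mmol/L).
#' @param qol_link list as [default_qol_link()].
#' @param seed integer seed (deterministic given the seed).
#' @return data.frame with columns `global_health` and `fatigue`.
#' @export
generate_qol <- function(hb, qol_link = default_qol_link(), seed = 1L) {
  if (any(hb <= 0)) stop("hb must be positive")
  with_seed(seed, {
    gh <- qol_link$global_health
    ft <- qol_link$fatigue
    n <- length(hb)
    data.frame(
      global_health = clip(gh[["intercept"]] + gh[["slope"]] * hb +
                             rnorm(n, 0, gh[["noise_sd"]]), 0, 100),
      fatigue = clip(ft[["intercept"]] + ft[["slope"]] * hb +
                       rnorm(n, 0, ft[["noise_sd"]]), 0, 100))
  })
}

#' Deterministic clinician triage label generator
#'
#' Stand-in for the (unpublished) clinician decision process, used as the
#' comparison target of the decision layer. Rule: start from the Hb
#' corridor of [hb_to_corridor()]; when the Hb corridor is Yellow and the
#' Fatigue score falls in its low-QoL band (>= 39, high symptom burden),
#' escalate one level to Red. The rule is monotone: at fixed fatigue, a
#' lower Hb never yields a less severe label.
#'
#' @param hb_true hemoglobin in mmol/L (> 0).
#' @param fatigue EORTC Fatigue scores in `[0, 100]`; `NA` disables the
#'   escalation.
#' @return character vector of corridor labels.
#' @export
#' @examples
#' assign_clinician_label(5.0, 60)  # "Red": Yellow Hb + severe fatigue
assign_clinician_label <- function(hb_true, fatigue = NA_real_) {
  if (any(!is.na(fatigue) & (fatigue < 0 | fatigue > 100))) {
    stop("fatigue must lie in [0, 100]")
  }
  n <- max(length(hb_true), length(fatigue))
  hb_true <- rep_len(hb_true, n)
  fatigue <- rep_len(fatigue, n)
  lab <- hb_to_corridor(hb_true)
  esc <- lab == "Yellow" & !is.na(fatigue) &
    fatigue >= qol_cutpoints()$fatigue[["low"]]
  lab[esc] <- "Red"
  lab
}
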