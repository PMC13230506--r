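#' Clinical Hb corridor labels
#'
#' The three ordered severity bands used throughout the package, in
#' decreasing severity: Red, Yellow, Green. Red marks hemoglobin levels at
#' which transfusion is commonly considered, Yellow a clinically ambiguous
#' zone, and Green levels where no immediate intervention is expected.
#'
#' @return character vector `c("Red", "Yellow", "Green")`.
#' @export
corridor_levels <- function() c("Red", "Yellow", "Green")

# severity rank: Green = 1 < Yellow = 2 < Red = 3
corridor_severity <- function(x) {
  s <- match(x, c("Green", "Yellow", "Red"))
  if (anyNA(s) && !anyNA(x)) stop("invalid corridor label")
  s
}

check_corridor <- function(x, arg = "labels") {
  bad <- !is.na(x) & !(x %in% corridor_levels())
  if (any(bad)) {
    stop(sprintf("%s must be one of %s", arg,
                 paste(corridor_levels(), collapse = ", ")))
  }
  invisible(x)
}

#' Discretize hemoglobin into clinical corridors
#'
#' Fixed cut-offs: Red for Hb < 4.5 mmol/L, Yellow for 4.5--6.0 mmol/L
#' (both boundaries included in Yellow), Green for Hb > 6.0 mmol/L. The
#' cut-offs reflect restrictive transfusion practice and are evaluation
#' anchors, not treatment rules.
#'
#' @param hb numeric vector of hemoglobin values in mmol/L; must be > 0.
#' @return character vector of corridor labels.
#' @export
#' @examples
#' hb_to_corridor(c(4.0, 5.0, 7.2))
hb_to_corridor <- function(hb) {
  if (!is.numeric(hb)) stop("hb must be numeric")
  if (any(!is.na(hb) & hb <= 0)) stop("hb must be positive (mmol/L)")
  out <- ifelse(hb < 4.5, "Red", ifelse(hb <= 6.0, "Yellow", "Green"))
  out[is.na(hb)] <- NA_character_
  out
}

#' Default cut-points for EORTC QLQ-C30 corridor strata
#'
#' Global Health Status (higher = better): low QoL `[0, 45)`, moderate
#' `[45, 66)`, high `[66, 100]`. Fatigue (reverse-scaled, higher = worse):
#' low QoL `[39, 100]`, moderate `[17, 39)`, high `[0, 17)`. The shared
#' boundary values (45, 66, 17, 39) are assigned to the less severe side
#' via half-open intervals; strata map low -> Red, moderate -> Yellow,
#' high -> Green.
#'
#' @return named list with elements `global_health` and `fatigue`, each a
#'   numeric vector of the two interior cut-points.
#' @export
qol_cutpoints <- function() {
  list(global_health = c(low = 45, high = 66),
       fatigue = c(high = 17, low = 39))
}

#' Map an EORTC score to a corridor stratum
#'
#' @param score numeric vector of scores in `[0, 100]`.
#' @param scale `"global_health"` or `"fatigue"`.
#' @param cutpoints list as returned by [qol_cutpoints()].
#' @return character vector of corridor labels.
#' @export
#' @examples
#' qol_to_corridor(70, "global_health")  # Green
#' qol_to_corridor(50, "fatigue")        # Red (high symptom burden)
qol_to_corridor <- function(score, scale = c("global_health", "fatigue"),
                            cutpoints = qol_cutpoints()) {
  scale <- match.arg(scale)
  if (any(!is.na(score) & (score < 0 | score > 100))) {
    stop("score must lie in [0, 100]")
  }
  out <- if (scale == "global_health") {
    cp <- cutpoints$global_health
    ifelse(score < cp[["low"]], "Red",
           ifelse(score < cp[["high"]], "Yellow", "Green"))
  } else {
    cp <- cutpoints$fatigue
    ifelse(score >= cp[["low"]], "Red",
           ifelse(score >= cp[["high"]], "Yellow", "Green"))
  }
  out[is.na(score)] <- NA_character_
  out
}

#' Equal-weight majority vote over corridor components
#'
#' Combines the predicted Hb corridor with the Global Health and Fatigue
#' corridor strata. Each component has equal weight; the label occurring
#' at least twice wins. Without a majority (all three distinct, or a tie
#' among available components) a conservative rule selects the more severe
#' corridor (Red > Yellow > Green). Missing (`NA`) components are dropped
#' and the vote runs over those available; a single component passes
#' through unchanged. The rule is fully deterministic; there are no
#' learned weights.
#'
#' @param hb_corridor,gh_corridor,fatigue_corridor corridor labels
#'   (vectors are recycled to a common length); `NA` marks a missing
#'   component.
#' @return character vector of aggregated corridor labels.
#' @export
#' @examples
#' majority_vote("Yellow", "Red", "Red")     # Red
#' majority_vote("Red", "Yellow", "Green")   # Red (no majority)
majority_vote <- function(hb_corridor, gh_corridor = NA,
                          fatigue_corridor = NA) {
  n <- max(length(hb_corridor), length(gh_corridor),
           length(fatigue_corridor))
  comp <- cbind(rep_len(hb_corridor, n), rep_len(gh_corridor, n),
                rep_len(fatigue_corridor, n))
  check_corridor(comp, "vote components")
  vapply(seq_len(n), function(i) {
    votes <- comp[i, !is.na(comp[i, ])]
    if (length(votes) == 0L) {
      stop("majority_vote needs at least one non-missing component")
    }
    counts <- vapply(corridor_levels(), function(l) sum(votes == l), 0L)
    top <- names(counts)[counts == max(counts)]
    # corridor_levels() is ordered by decreasing severity, so the first
    # maximal label is the most severe one (the conservative tie-break)
    top[1L]
  }, character(1))
}

#' Concordance between aggregated labels and clinician decisions
#'
#' Cross-tabulates aggregated corridor labels against clinician labels
#' (rows = clinician, cols = aggregated) and reports the agreement
#' fraction (diagonal sum over total).
#'
#' @param aggregated_labels,clinician_labels equal-length corridor label
#'   vectors.
#' @return list with `confusion` (the [corridor_confusion()] result) and
#'   `agreement`.
#' @export
concordance_report <- function(aggregated_labels, clinician_labels) {
  if (length(aggregated_labels) != length(clinician_labels)) {
    stop("label vectors must have equal length")
  }
  conf <- corridor_confusion(clinician_labels, aggregated_labels)
  agreement <- if (conf$n > 0) conf$total_correct / conf$n else NA_real_
  list(confusion = conf, agreement = agreement, n = conf$n)
}
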