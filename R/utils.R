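`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Convert hemoglobin between mmol/L and g/dL
#'
#' Uses the monomer convention 1 mmol/L = 1.611 g/dL.
#'
#' @param x numeric vector of concentrations.
#' @return numeric vector in the other unit.
#' @export
#' @examples
#' mmol_to_gdl(6.21)
mmol_to_gdl <- function(x) x * 1.611

#' @rdname mmol_to_gdl
#' @export
gdl_to_mmol <- function(x) x / 1.611

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# One global seed is split into per-stage substreams so partial reruns of a
# stage reproduce exactly. All derived seeds stay below 2^31 - 1.
substream_seed <- function(seed, stage) {
  offsets <- c(cohort = 1L, qol = 2L, images = 3L, folds = 4L,
               model = 5L, pipeline = 6L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + off * 7919) %% 2147483647) + 1L
}

# Vectorized numeric HSV -> RGB (h in degrees, s and v in [0,1]).
# grDevices::hsv() builds color strings, far too slow for per-pixel use.
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- v; g <- v; b <- v
  r[i == 1] <- q[i == 1]; r[i == 2] <- p[i == 2]; r[i == 3] <- p[i == 3]
  r[i == 4] <- t[i == 4]
  g[i == 0] <- t[i == 0]; g[i == 3] <- q[i == 3]; g[i == 4] <- p[i == 4]
  g[i == 5] <- p[i == 5]
  b[i == 0] <- p[i == 0]; b[i == 1] <- p[i == 1]; b[i == 2] <- t[i == 2]
  b[i == 5] <- q[i == 5]
  cbind(r = r, g = g, b = b)
}

# Truncated normal sampling by inverse-CDF (no rejection, so the draw count
# is deterministic given the seed).
r_truncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}
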