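#' Ridge regression with closed-form solution
#'
#' Penalized least squares on internally standardized features; the
#' intercept is unpenalized. Solved via the augmented-data QR
#' factorization (equivalent to the normal equations
#' `(Z'Z + lambda I) b = Z'y`). Ridge serves as the regularized linear
#' baseline that mitigates the strong multicollinearity of neighboring
#' hue-histogram bins.
#'
#' @param X N x p numeric feature matrix, no missing values.
#' @param y numeric response (hemoglobin in mmol/L).
#' @param lambda non-negative penalty; `lambda = 0` requires a
#'   full-column-rank design.
#' @return object of class `ridge_model` with `weights` (intercept plus
#'   slopes on the original feature scale), `lambda`, and the stored
#'   training standardization.
#' @export
#' @examples
#' m <- fit_ridge(matrix(0:2), c(1, 3, 5), lambda = 0)
#' m$weights  # intercept 1, slope 2
fit_ridge <- function(X, y, lambda = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (lambda < 0) stop("lambda must be >= 0")
  p <- ncol(X)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  ybar <- mean(y)
  if (lambda == 0) {
    qz <- qr(Z)
    if (qz$rank < p) {
      stop("singular system at lambda = 0; use lambda > 0")
    }
    beta <- qr.coef(qz, y - ybar)
  } else {
    beta <- qr.coef(qr(rbind(Z, diag(sqrt(lambda), p))),
                    c(y - ybar, rep(0, p)))
  }
  slope <- beta / sdev
  intercept <- ybar - sum(slope * mu)
  w <- c(intercept, slope)
  names(w) <- c("(Intercept)",
                colnames(X) %||% paste0("x", seq_len(p)))
  structure(list(weights = w, lambda = lambda, center = mu,
                 scale = sdev, p = p),
            class = "ridge_model")
}

#' @export
predict.ridge_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (nrow(X) == 0) return(numeric(0))
  if (ncol(X) != object$p) {
    stop(sprintf("feature dimension mismatch: model has %d, data has %d",
                 object$p, ncol(X)))
  }
  drop(cbind(1, X) %*% object$weights)
}

#' Gradient-boosted regression trees
#'
#' Least-squares gradient boosting with exact-split regression trees,
#' implemented in C++. Defaults mirror common gradient-boosting practice
#' (500 trees, depth at most 6, learning rate 0.05, at least 20
#' observations per leaf). No row or column subsampling is used, so the
#' fit is deterministic regardless of `seed`; the seed is stored for
#' provenance.
#'
#' @param X N x p numeric feature matrix.
#' @param y numeric response.
#' @param n_trees,max_depth,learning_rate,min_obs boosting
#'   hyperparameters.
#' @param seed stored in the model record.
#' @return object of class `hb_gbm`.
#' @export
fit_gbm <- function(X, y, n_trees = 500, max_depth = 6,
                    learning_rate = 0.05, min_obs = 20, seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  fit <- gbm_fit_cpp(X, as.numeric(y), as.integer(n_trees),
                     as.integer(max_depth), learning_rate,
                     as.integer(min_obs))
  structure(list(fit = fit, p = ncol(X),
                 hyperparameters = list(n_trees = n_trees,
                                        max_depth = max_depth,
                                        learning_rate = learning_rate,
                                        min_obs = min_obs,
                                        seed = as.integer(seed))),
            class = "hb_gbm")
}

#' @export
predict.hb_gbm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (nrow(X) == 0) return(numeric(0))
  if (ncol(X) != object$p) {
    stop(sprintf("feature dimension mismatch: model has %d, data has %d",
                 object$p, ncol(X)))
  }
  as.numeric(gbm_predict_cpp(object$fit, X))
}

# argmax over class scores with the conservative severity tie-break:
# columns must be ordered Red, Yellow, Green, so "first" = most severe.
severity_argmax <- function(scores) {
  stopifnot(ncol(scores) == 3)
  corridor_levels()[max.col(scores, ties.method = "first")]
}

#' Three-class corridor classifier
#'
#' One-vs-rest scoring with either ridge-regression scores or
#' gradient-boosted trees on 0/1 class indicators; the predicted class is
#' the score argmax with exact ties resolved toward the more severe
#' corridor (Red > Yellow > Green).
#'
#' @param X N x p feature matrix.
#' @param corridor_labels labels in Red/Yellow/Green; at least two
#'   classes must be present.
#' @param family `"ridge"` or `"gbm"`.
#' @param lambda ridge penalty.
#' @param ... passed to [fit_gbm()] for the gbm family.
#' @return object of class `corridor_classifier`.
#' @export
fit_classifier <- function(X, corridor_labels,
                           family = c("ridge", "gbm"), lambda = 1, ...) {
  family <- match.arg(family)
  X <- as.matrix(X)
  check_corridor(corridor_labels)
  if (length(unique(corridor_labels)) < 2) {
    stop("training labels contain a single class")
  }
  models <- lapply(corridor_levels(), function(cl) {
    y <- as.numeric(corridor_labels == cl)
    if (family == "ridge") fit_ridge(X, y, lambda = lambda)
    else fit_gbm(X, y, ...)
  })
  names(models) <- corridor_levels()
  structure(list(models = models, family = family, p = ncol(X)),
            class = "corridor_classifier")
}

#' @export
predict.corridor_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (nrow(X) == 0) return(character(0))
  scores <- vapply(object$models, function(m) predict(m, X),
                   numeric(nrow(X)))
  if (nrow(X) == 1) scores <- matrix(scores, nrow = 1)
  severity_argmax(scores)
}
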