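# Linear support-vector models via dual coordinate descent.
#
# No SVM package is available in the build environment, so the two linear
# models the prediction module needs are implemented directly after Hsieh et
# al. (2008): L1-loss SVC (hinge) and L1-loss epsilon-insensitive SVR, both
# with L2 regularization, bias handled by an augmented constant feature.
# Deterministic (fixed sweep order), no randomness.

#' Fit a linear support-vector model
#'
#' @param X numeric matrix n x p of (already standardized) features.
#' @param y targets; for `type = "svc"` a vector coercible to two classes,
#'   for `"svr"` numeric.
#' @param type `"svc"` (hinge-loss classification) or `"svr"`
#'   (epsilon-insensitive regression).
#' @param cost box constraint C (default 1, the conventional default).
#' @param epsilon SVR insensitivity half-width; default `0.1 * sd(y)`.
#' @param max_pass maximum coordinate-descent sweeps.
#' @param tol stop when the largest dual update in a sweep falls below this.
#' @return object of class `linear_svm` with `w` (p + 1 weights, last = bias),
#'   `type`, and for SVC the class `levels`.
#' @export
linear_svm <- function(X, y, type = c("svc", "svr"), cost = 1, epsilon = NULL,
                       max_pass = 250, tol = 1e-5) {
  type <- match.arg(type)
  X <- cbind(as.matrix(X), bias = 1)
  n <- nrow(X)
  lev <- NULL
  if (type == "svc") {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2) stopf("svc needs exactly 2 classes, got %d", length(lev))
    yy <- ifelse(as.character(y) == lev[2], 1, -1)
  } else {
    yy <- as.numeric(y)
    if (is.null(epsilon)) epsilon <- 0.1 * sd(yy)
  }
  qii <- rowSums(X^2)
  w <- numeric(ncol(X))
  if (type == "svc") {
    alpha <- numeric(n)
    for (pass in seq_len(max_pass)) {
      delta_max <- 0
      for (i in seq_len(n)) {
        g <- yy[i] * sum(w * X[i, ]) - 1
        a_new <- min(max(alpha[i] - g / qii[i], 0), cost)
        d <- a_new - alpha[i]
        if (d != 0) {
          w <- w + d * yy[i] * X[i, ]
          alpha[i] <- a_new
          delta_max <- max(delta_max, abs(d))
        }
      }
      if (delta_max < tol) break
    }
  } else {
    beta <- numeric(n)
    for (pass in seq_len(max_pass)) {
      delta_max <- 0
      for (i in seq_len(n)) {
        g <- sum(w * X[i, ]) - yy[i]
        G <- g - qii[i] * beta[i]
        b_new <- sign(-G) * max(abs(G) - epsilon, 0) / qii[i]
        b_new <- min(max(b_new, -cost), cost)
        d <- b_new - beta[i]
        if (d != 0) {
          w <- w + d * X[i, ]
          beta[i] <- b_new
          delta_max <- max(delta_max, abs(d))
        }
      }
      if (delta_max < tol) break
    }
  }
  structure(list(w = w, type = type, levels = lev), class = "linear_svm")
}

#' Predict from a fitted linear SVM
#' @param object a `linear_svm`.
#' @param newdata matrix with the same feature columns used in fitting.
#' @param ... unused.
#' @return numeric predictions (SVR) or character class labels (SVC).
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  sc <- as.vector(cbind(as.matrix(newdata), 1) %*% object$w)
  if (object$type == "svc") ifelse(sc > 0, object$levels[2], object$levels[1]) else sc
}
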