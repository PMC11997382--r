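#' SVM hyperparameters
#' @param C Soft-margin cost, `C > 0`.
#' @param gamma RBF kernel width, `gamma > 0`.
#' @return A list of class `svm_params`. The kernel is fixed to the RBF.
#' @export
svm_params <- function(C, gamma) {
  if (C <= 0 || gamma <= 0) stop("C and gamma must be positive", call. = FALSE)
  structure(list(C = C, gamma = gamma, kernel = "rbf"), class = "svm_params")
}

# Fit a binary RBF C-SVC. y in {0, 1} (1 = imagery). X already scaled.
svm_fit <- function(X, y, params) {
  X <- as.matrix(X)
  ys <- ifelse(y == 1, 1, -1)
  K <- rbf_kernel(X, X, params$gamma)
  fit <- smo_train(K, ys, params$C)
  list(X = X, y_signed = ys, alpha = fit$alpha, b = fit$b, params = params)
}

# Predict labels in {0, 1} for rows of newX (already scaled).
svm_predict <- function(fit, newX) {
  newX <- as.matrix(newX)
  K <- rbf_kernel(fit$X, newX, fit$params$gamma)
  f <- as.vector(crossprod(K, fit$alpha * fit$y_signed)) + fit$b
  as.integer(f > 0)
}

# Min-max scaling to [0, 1], fitted on training data only.
minmax_fit <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1       # constant feature: map to 0
  list(lo = lo, rng = rng)
}

minmax_apply <- function(scaling, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, scaling$lo, "-"), 2, scaling$rng, "/")
}
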