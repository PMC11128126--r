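# NIPALS PLS1 core. This sits under everything: the calibration family,
# the CARS selector (coefficient weights), the Monte-Carlo outlier screen and
# every RMSECV, so it is implemented here once on plain matrices.

# Fit PLS1 by NIPALS on (X, y). Returns the full coefficient path so a single
# fit serves every component count up to ncomp.
pls_core <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  if (ncomp < 1) {
    rlang::abort("PLS needs at least 2 samples and 1 predictor.",
                 class = "nircal_fit_error")
  }
  xmean <- colMeans(X)
  ymean <- mean(y)
  Xd <- sweep(X, 2, xmean)
  if (all(apply(Xd, 2, function(v) max(abs(v))) < 1e-13)) {
    rlang::abort("degenerate X: all predictor columns constant.",
                 class = "nircal_fit_error")
  }
  yd <- y - ymean
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-13) break
    w <- w / nw
    tt <- Xd %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-26) break
    pp <- crossprod(Xd, tt) / tt2
    qq <- sum(yd * tt) / tt2
    Xd <- Xd - tcrossprod(tt, pp)
    yd <- yd - qq * tt
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; q[a] <- qq
    a_used <- a
  }
  if (a_used == 0L) {
    rlang::abort("PLS found no predictive direction (X'y ~ 0).",
                 class = "nircal_fit_error")
  }
  W <- W[, 1:a_used, drop = FALSE]; P <- P[, 1:a_used, drop = FALSE]
  Tm <- Tm[, 1:a_used, drop = FALSE]; q <- q[1:a_used]
  # coefficient path: B[, a] uses components 1..a; P'W is upper triangular
  PtW <- crossprod(P, W)
  B <- matrix(0, p, a_used)
  for (a in seq_len(a_used)) {
    ra <- backsolve(PtW[1:a, 1:a, drop = FALSE], q[1:a])
    B[, a] <- W[, 1:a, drop = FALSE] %*% ra
  }
  intercepts <- ymean - as.numeric(xmean %*% B)
  list(ncomp = a_used, xmean = xmean, ymean = ymean,
       W = W, P = P, scores = Tm, q = q,
       coef_path = B, intercepts = intercepts)
}

pls_core_predict <- function(fit, X, ncomp = fit$ncomp) {
  ncomp <- min(ncomp, fit$ncomp)
  as.numeric(as.matrix(X) %*% fit$coef_path[, ncomp] + fit$intercepts[ncomp])
}

# K-fold CV RMSE over a whole component path at once.
# Returns vector rmsecv[1..ncomp] (and pooled out-of-fold predictions for the
# best component count if keep_pred).
pls_cv_path <- function(X, y, ncomp, n_folds, seed) {
  n <- nrow(X)
  n_folds <- min(n_folds, n)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  max_comp <- 0L
  preds <- matrix(NA_real_, n, ncomp)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    fit <- pls_core(X[tr, , drop = FALSE], y[tr], ncomp)
    max_comp <- max(max_comp, fit$ncomp)
    Xte <- X[!tr, , drop = FALSE]
    for (a in seq_len(ncomp)) {
      preds[!tr, a] <- pls_core_predict(fit, Xte, min(a, fit$ncomp))
    }
  }
  rmse_path <- sqrt(colMeans((preds - y)^2))
  list(rmsecv = rmse_path[seq_len(max_comp)], preds = preds, folds = folds)
}
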