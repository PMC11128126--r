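# A minimal 1-D CNN regression engine in base R matrix algebra.
# Architecture: conv(filters=16, kernel=20, stride=10) -> ReLU ->
# maxpool(width=3, stride=1) -> flatten -> dense(hidden, ReLU) -> linear.
# Full-batch SGD on MSE. Small enough (tens of thousands of weights) that
# explicit matrix backprop is fast for calibration-sized sample sets.

cnn_dims <- function(p, kernel = 20L, stride = 10L, pool = 3L) {
  if (p < kernel) {
    rlang::abort(sprintf("input width %d smaller than the convolution kernel (%d).",
                         p, kernel),
                 class = "nircal_architecture_error")
  }
  l1 <- (p - kernel) %/% stride + 1L
  l2 <- l1 - (pool - 1L)
  if (l2 < 1L) {
    rlang::abort("input too narrow for the pooling stage.",
                 class = "nircal_architecture_error")
  }
  list(l1 = l1, l2 = l2)
}

# column indices that gather all conv patches of X in one subscript:
# result is n x (l1*kernel), column-major equal to array(n, l1, kernel)
cnn_patch_cols <- function(kernel, stride, l1) {
  as.vector(outer((seq_len(l1) - 1L) * stride, seq_len(kernel), `+`))
}

cnn_forward <- function(par, Xs, dims, keep = FALSE) {
  n <- nrow(Xs)
  M <- matrix(Xs[, par$patch_cols, drop = FALSE], n * dims$l1, par$kernel)
  conv_pre <- M %*% par$Wc + rep(par$bc, each = n * dims$l1)
  conv <- pmax(conv_pre, 0)
  A <- array(conv, c(n, dims$l1, par$filters))
  s1 <- A[, seq_len(dims$l2), , drop = FALSE]
  s2 <- A[, seq_len(dims$l2) + 1L, , drop = FALSE]
  s3 <- A[, seq_len(dims$l2) + 2L, , drop = FALSE]
  P <- pmax(s1, s2, s3)
  Fm <- matrix(P, n, dims$l2 * par$filters)
  H_pre <- Fm %*% par$W1 + rep(par$b1, each = n)
  H <- pmax(H_pre, 0)
  out <- as.numeric(H %*% par$w2 + par$b2)
  if (!keep) return(out)
  list(out = out, M = M, conv_pre = conv_pre, A = A,
       s1 = s1, s2 = s2, s3 = s3, P = P, Fm = Fm, H = H)
}

cnn_train <- function(X, y, lr = 0.01, epochs = 200, hidden = 64, seed = 1,
                      kernel = 20L, stride = 10L, filters = 16L, pool = 3L) {
  n <- nrow(X); p <- ncol(X)
  dims <- cnn_dims(p, kernel, stride, pool)
  xmean <- colMeans(X)
  xsd <- apply(X, 2, stats::sd)
  xsd[xsd < 1e-12] <- 1
  ymean <- mean(y); ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd < 1e-12) ysd <- 1
  Xs <- sweep(sweep(X, 2, xmean), 2, xsd, "/")
  ys <- (y - ymean) / ysd
  nf <- dims$l2 * filters
  # LeCun-scaled init (sd = 1/sqrt(fan_in)): conservative enough that
  # full-batch SGD at lr = 0.01 descends monotonically from the start
  par <- withr::with_seed(seed, list(
    Wc = matrix(stats::rnorm(kernel * filters, 0, sqrt(1 / kernel)), kernel, filters),
    bc = numeric(filters),
    W1 = matrix(stats::rnorm(nf * hidden, 0, sqrt(1 / nf)), nf, hidden),
    b1 = numeric(hidden),
    w2 = matrix(stats::rnorm(hidden, 0, sqrt(1 / hidden)), hidden, 1),
    b2 = 0,
    kernel = kernel, filters = filters,
    patch_cols = cnn_patch_cols(kernel, stride, dims$l1)
  ))
  loss <- numeric(epochs)
  l2i <- seq_len(dims$l2)
  for (e in seq_len(epochs)) {
    fw <- cnn_forward(par, Xs, dims, keep = TRUE)
    err <- fw$out - ys
    loss[e] <- mean(err^2)
    dout <- matrix(2 * err / n, n, 1)
    dw2 <- crossprod(fw$H, dout)
    db2 <- sum(dout)
    dH <- dout %*% t(par$w2)
    dH[fw$H <= 0] <- 0
    dW1 <- crossprod(fw$Fm, dH)
    db1 <- colSums(dH)
    dF <- dH %*% t(par$W1)
    dP <- array(dF, c(n, dims$l2, filters))
    m1 <- fw$s1 == fw$P
    m2 <- (fw$s2 == fw$P) & !m1
    m3 <- (fw$s3 == fw$P) & !m1 & !m2
    dA <- array(0, dim(fw$A))
    dA[, l2i, ] <- dP * m1
    dA[, l2i + 1L, ] <- dA[, l2i + 1L, , drop = FALSE] + dP * m2
    dA[, l2i + 2L, ] <- dA[, l2i + 2L, , drop = FALSE] + dP * m3
    dC <- matrix(dA, n * dims$l1, filters)
    dC[fw$conv_pre <= 0] <- 0
    dWc <- crossprod(fw$M, dC)
    dbc <- colSums(dC)
    par$Wc <- par$Wc - lr * dWc
    par$bc <- par$bc - lr * dbc
    par$W1 <- par$W1 - lr * dW1
    par$b1 <- par$b1 - lr * db1
    par$w2 <- par$w2 - lr * dw2
    par$b2 <- par$b2 - lr * db2
  }
  list(par = par, dims = dims, xmean = xmean, xsd = xsd,
       ymean = ymean, ysd = ysd, loss = loss)
}

cnn_predict <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$xmean), 2, fit$xsd, "/")
  fit$ymean + fit$ysd * cnn_forward(fit$par, Xs, fit$dims)
}
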