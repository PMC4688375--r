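# Independent oracles used to check the package's implementations.
# These are deliberately naive and share no code with the package.

# closed-form OLS + t statistic via explicit normal equations
ols_oracle <- function(X, y, cvec) {
  XtXinv <- solve(t(X) %*% X)
  beta <- XtXinv %*% t(X) %*% y
  res <- y - X %*% beta
  dof <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / dof
  tval <- as.numeric(t(cvec) %*% beta) /
    sqrt(sigma2 * as.numeric(t(cvec) %*% XtXinv %*% cvec))
  list(beta = as.numeric(beta), sigma2 = sigma2, t = tval, dof = dof)
}

# residual-forming projection matrix applied explicitly
projection_oracle <- function(X, Y) {
  P <- diag(nrow(X)) - X %*% solve(t(X) %*% X) %*% t(X)
  P %*% Y
}

# soft-margin linear SVM solved in the dual by exhaustive pairwise (SMO)
# coordinate optimization; adequate for toy problems of a few points
smo_svm_oracle <- function(X, y, C = 1, sweeps = 2000) {
  n <- nrow(X)
  K <- X %*% t(X)
  a <- numeric(n)
  for (s in seq_len(sweeps)) {
    moved <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      Fi <- sum(a * y * K[, i]); Fj <- sum(a * y * K[, j])
      Ei <- Fi - y[i]; Ej <- Fj - y[j]
      eta <- K[i, i] + K[j, j] - 2 * K[i, j]
      if (eta <= 1e-12) next
      aj <- a[j] + y[j] * (Ei - Ej) / eta
      if (y[i] == y[j]) {
        L <- max(0, a[i] + a[j] - C); H <- min(C, a[i] + a[j])
      } else {
        L <- max(0, a[j] - a[i]); H <- min(C, C + a[j] - a[i])
      }
      aj <- min(max(aj, L), H)
      moved <- moved + abs(aj - a[j])
      a[i] <- a[i] + y[i] * y[j] * (a[j] - aj)
      a[j] <- aj
    }
    if (moved < 1e-15) break
  }
  w <- as.numeric(t(X) %*% (a * y))
  margin_sv <- which(a > 1e-7 & a < C - 1e-7)
  b <- if (length(margin_sv) > 0) {
    mean(y[margin_sv] - (X %*% w)[margin_sv])
  } else {
    -(max((X %*% w)[y == -1]) + min((X %*% w)[y == 1])) / 2
  }
  list(w = w, b = b, alpha = a)
}

svm_primal_objective <- function(w, b, X, y, C) {
  f <- as.numeric(X %*% w + b)
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * f))
}

# direct (non-separable) 3D Gaussian convolution with zero padding
direct_gaussian_conv3d <- function(vol, fwhm_mm, voxel_size_mm) {
  sds <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- dim(vol)
  rad <- pmax(1L, ceiling(4 * sds))
  k1 <- lapply(1:3, function(ax) {
    k <- dnorm(seq(-rad[ax], rad[ax]), sd = sds[ax]); k / sum(k)
  })
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (dx in -rad[1]:rad[1]) for (dy in -rad[2]:rad[2])
      for (dz in -rad[3]:rad[3]) {
        xi <- x + dx; yi <- y + dy; zi <- z + dz
        if (xi >= 1 && xi <= d[1] && yi >= 1 && yi <= d[2] &&
            zi >= 1 && zi <= d[3]) {
          acc <- acc + vol[xi, yi, zi] *
            k1[[1]][dx + rad[1] + 1] * k1[[2]][dy + rad[2] + 1] *
            k1[[3]][dz + rad[3] + 1]
        }
      }
    out[x, y, z] <- acc
  }
  out
}

# brute-force majority counter over the first k labels
counting_vote_oracle <- function(labels, k) {
  n_yes <- 0; n_no <- 0
  for (i in seq_len(k)) {
    if (labels[i] == 1) n_yes <- n_yes + 1 else n_no <- n_no + 1
  }
  if (n_yes > n_no) "YES" else if (n_no > n_yes) "NO" else "TIE"
}
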