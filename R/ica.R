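#' FastICA decomposition of a multichannel signal
#'
#' Symmetric fixed-point FastICA with a log-cosh contrast: the data are
#' centred and whitened by PCA (dropping near-zero-variance dimensions),
#' then an orthogonal unmixing matrix is iterated to convergence. Returns
#' the sources and the mixing needed for exact reconstruction of the
#' retained subspace.
#'
#' @param X channels x samples matrix.
#' @param n_comp number of components (default: all with non-negligible
#'   variance).
#' @param max_iter,tol fixed-point iteration controls.
#' @param seed seed for the random initial unmixing matrix.
#' @return list with `S` (components x samples), `A` (channels x components
#'   mixing), `means` (channel means); `X ~= A %*% S + means`.
#' @export
fast_ica <- function(X, n_comp = NULL, max_iter = 200, tol = 1e-6,
                     seed = 42L) {
  nch <- nrow(X)
  n <- ncol(X)
  means <- rowMeans(X)
  Xc <- X - means
  C <- (Xc %*% t(Xc)) / n
  e <- eigen(C, symmetric = TRUE)
  keep <- which(e$values > max(e$values) * 1e-10)
  if (length(keep) < 2)
    stop("rank-deficient data: need at least 2 channels with independent ",
         "variance for ICA", call. = FALSE)
  if (!is.null(n_comp)) keep <- keep[seq_len(min(n_comp, length(keep)))]
  D <- e$values[keep]
  E <- e$vectors[, keep, drop = FALSE]
  K <- diag(1 / sqrt(D), length(keep)) %*% t(E)     # whitening
  Z <- K %*% Xc
  k <- nrow(Z)
  W <- withr::with_seed(as.integer(seed),
                        matrix(rnorm(k * k), k, k))
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / n - diag(gprime, k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z
  # mixing back to channel space: X ~ A S, A = E D^{1/2} W^T
  A <- E %*% diag(sqrt(D), length(keep)) %*% t(W)
  list(S = S, A = A, means = means)
}

#' Remove blink activity by zeroing EOG-correlated independent components
#'
#' Decomposes the recording into independent components, zeroes every
#' component whose time course correlates with the EOG channel beyond the
#' threshold (the blink subspace), and reconstructs the scalp channels.
#' The EOG channel itself is excluded from the decomposition and passed
#' through unchanged so it stays available as a blink reference.
#'
#' @param recording an `eeg_recording` containing an `"EOG"` channel.
#' @param threshold absolute correlation with EOG above which a component
#'   is zeroed.
#' @param seed seed for the ICA initialisation.
#' @return list with `recording` (cleaned) and `report` (data frame of
#'   component-EOG correlations and which were zeroed).
#' @export
remove_blinks <- function(recording, threshold = 0.8, seed = 42L) {
  labels <- recording$labels
  if (!"EOG" %in% labels)
    stop("EOG channel required for blink removal", call. = FALSE)
  eog <- recording$data[match("EOG", labels), ]
  scalp <- which(labels != "EOG")
  X <- recording$data[scalp, , drop = FALSE]
  dec <- fast_ica(X, seed = seed)
  r <- apply(dec$S, 1, function(s) {
    if (sd(s) == 0 || sd(eog) == 0) return(0)
    cor(s, eog)
  })
  zero <- which(abs(r) > threshold)
  S <- dec$S
  if (length(zero)) S[zero, ] <- 0
  Xc <- dec$A %*% S + dec$means
  recording$data[scalp, ] <- Xc
  report <- data.frame(component = seq_along(r), eog_correlation = r,
                       zeroed = seq_along(r) %in% zero)
  list(recording = recording, report = report)
}
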