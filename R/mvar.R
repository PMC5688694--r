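# Multivariate autoregressive (MVAR) modelling of multichannel EEG.
#
# An order-p MVAR model writes the N-channel signal as
#   x(t) = sum_{k=1..p} A_k x(t-k) + w(t)
# with N x N coefficient matrices A_k and innovation noise w(t). The
# eigenvalue spectrum of A (order 1) summarizes the damping of the joint
# dynamics: moduli near 1 indicate slow, weakly damped modes.

#' Fit an MVAR model by least squares
#'
#' Ordinary least squares over the one-step prediction equations; with order
#' p the regressor stacks the p lagged sample vectors.
#'
#' @param epoch channels x samples numeric matrix (a single channel may be
#'   passed as a 1-row matrix or plain vector).
#' @param p model order (default 1).
#' @return object of class `mvar_model`: list with `order`, `A` (list of p
#'   N x N coefficient matrices) and `noise_cov` (innovation covariance).
#' @export
fit_mvar <- function(epoch, p = 1L) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  n_ch <- nrow(epoch)
  n_t <- ncol(epoch)
  p <- as.integer(p)
  if (p < 1L) config_error("MVAR order must be >= 1")
  if (n_t <= p * n_ch + 1L) {
    stop_eegdloc(sprintf(
      "epoch too short for MVAR fit: %d samples for %d parameters per channel",
      n_t, p * n_ch
    ), "eegdloc_estimation_error")
  }
  resp <- t(epoch[, (p + 1L):n_t, drop = FALSE]) # (T-p) x N
  regr <- do.call(cbind, lapply(seq_len(p), function(k) {
    t(epoch[, (p + 1L - k):(n_t - k), drop = FALSE])
  })) # (T-p) x (N*p)
  qr_z <- qr(regr)
  if (qr_z$rank < ncol(regr)) {
    stop_eegdloc("rank-deficient regressor matrix in MVAR fit",
                 "eegdloc_estimation_error")
  }
  coef <- qr.coef(qr_z, resp) # (N*p) x N
  resid <- resp - regr %*% coef
  a_list <- lapply(seq_len(p), function(k) {
    t(coef[((k - 1L) * n_ch + 1L):(k * n_ch), , drop = FALSE])
  })
  structure(
    list(order = p, A = a_list,
         noise_cov = crossprod(resid) / (nrow(resp) - ncol(regr))),
    class = "mvar_model"
  )
}

#' Eigenvalue features of an order-1 MVAR model
#'
#' @param model an order-1 `mvar_model` (or a plain square matrix A).
#' @param threshold modulus threshold for counting slow modes (default 0.95).
#' @return named numeric vector: `f1` max eigenvalue modulus, `f2` min
#'   modulus, `f3` count of moduli strictly above `threshold`. Complex
#'   eigenvalues enter through their modulus.
#' @export
mvar_eigen_features <- function(model, threshold = 0.95) {
  a <- if (inherits(model, "mvar_model")) {
    if (model$order != 1L) {
      config_error("eigenvalue features are defined for order-1 models")
    }
    model$A[[1]]
  } else {
    model
  }
  ev <- Mod(eigen(a, only.values = TRUE)$values)
  c(f1 = max(ev), f2 = min(ev), f3 = sum(ev > threshold))
}
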