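#' Frozen random Gaussian-process functions
#'
#' Samples `n_funs` independent functions from the prior of a Gaussian process
#' with a radial basis function kernel of the given length scale, then freezes
#' each function by interpolating through its values at a common set of
#' `n_anchors` support points drawn from the latent distribution. The frozen
#' functions are deterministic: repeated evaluation at the anchors reproduces
#' the sampled values essentially exactly.
#'
#' The prior sample and the interpolation weights are computed in the
#' eigenbasis of the anchor kernel matrix, truncated to eigenvalues above
#' `1e-12` of the largest. This restricts the sample to the numerically
#' non-degenerate subspace of the kernel (important at large length scales,
#' where the kernel matrix is close to singular) and makes the interpolant
#' reproduce the anchor values to machine precision.
#'
#' @param n_funs Number of independent functions.
#' @param d Input dimensionality.
#' @param length_scale RBF kernel length scale, in latent-space units.
#' @param n_anchors Number of support points (500 by default).
#' @param distribution Distribution the anchor points are drawn from.
#' @param seed Integer seed.
#' @return An object of class `gp_functions` with fields `anchors`
#'   (`n_anchors x d`), `values` (`n_anchors x n_funs`), `weights`, and
#'   `length_scale`.
#' @export
make_gp_functions <- function(n_funs, d, length_scale, n_anchors = 500L,
                              distribution = c("gaussian", "uniform"),
                              seed = 1L) {
  if (length_scale <= 0) stop("invalid-config: length_scale must be positive")
  distribution <- match.arg(distribution)
  anchors <- unclass(sample_latents(n_anchors, d, distribution, seed = seed))
  K <- rbf_kernel(anchors, anchors, length_scale)
  eig <- eigen(K, symmetric = TRUE)
  keep <- eig$values > 1e-12 * eig$values[1]
  Q <- eig$vectors[, keep, drop = FALSE]
  lam <- eig$values[keep]
  z <- with_seed(seed + 1L,
                 matrix(stats::rnorm(sum(keep) * n_funs), sum(keep), n_funs))
  values <- Q %*% (sqrt(lam) * z)              # prior sample at the anchors
  weights <- Q %*% (z / sqrt(lam))             # K^+ %*% values
  structure(list(anchors = anchors, values = values, weights = weights,
                 length_scale = length_scale, seed = seed),
            class = "gp_functions")
}

#' Evaluate frozen Gaussian-process functions
#'
#' @param gp A [make_gp_functions()] object.
#' @param x An `n x d` matrix of evaluation points.
#' @return An `n x n_funs` matrix of function values.
#' @export
evaluate_gp <- function(gp, x) {
  stopifnot(inherits(gp, "gp_functions"))
  x <- as.matrix(unclass(x))
  if (ncol(x) != ncol(gp$anchors))
    stop("invalid-input: dimension mismatch with GP anchors")
  rbf_kernel(x, gp$anchors, gp$length_scale) %*% gp$weights
}

rbf_kernel <- function(x, y, length_scale) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  exp(-pmax(d2, 0) / (2 * length_scale^2))
}
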