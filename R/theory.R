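#' Sign covariance of task label vectors
#'
#' For `P` balanced linear tasks with unit-norm normals `A`, the covariance
#' of the label vector `sign(Ax)` over centered latents has the closed form
#' `M_ij = 1 - (2/pi) arccos(A_i . A_j)`. Its first-order expansion around
#' orthogonal task normals is `M ~ (2/pi) A A'`, whose rank is exactly
#' `min(P, D)` — the analytic account of why the representation layer comes
#' to be dominated by a roughly `min(P, D)`-dimensional component. This
#' function computes the analytic matrix, its linear approximation, and a
#' Monte-Carlo estimate from Gaussian latents, with eigen-spectrum summaries
#' (participation ratio and numerical rank) of each.
#'
#' @param A A `P x D` matrix with unit-norm rows.
#' @param n_samples Monte-Carlo sample count for the empirical estimate.
#' @param seed Integer seed.
#' @param rank_tol Relative eigenvalue threshold for the numerical rank.
#' @return An object of class `sign_covariance` with fields `analytic`,
#'   `linear`, `empirical`, `eigenvalues` (list), `pr` and `rank` (named
#'   vectors), and `n_samples`.
#' @export
sign_covariance <- function(A, n_samples = 1e5, seed = 1L,
                            rank_tol = 1e-10) {
  A <- as.matrix(A)
  check_unit_rows(A)
  G <- tcrossprod(A)
  M_analytic <- 1 - (2 / pi) * acos(pmin(pmax(G, -1), 1))
  M_linear <- (2 / pi) * G
  x <- unclass(sample_latents(as.integer(n_samples), ncol(A), "gaussian",
                              seed = seed))
  s <- sign_pm1(x %*% t(A))
  # raw second moment: the labels are mean-zero for balanced tasks
  M_emp <- crossprod(s) / nrow(s)
  mats <- list(analytic = M_analytic, linear = M_linear, empirical = M_emp)
  eigs <- lapply(mats, function(m) eigen(m, symmetric = TRUE,
                                         only.values = TRUE)$values)
  pr <- vapply(eigs, function(ev) pr_from_eigenvalues(pmax(ev, 0)),
               numeric(1))
  rank <- vapply(eigs, function(ev) sum(ev > rank_tol * max(ev)), numeric(1))
  structure(list(analytic = M_analytic, linear = M_linear,
                 empirical = M_emp, eigenvalues = eigs, pr = pr, rank = rank,
                 n_samples = n_samples, seed = seed),
            class = "sign_covariance")
}

#' @export
print.sign_covariance <- function(x, ...) {
  cat("<sign_covariance>", nrow(x$analytic), "tasks\n")
  cat("  PR:  ", paste(sprintf("%s %.2f", names(x$pr), x$pr),
                       collapse = ", "), "\n")
  cat("  rank:", paste(sprintf("%s %d", names(x$rank), x$rank),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Gap between the exact sign covariance and its linear approximation
#'
#' Off-diagonal discrepancy between the arccos closed form and its Taylor
#' expansion `(2/pi) A A'`. For random unit task normals the dot products
#' concentrate around 0 with variance ~ 1/D, so the gap shrinks as the latent
#' dimensionality grows.
#'
#' @param A A `P x D` matrix with unit-norm rows.
#' @return A list with `max` and `mean` absolute off-diagonal gap.
#' @export
taylor_gap <- function(A) {
  A <- as.matrix(A)
  check_unit_rows(A)
  G <- pmin(pmax(tcrossprod(A), -1), 1)
  gap <- abs((1 - (2 / pi) * acos(G)) - (2 / pi) * G)
  off <- gap[row(gap) != col(gap)]
  if (length(off) == 0) off <- 0
  list(max = max(off), mean = mean(off))
}

#' One step of the idealized representation update
#'
#' For the simplified model with a linear output head `W` and squared-error
#' loss, gradient descent directly on the representation `r(x)` takes the
#' step `r <- r + mu W' sign(Ax) - mu W' W r`. This is an idealization: in
#' the real network the change is achieved indirectly through the preceding
#' weights, whose side effects are ignored here. Iterating the update drives
#' `r` toward a linear transform of the task label vector `sign(Ax)`, which
#' is what endows the representation with the `min(P, D)`-dimensional
#' dominant component analyzed by [sign_covariance()].
#'
#' @param W A `P x m` output weight matrix.
#' @param r Length-`m` representation vector.
#' @param A `P x D` task normals.
#' @param x Length-`D` latent vector.
#' @param mu Step size.
#' @return The updated representation vector.
#' @export
update_rule_check <- function(W, r, A, x, mu) {
  W <- as.matrix(W); A <- as.matrix(A)
  r <- as.numeric(r); x <- as.numeric(x)
  if (ncol(W) != length(r) || ncol(A) != length(x) || nrow(W) != nrow(A))
    stop("invalid-input: inconsistent shapes")
  t_x <- drop(sign_pm1(matrix(A %*% x, 1)))
  r + mu * drop(crossprod(W, t_x)) - mu * drop(crossprod(W, W %*% r))
}

check_unit_rows <- function(A, tol = 1e-6) {
  if (any(abs(sqrt(rowSums(A^2)) - 1) > tol))
    stop("invalid-input: rows of A must be unit norm")
  invisible(A)
}
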