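#' Sample latent variables
#'
#' Draws `n` independent samples of `d` continuous latent variables. These
#' latents are the ground-truth factors that all downstream input encodings
#' and classification tasks are built on. Gaussian latents are standard normal
#' per dimension; uniform latents are on `[-1, 1]` per dimension, centered so
#' that sign-based half-space splits remain balanced.
#'
#' @param n Number of samples.
#' @param d Number of latent dimensions.
#' @param distribution `"gaussian"` or `"uniform"`.
#' @param seed Integer seed; identical arguments give identical output.
#' @return An `n x d` matrix of class `latent_sample` with attributes
#'   `distribution` and `seed`.
#' @examples
#' x <- sample_latents(1000, 5, seed = 1)
#' colMeans(x)
#' @export
sample_latents <- function(n, d, distribution = c("gaussian", "uniform"),
                           seed = 1L) {
  if (n < 1 || d < 1) stop("invalid-config: n and d must be at least 1")
  distribution <- match.arg(distribution)
  x <- with_seed(seed, switch(distribution,
    gaussian = matrix(stats::rnorm(n * d), n, d),
    uniform = matrix(stats::runif(n * d, -1, 1), n, d)
  ))
  structure(x, distribution = distribution, seed = seed,
            class = c("latent_sample", class(x)))
}

#' Construct a random orthogonal pair of half-space divisions
#'
#' Draws two orthonormal direction vectors in latent space. The first
#' (`split_normal`) divides the space into a training half `{x : u'x > 0}`
#' and a testing half; the second (`target_normal`) is orthogonal to it and
#' defines the decoded category (or selects regression targets) for the
#' generalization metrics. Both divisions pass through the origin, so they
#' are balanced for the centered latent distributions used here.
#'
#' @param d Latent dimensionality, at least 2 (an orthogonal second division
#'   does not exist for `d = 1`).
#' @param seed Integer seed.
#' @return A list of class `half_space_split` with unit vectors
#'   `split_normal` and `target_normal`.
#' @export
make_split <- function(d, seed = 1L) {
  if (d < 2) stop("invalid-config: d must be >= 2 for an orthogonal split pair")
  with_seed(seed, {
    u <- stats::rnorm(d)
    u <- u / sqrt(sum(u^2))
    v <- stats::rnorm(d)
    v <- v - sum(v * u) * u
    v <- v / sqrt(sum(v^2))
    structure(list(split_normal = u, target_normal = v),
              class = "half_space_split")
  })
}

#' Sample latents restricted to one half of latent space
#'
#' Rejection-samples from the unconditional latent distribution, keeping only
#' points on the requested side of the split plane. Rejection preserves the
#' exact conditional law at roughly twice the sampling cost.
#'
#' @param split A [make_split()] object.
#' @param side `"train"` (points with `u'x > 0`) or `"test"` (`u'x <= 0`).
#' @param n Number of samples to return.
#' @param d Latent dimensionality (must match the split).
#' @param distribution Latent distribution tag.
#' @param seed Integer seed.
#' @return An `n x d` `latent_sample` matrix, all on the requested side.
#' @export
sample_in_half <- function(split, side = c("train", "test"), n, d,
                           distribution = c("gaussian", "uniform"),
                           seed = 1L) {
  side <- match.arg(side)
  distribution <- match.arg(distribution)
  stopifnot(inherits(split, "half_space_split"),
            length(split$split_normal) == d)
  u <- split$split_normal
  out <- with_seed(seed, {
    acc <- matrix(numeric(0), 0, d)
    while (nrow(acc) < n) {
      m <- max(2L * (n - nrow(acc)), 64L)
      x <- switch(distribution,
        gaussian = matrix(stats::rnorm(m * d), m, d),
        uniform = matrix(stats::runif(m * d, -1, 1), m, d)
      )
      proj <- drop(x %*% u)
      keep <- if (side == "train") proj > 0 else proj <= 0
      acc <- rbind(acc, x[keep, , drop = FALSE])
    }
    acc[seq_len(n), , drop = FALSE]
  })
  structure(out, distribution = distribution, seed = seed,
            class = c("latent_sample", class(out)))
}

# run expr under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
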