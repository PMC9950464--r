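#' Random linear (full) classification tasks
#'
#' Generates `p` binary classification tasks on the latent variables, each
#' defined by a random hyperplane through the origin: the label of `x` for
#' task `i` is `sign(A_i . x)`. Task normals are i.i.d. uniform on the unit
#' sphere; unit norm leaves the labels unchanged and makes the task normals
#' directly usable in the arccos sign-covariance formula.
#'
#' @param p Number of tasks.
#' @param d Latent dimensionality.
#' @param seed Integer seed.
#' @return An object of class `c("linear_tasks", "task_set")` with fields
#'   `A` (`p x d`, unit rows), `b` (offsets, zero here), `C` (context matrix,
#'   `NULL` here), `kind`, `sigma_offset`, `p`, `d`.
#' @examples
#' ts <- make_linear_tasks(10, 5, seed = 1)
#' labels <- evaluate_tasks(ts, sample_latents(100, 5, seed = 2))
#' @export
make_linear_tasks <- function(p, d, seed = 1L) {
  new_linear_tasks(p, d, kind = "full", sigma_offset = 0, contextual = FALSE,
                   seed = seed)
}

#' Unbalanced classification tasks
#'
#' As [make_linear_tasks()], but each hyperplane is shifted away from the
#' origin by a random offset `b_i ~ N(0, sigma_offset)`, so the two label
#' classes are no longer equally probable. Labels are `sign(A_i . x + b_i)`.
#' With `sigma_offset = 0` this reduces exactly to the full tasks at the same
#' seed.
#'
#' @inheritParams make_linear_tasks
#' @param sigma_offset Standard deviation of the hyperplane offsets.
#' @export
make_unbalanced_tasks <- function(p, d, sigma_offset = 0.4, seed = 1L) {
  if (sigma_offset < 0) stop("invalid-config: sigma_offset must be >= 0")
  new_linear_tasks(p, d, kind = "unbalanced", sigma_offset = sigma_offset,
                   contextual = FALSE, seed = seed)
}

#' Contextual classification tasks
#'
#' As [make_linear_tasks()], but each task only provides a label within half
#' of latent space: task `i` has label `sign(A_i . x)` when `C_i . x > 0` and
#' an absent (masked) target otherwise. The context normals `C_i` are drawn
#' independently of the task normals.
#'
#' @inheritParams make_linear_tasks
#' @export
make_contextual_tasks <- function(p, d, seed = 1L) {
  new_linear_tasks(p, d, kind = "contextual", sigma_offset = 0,
                   contextual = TRUE, seed = seed)
}

new_linear_tasks <- function(p, d, kind, sigma_offset, contextual, seed) {
  if (p < 1 || d < 1) stop("invalid-config: p and d must be at least 1")
  with_seed(seed, {
    A <- matrix(stats::rnorm(p * d), p, d)
    A <- A / sqrt(rowSums(A^2))
    b <- if (sigma_offset > 0) stats::rnorm(p, 0, sigma_offset) else
      numeric(p)
    C <- NULL
    if (contextual) {
      C <- matrix(stats::rnorm(p * d), p, d)
      C <- C / sqrt(rowSums(C^2))
    }
    structure(list(A = A, b = b, C = C, kind = kind,
                   sigma_offset = sigma_offset, p = p, d = d, seed = seed),
              class = c("linear_tasks", "task_set"))
  })
}

#' Grid classification tasks
#'
#' Divides each latent dimension into `grid_n` bins of (approximately) equal
#' occupation probability using the quantiles of the latent distribution, so
#' latent space is partitioned into `grid_n^d` hyper-rectangular chambers.
#' Each task assigns every chamber independently to one of the two categories
#' with a fair coin; there is no enforced spatial dependence, so these tasks
#' are deliberately misaligned with the latent variables.
#'
#' @inheritParams make_linear_tasks
#' @param grid_n Number of bins per dimension (at least 2).
#' @param distribution Latent distribution whose quantiles define the bins.
#' @param chamber_limit Refuse task sets with more chambers than this.
#' @export
make_grid_tasks <- function(p, d, grid_n, seed = 1L,
                            distribution = c("gaussian", "uniform"),
                            chamber_limit = 1e6) {
  if (grid_n < 2) stop("invalid-config: grid_n must be >= 2")
  distribution <- match.arg(distribution)
  n_chambers <- grid_n^d
  if (n_chambers > chamber_limit)
    stop("invalid-config: grid_n^d exceeds the chamber limit")
  qfun <- switch(distribution,
    gaussian = function(q) stats::qnorm(q),
    uniform = function(q) 2 * q - 1
  )
  edges <- qfun(seq_len(grid_n - 1) / grid_n)
  assignment <- with_seed(seed,
    matrix(sample(c(-1, 1), n_chambers * p, replace = TRUE), n_chambers, p))
  structure(list(p = p, d = d, grid_n = grid_n, bin_edges = edges,
                 assignment = assignment, distribution = distribution,
                 seed = seed),
            class = c("grid_tasks", "task_set"))
}

#' Random Gaussian-process classification tasks
#'
#' Each task is the sign of an independent frozen random Gaussian-process
#' function with an RBF kernel of the given length scale (values above 0 form
#' one category, values at or below 0 the other). Small length scales give
#' highly curved category boundaries; as the length scale grows the boundary
#' approaches a single hyperplane and the tasks approach linear behavior.
#'
#' @inheritParams make_linear_tasks
#' @param length_scale RBF length scale of the task functions.
#' @param n_anchors Support points per frozen function.
#' @param distribution Distribution of the anchor points.
#' @export
make_gp_tasks <- function(p, d, length_scale, seed = 1L, n_anchors = 500L,
                          distribution = c("gaussian", "uniform")) {
  distribution <- match.arg(distribution)
  gp <- make_gp_functions(p, d, length_scale, n_anchors, distribution, seed)
  structure(list(p = p, d = d, length_scale = length_scale, functions = gp,
                 threshold = 0, seed = seed),
            class = c("gp_tasks", "task_set"))
}

#' Combine several task sets into one
#'
#' Concatenates the tasks of two or more task sets over the same latent
#' space, e.g. linear tasks plus grid tasks for mixture experiments.
#'
#' @param ... Task sets with matching `d`.
#' @export
mixture_tasks <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "task_set")) parts <- parts[[1]]
  stopifnot(length(parts) >= 1,
            all(vapply(parts, inherits, logical(1), "task_set")))
  d <- unique(vapply(parts, function(t) t$d, numeric(1)))
  if (length(d) != 1) stop("invalid-config: task sets differ in d")
  structure(list(parts = parts, p = sum(vapply(parts, function(t) t$p,
                                               numeric(1))), d = d),
            class = c("mixture_tasks", "task_set"))
}

#' Evaluate a task set on latent samples
#'
#' Computes the `n x p` matrix of binary targets in `{-1, +1}`, with `NA` for
#' absent targets (contextual tasks outside their context). The logical
#' attribute `"mask"` marks present entries; absent entries are ignored
#' during network training.
#'
#' @param taskset A `task_set` object.
#' @param latents An `n x d` latent matrix.
#' @return A `target_matrix`: `n x p` matrix of `+1 / -1 / NA` with a
#'   `"mask"` attribute.
#' @export
evaluate_tasks <- function(taskset, latents) {
  UseMethod("evaluate_tasks")
}

#' @export
evaluate_tasks.linear_tasks <- function(taskset, latents) {
  x <- check_latents(taskset, latents)
  raw <- x %*% t(taskset$A) + rep(taskset$b, each = nrow(x))
  values <- sign_pm1(raw)
  mask <- matrix(TRUE, nrow(x), taskset$p)
  if (!is.null(taskset$C)) {
    mask <- (x %*% t(taskset$C)) > 0
    values[!mask] <- NA_real_
  }
  new_target_matrix(values, mask)
}

#' @export
evaluate_tasks.grid_tasks <- function(taskset, latents) {
  x <- check_latents(taskset, latents)
  bins <- vapply(seq_len(taskset$d), function(j)
    findInterval(x[, j], taskset$bin_edges), integer(nrow(x)))
  bins <- matrix(bins, nrow(x), taskset$d)
  chamber <- drop(bins %*% taskset$grid_n^(seq_len(taskset$d) - 1)) + 1L
  values <- taskset$assignment[chamber, , drop = FALSE]
  new_target_matrix(values, matrix(TRUE, nrow(x), taskset$p))
}

#' @export
evaluate_tasks.gp_tasks <- function(taskset, latents) {
  x <- check_latents(taskset, latents)
  values <- sign_pm1(evaluate_gp(taskset$functions, x))
  new_target_matrix(values, matrix(TRUE, nrow(x), taskset$p))
}

#' @export
evaluate_tasks.mixture_tasks <- function(taskset, latents) {
  evals <- lapply(taskset$parts, evaluate_tasks, latents = latents)
  values <- do.call(cbind, lapply(evals, unclass))
  mask <- do.call(cbind, lapply(evals, attr, "mask"))
  new_target_matrix(values, mask)
}

#' Mask targets down to partial task information
#'
#' Models training examples that carry information about only some tasks. In
#' `"one-per-sample"` mode exactly one randomly chosen task per example keeps
#' its target and all others are masked (the strict regime). In `"fraction"`
#' mode each entry is independently masked with probability
#' `missing_fraction`.
#'
#' @param targets A `target_matrix` from [evaluate_tasks()].
#' @param mode `"one-per-sample"` or `"fraction"`.
#' @param missing_fraction Probability an entry is masked (fraction mode).
#' @param seed Integer seed.
#' @return A `target_matrix` with the reduced mask.
#' @export
apply_partial_information <- function(targets,
                                      mode = c("one-per-sample", "fraction"),
                                      missing_fraction = 0.9, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(targets, "target_matrix"))
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("invalid-config: missing_fraction must be in [0, 1)")
  values <- unclass(targets)
  mask <- attr(targets, "mask")
  n <- nrow(values); p <- ncol(values)
  if (mode == "one-per-sample") {
    keep_col <- with_seed(seed, sample.int(p, n, replace = TRUE))
    keep <- matrix(FALSE, n, p)
    keep[cbind(seq_len(n), keep_col)] <- TRUE
    mask <- mask & keep
  } else if (missing_fraction > 0) {
    drop <- with_seed(seed,
                      matrix(stats::runif(n * p) < missing_fraction, n, p))
    mask <- mask & !drop
  }
  values[!mask] <- NA_real_
  new_target_matrix(values, mask)
}

#' Pairwise alignment between tasks
#'
#' Estimates the Monte-Carlo correlation matrix between the label vectors of
#' two task sets over the latent distribution. When both sets are linear, the
#' absolute cosine similarities of their task normals are also returned.
#'
#' @param taskset_a,taskset_b Task sets over the same latent space.
#' @param n_samples Monte-Carlo sample size.
#' @param distribution Latent distribution.
#' @param seed Integer seed.
#' @return A list with `correlation` (`p_a x p_b`) and `cosine` (or `NULL`).
#' @export
task_alignment <- function(taskset_a, taskset_b = taskset_a,
                           n_samples = 1e4,
                           distribution = c("gaussian", "uniform"),
                           seed = 1L) {
  distribution <- match.arg(distribution)
  if (taskset_a$d != taskset_b$d) stop("invalid-config: task sets differ in d")
  x <- sample_latents(n_samples, taskset_a$d, distribution, seed)
  la <- unclass(evaluate_tasks(taskset_a, x))
  lb <- unclass(evaluate_tasks(taskset_b, x))
  corr <- suppressWarnings(stats::cor(la, lb, use = "pairwise.complete.obs"))
  cosine <- NULL
  if (inherits(taskset_a, "linear_tasks") && inherits(taskset_b, "linear_tasks"))
    cosine <- abs(tcrossprod(taskset_a$A, taskset_b$A))
  list(correlation = corr, cosine = cosine)
}

#' Embedding dimensionality of the task output patterns
#'
#' Participation ratio of the `n x p` matrix of task labels: the effective
#' dimensionality of the binary output patterns a task collection requires.
#' Linear tasks on `d` latents need only about `min(p, d)` output dimensions,
#' while grid tasks push this toward `p`.
#'
#' @param taskset A task set whose evaluation has no absent labels.
#' @param latents Latent samples to evaluate on.
#' @export
task_output_dimensionality <- function(taskset, latents) {
  values <- evaluate_tasks(taskset, latents)
  if (any(!attr(values, "mask")))
    stop("invalid-input: task output dimensionality requires no absent labels")
  participation_ratio(unclass(values))
}

new_target_matrix <- function(values, mask) {
  structure(values, mask = mask, class = c("target_matrix", "matrix"))
}

check_latents <- function(taskset, latents) {
  x <- as.matrix(unclass(latents))
  if (ncol(x) != taskset$d)
    stop("invalid-input: latent dimension does not match task set")
  x
}

# sign with the tie broken upward, so labels are always +/-1
sign_pm1 <- function(z) {
  out <- matrix(-1, nrow(z), ncol(z))
  out[z > 0] <- 1
  out
}
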