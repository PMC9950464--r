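#' Participation ratio of a population response
#'
#' `PR = (sum lambda)^2 / sum lambda^2` over the eigenvalues of the sample
#' covariance of the activation matrix: a soft count of embedding dimensions,
#' equal to 1 when a single eigenvalue carries all variance and to the number
#' of units when all eigenvalues are equal. Computed through the trace
#' identities `tr(C)` and `tr(C^2)`, which equal the eigenvalue sums exactly.
#'
#' @param activations An `n x m` matrix, rows are samples (`n >= 2`).
#' @return The participation ratio (scalar).
#' @examples
#' participation_ratio(matrix(rnorm(4000 * 5), 4000, 5))  # close to 5
#' @export
participation_ratio <- function(activations) {
  x <- as.matrix(unclass(activations))
  if (nrow(x) < 2) stop("invalid-input: need at least 2 samples")
  xc <- sweep(x, 2, colMeans(x))
  C <- crossprod(xc) / (nrow(x) - 1)
  tr <- sum(diag(C))
  if (tr <= 0) stop("invalid-input: zero total variance")
  tr^2 / sum(C^2)
}

#' Participation ratio from an eigenvalue spectrum
#'
#' @param lambda Non-negative eigenvalues of a covariance matrix.
#' @export
pr_from_eigenvalues <- function(lambda) {
  if (sum(lambda) <= 0) stop("invalid-input: zero total variance")
  sum(lambda)^2 / sum(lambda^2)
}

#' Per-unit lifetime sparseness
#'
#' `S = 1 - E[r]^2 / E[r^2]` for each unit's non-negative response `r` over
#' stimuli: near 1 for a unit that responds to one or a few stimuli, 0 for a
#' unit with constant response. Units that never respond are excluded from
#' the mean and counted separately.
#'
#' @param activations An `n x m` non-negative activation matrix.
#' @return A list with `per_unit` (length `m`, `NA` for silent units),
#'   `mean`, and `n_silent`.
#' @export
sparseness <- function(activations) {
  x <- as.matrix(unclass(activations))
  if (any(x < 0))
    stop("invalid-input: sparseness assumes non-negative (rectified) rates")
  e1 <- colMeans(x)
  e2 <- colMeans(x^2)
  per_unit <- ifelse(e2 > 0, 1 - e1^2 / e2, NA_real_)
  list(per_unit = per_unit, mean = mean(per_unit, na.rm = TRUE),
       n_silent = sum(e2 == 0))
}

#' Classifier generalization metric
#'
#' Quantifies abstractness of a representation by cross-condition decoding:
#' draw a random balanced division of latent space (the train/test halves)
#' and an orthogonal second division (the decoded category); train a linear
#' classifier on `n_train` encoded stimuli from the training half, labeled by
#' the sign of the category division; report its accuracy on `n_test` stimuli
#' from the held-out half (`generalization_score`). The `standard_score` is
#' the same classifier's held-out accuracy when trained and tested across the
#' whole space. Chance is 0.5 for these balanced categories. Scores are
#' averaged over `n_splits` random division pairs.
#'
#' The classifier is ridge-penalized logistic regression (glmnet, `alpha =
#' 0`) with penalty `lambda = 1 / (n_train * cost)`, matching an
#' inverse-regularization (cost) parameter of 1 on the unnormalized loss.
#'
#' @param rep A `representation_map`.
#' @param d Latent dimensionality.
#' @param distribution Latent distribution.
#' @param n_train,n_test Training and testing sample counts.
#' @param n_splits Number of random division pairs to average over.
#' @param cost Inverse regularization strength of the classifier.
#' @param seed Integer seed.
#' @return A list of class `generalization_result` with `metric`,
#'   `standard_score`, `generalization_score`, the per-split scores, and the
#'   sampling parameters.
#' @export
classifier_generalization <- function(rep, d,
                                      distribution = c("gaussian", "uniform"),
                                      n_train = 1000L, n_test = 2000L,
                                      n_splits = 10L, cost = 1,
                                      seed = 1L) {
  distribution <- match.arg(distribution)
  gen <- std <- numeric(n_splits)
  for (k in seq_len(n_splits)) {
    sk <- seed + 1000L * (k - 1L)
    split <- make_split(d, seed = sk)
    tr <- sample_in_half(split, "train", n_train, d, distribution, sk + 1L)
    te <- sample_in_half(split, "test", n_test, d, distribution, sk + 2L)
    gen[k] <- fit_linear_classifier(rep, split, tr, te, n_train, cost)
    wtr <- sample_latents(n_train, d, distribution, seed = sk + 3L)
    wte <- sample_latents(n_test, d, distribution, seed = sk + 4L)
    std[k] <- fit_linear_classifier(rep, split, wtr, wte, n_train, cost)
  }
  structure(list(metric = "classifier", standard_score = mean(std),
                 generalization_score = mean(gen), per_split_standard = std,
                 per_split_generalization = gen, n_train = n_train,
                 n_test = n_test, n_splits = n_splits, seed = seed),
            class = "generalization_result")
}

fit_linear_classifier <- function(rep, split, train_lat, test_lat, n_train,
                                  cost) {
  ytr <- factor(drop(unclass(train_lat) %*% split$target_normal) > 0,
                levels = c(FALSE, TRUE))
  yte <- drop(unclass(test_lat) %*% split$target_normal) > 0
  ztr <- encode_latents(rep, train_lat)
  zte <- encode_latents(rep, test_lat)
  fit <- tryCatch(
    glmnet::glmnet(ztr, ytr, family = "binomial", alpha = 0,
                   lambda = 1 / (n_train * cost), standardize = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("degenerate encoding; classifier score set to chance")
    return(0.5)
  }
  pred <- drop(stats::predict(fit, zte, type = "class")) == "TRUE"
  mean(pred == yte)
}

#' Regression generalization metric
#'
#' The stricter companion of [classifier_generalization()]: a linear ridge
#' regression is trained to read out all `d` latent variables from `n_train`
#' encoded stimuli drawn from the training half of latent space, and
#' evaluated on `n_test` stimuli from the held-out half with
#' `r^2 = 1 - MSE / Var`, averaged over the `d` latent dimensions. Chance
#' (always predicting the mean) gives `r^2 = 0`; the score is unbounded
#' below. The `standard_score` uses whole-space train and test samples.
#'
#' @inheritParams classifier_generalization
#' @param ridge Ridge penalty added to the normal equations.
#' @export
regression_generalization <- function(rep, d,
                                      distribution = c("gaussian", "uniform"),
                                      n_train = 4000L, n_test = 1000L,
                                      n_splits = 10L, ridge = 1,
                                      seed = 1L) {
  distribution <- match.arg(distribution)
  gen <- std <- numeric(n_splits)
  for (k in seq_len(n_splits)) {
    sk <- seed + 1000L * (k - 1L)
    split <- make_split(d, seed = sk)
    tr <- sample_in_half(split, "train", n_train, d, distribution, sk + 1L)
    te <- sample_in_half(split, "test", n_test, d, distribution, sk + 2L)
    gen[k] <- fit_ridge_readout(rep, tr, te, ridge)
    wtr <- sample_latents(n_train, d, distribution, seed = sk + 3L)
    wte <- sample_latents(n_test, d, distribution, seed = sk + 4L)
    std[k] <- fit_ridge_readout(rep, wtr, wte, ridge)
  }
  structure(list(metric = "regression", standard_score = mean(std),
                 generalization_score = mean(gen), per_split_standard = std,
                 per_split_generalization = gen, n_train = n_train,
                 n_test = n_test, n_splits = n_splits, seed = seed),
            class = "generalization_result")
}

fit_ridge_readout <- function(rep, train_lat, test_lat, ridge) {
  ztr <- encode_latents(rep, train_lat)
  zte <- encode_latents(rep, test_lat)
  ytr <- unclass(train_lat)
  yte <- unclass(test_lat)
  mu_z <- colMeans(ztr)
  mu_y <- colMeans(ytr)
  zc <- sweep(ztr, 2, mu_z)
  if (sum(zc^2) == 0) {
    warning("degenerate encoding; regression score set to chance")
    return(0)
  }
  beta <- tryCatch({
    G <- crossprod(zc)
    diag(G) <- diag(G) + ridge
    solve(G, crossprod(zc, sweep(ytr, 2, mu_y)))
  }, error = function(e) NULL)
  if (is.null(beta)) {
    warning("degenerate encoding; regression score set to chance")
    return(0)
  }
  pred <- sweep(sweep(zte, 2, mu_z) %*% beta, 2, mu_y, "+")
  mse <- colMeans((pred - yte)^2)
  v <- apply(yte, 2, stats::var)
  mean(1 - mse / v)
}

#' @export
print.generalization_result <- function(x, ...) {
  cat(sprintf("<%s generalization> standard: %.3f  generalization: %.3f  (%d splits)\n",
              x$metric, x$standard_score, x$generalization_score, x$n_splits))
  invisible(x)
}

#' Few-shot learning of a novel task
#'
#' Measures how efficiently a novel binary task can be learned from a
#' representation with limited samples: for each sample count `k`, a linear
#' classifier is trained on `k` encoded stimuli and evaluated on a held-out
#' set. The curve is computed for the representation under study, for the raw
#' input encoding (lower bound), and for the latent variables themselves
#' (upper bound). In `"standard"` mode training and test stimuli come from
#' the whole space; in `"generalization"` mode training stimuli come from the
#' training half of a random split and test stimuli from the other half.
#'
#' @param rep Representation under study.
#' @param input_encoding The raw input `representation_map` (lower bound).
#' @param d Latent dimensionality.
#' @param task A task set with a single task, not among the trained tasks.
#' @param sample_counts Training sample counts (entries below 2 are skipped).
#' @param mode `"standard"` or `"generalization"`.
#' @param n_test Held-out test sample count.
#' @param distribution Latent distribution.
#' @param seed Integer seed.
#' @return A list of class `few_shot_curve` with `sample_counts`,
#'   `model_scores`, `lower_bound_scores`, `upper_bound_scores`, `mode`.
#' @export
few_shot_novel_task <- function(rep, input_encoding, d, task, sample_counts,
                                mode = c("standard", "generalization"),
                                n_test = 2000L,
                                distribution = c("gaussian", "uniform"),
                                seed = 1L) {
  mode <- match.arg(mode)
  distribution <- match.arg(distribution)
  stopifnot(task$p == 1)
  keep <- sample_counts >= 2
  if (any(!keep)) warning("sample counts below 2 skipped")
  sample_counts <- sample_counts[keep]
  split <- make_split(d, seed = seed)
  pool_seed <- seed + 17L
  draw <- function(n, s, side) {
    if (mode == "standard") sample_latents(n, d, distribution, seed = s)
    else sample_in_half(split, side, n, d, distribution, seed = s)
  }
  test_lat <- draw(n_test, pool_seed, "test")
  yte <- drop(unclass(evaluate_tasks(task, test_lat)))
  reps <- list(model = rep, lower = input_encoding,
               upper = identity_representation(d))
  scores <- lapply(reps, function(r) {
    vapply(seq_along(sample_counts), function(i) {
      k <- sample_counts[i]
      tr <- draw(k, pool_seed + i, "train")
      ytr <- drop(unclass(evaluate_tasks(task, tr)))
      few_shot_classifier(encode_latents(r, tr), ytr,
                          encode_latents(r, test_lat), yte)
    }, numeric(1))
  })
  structure(list(sample_counts = sample_counts,
                 model_scores = scores$model,
                 lower_bound_scores = scores$lower,
                 upper_bound_scores = scores$upper, mode = mode),
            class = "few_shot_curve")
}

# linear classifier robust to tiny samples: glmnet when feasible, otherwise
# a nearest-class-mean rule
few_shot_classifier <- function(ztr, ytr, zte, yte) {
  fit <- NULL
  if (length(unique(ytr)) == 2 && length(ytr) >= 4)
    fit <- tryCatch(glmnet::glmnet(ztr, factor(ytr), family = "binomial",
                                   alpha = 0, lambda = 1 / length(ytr),
                                   standardize = FALSE),
                    error = function(e) NULL)
  if (!is.null(fit)) {
    pred <- as.numeric(drop(stats::predict(fit, zte, type = "class")))
    return(mean(pred == yte))
  }
  if (length(unique(ytr)) < 2) return(mean(yte == ytr[1]))
  mu_pos <- colMeans(ztr[ytr > 0, , drop = FALSE])
  mu_neg <- colMeans(ztr[ytr < 0, , drop = FALSE])
  w <- mu_pos - mu_neg
  thr <- sum(w * (mu_pos + mu_neg)) / 2
  pred <- ifelse(drop(zte %*% w) > thr, 1, -1)
  mean(pred == yte)
}
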