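test_that("linear tasks are unit-norm random hyperplanes with balanced labels", {
  ts <- make_linear_tasks(10, 5, seed = 1)
  expect_equal(dim(ts$A), c(10, 5))
  expect_equal(sqrt(rowSums(ts$A^2)), rep(1, 10), tolerance = 1e-12)
  expect_equal(ts$b, rep(0, 10))

  # label definition: sign of the projection
  ts1 <- ts
  ts1$A <- matrix(c(1, 0, 0, 0, 0), 1, 5)
  ts1$b <- 0
  ts1$p <- 1L
  lab <- evaluate_tasks(ts1, matrix(c(2, 0, 0, 0, 0), 1, 5))
  expect_equal(as.numeric(lab), 1)

  x <- sample_latents(1e4, 5, seed = 2)
  labs <- unclass(evaluate_tasks(ts, x))
  pos <- colMeans(labs > 0)
  expect_true(all(abs(pos - 0.5) < 0.02))

  # odd symmetry: x and -x get opposite labels
  labs_neg <- unclass(evaluate_tasks(ts, -unclass(x)))
  expect_true(all(labs * labs_neg == -1))
})

test_that("unbalanced tasks reduce to full tasks at zero offset and tilt label rates", {
  x <- sample_latents(1e4, 5, seed = 3)
  t0 <- make_unbalanced_tasks(6, 5, sigma_offset = 0, seed = 9)
  tf <- make_linear_tasks(6, 5, seed = 9)
  expect_identical(unclass(evaluate_tasks(t0, x)),
                   unclass(evaluate_tasks(tf, x)))

  # unit row with offset +2: positive fraction is Phi(2)
  tb <- make_linear_tasks(1, 5, seed = 4)
  tb$b <- 2
  frac <- mean(unclass(evaluate_tasks(tb, x)) > 0)
  expect_equal(frac, pnorm(2), tolerance = 0.01)

  # larger offsets make labels less informative (lower label entropy)
  ent <- function(p) ifelse(p %in% c(0, 1), 0, -p * log2(p) - (1 - p) * log2(1 - p))
  mean_ent <- sapply(c(0, 0.8, 2), function(s) {
    tu <- make_unbalanced_tasks(40, 5, sigma_offset = s, seed = 5)
    mean(ent(colMeans(unclass(evaluate_tasks(tu, x)) > 0)))
  })
  expect_true(all(diff(mean_ent) < 0))
})

test_that("contextual tasks mask half of latent space and agree with full tasks inside", {
  x <- sample_latents(1e4, 5, seed = 6)
  tc <- make_contextual_tasks(8, 5, seed = 7)
  tf <- make_linear_tasks(8, 5, seed = 7)
  tgt <- evaluate_tasks(tc, x)
  mask <- attr(tgt, "mask")
  expect_identical(mask, unclass(x %*% t(tc$C)) > 0)
  expect_true(all(abs(colMeans(mask) - 0.5) < 0.02))
  expect_true(all(is.na(unclass(tgt)[!mask])))
  full <- unclass(evaluate_tasks(tf, x))
  expect_identical(unclass(tgt)[mask], full[mask])
})

test_that("partial information masking follows its two modes", {
  x <- sample_latents(100, 5, seed = 8)
  tgt <- evaluate_tasks(make_linear_tasks(15, 5, seed = 9), x)
  one <- apply_partial_information(tgt, "one-per-sample", seed = 10)
  expect_equal(rowSums(attr(one, "mask")), rep(1, 100))
  expect_true(all(is.na(unclass(one)[!attr(one, "mask")])))

  big <- evaluate_tasks(make_linear_tasks(10, 5, seed = 9),
                        sample_latents(10000, 5, seed = 11))
  frac <- apply_partial_information(big, "fraction", missing_fraction = 0.9,
                                    seed = 12)
  expect_equal(mean(attr(frac, "mask")), 0.1, tolerance = 0.01)

  none <- apply_partial_information(big, "fraction", missing_fraction = 0,
                                    seed = 13)
  expect_identical(attr(none, "mask"), attr(big, "mask"))
  expect_error(apply_partial_information(big, "fraction", 1), "invalid-config")
})

test_that("grid tasks partition latent space into equal-probability chambers", {
  expect_error(make_grid_tasks(3, 5, 1), "invalid-config")
  expect_error(make_grid_tasks(3, 10, 10), "invalid-config")

  gt <- make_grid_tasks(4, 5, 2, seed = 1)
  expect_equal(nrow(gt$assignment), 32)

  # chamber occupancy is uniform within a few percent relative
  x <- sample_latents(1e5, 5, seed = 2)
  bins <- sapply(1:5, function(j) findInterval(x[, j], gt$bin_edges))
  chamber <- drop(bins %*% 2^(0:4)) + 1
  occ <- tabulate(chamber, 32) / 1e5
  expect_true(all(abs(occ - 1 / 32) / (1 / 32) < 0.1))

  # two points in the same chamber always share a label
  same <- evaluate_tasks(gt, rbind(c(0.1, 0.1, 0.1, 0.1, 0.1),
                                   c(0.2, 0.3, 0.1, 0.4, 0.2)))
  expect_equal(unclass(same)[1, ], unclass(same)[2, ])

  # degenerate case: one dimension, two bins = a threshold task at the median
  g1 <- make_grid_tasks(1, 1, 2, seed = 3)
  xs <- matrix(seq(-2, 2, length.out = 50), 50, 1)
  labs <- drop(unclass(evaluate_tasks(g1, xs)))
  expect_true(all(labs[xs < 0] == labs[1]) && all(labs[xs > 0] == labs[50]))
})

test_that("GP tasks are signs of frozen functions and approach linear tasks at large scale", {
  gt <- make_gp_tasks(3, 2, length_scale = 1, seed = 1)
  vals <- evaluate_gp(gt$functions, gt$functions$anchors)
  labs <- unclass(evaluate_tasks(gt, gt$functions$anchors))
  expect_equal(labs, ifelse(vals > 0, 1, -1), ignore_attr = TRUE)

  # very smooth GP tasks are nearly linearly separable (tasks that put all
  # mass in one category are trivially so and are skipped)
  x <- sample_latents(3000, 5, seed = 3)
  linear_agreement <- function(ls) {
    labs <- unclass(evaluate_tasks(make_gp_tasks(6, 5, ls, seed = 2), x))
    mean(sapply(1:6, function(j) {
      if (length(unique(labs[, j])) < 2) return(1)  # constant: trivially linear
      fit <- suppressWarnings(
        glmnet::glmnet(unclass(x), factor(labs[, j]), family = "binomial",
                       alpha = 0, lambda = 1e-4))
      mean((drop(predict(fit, unclass(x), type = "class")) == "1") ==
             (labs[, j] > 0))
    }))
  }
  ag <- sapply(c(1, 2, 8), linear_agreement)
  expect_true(all(diff(ag) > 0))   # smoother tasks are closer to linear
  expect_gt(ag[3], 0.95)
})

test_that("task evaluation validates dimensions and is deterministic", {
  ts <- make_linear_tasks(3, 5, seed = 1)
  expect_error(evaluate_tasks(ts, matrix(0, 5, 4)), "invalid-input")
  x <- sample_latents(50, 5, seed = 2)
  expect_identical(evaluate_tasks(ts, x), evaluate_tasks(ts, x))
})

test_that("task alignment matches the arccos law and separates grid from linear tasks", {
  # orthogonal linear tasks have uncorrelated labels
  ts <- make_linear_tasks(2, 5, seed = 1)
  ts$A <- rbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0))
  al <- task_alignment(ts, n_samples = 1e4, seed = 2)
  expect_equal(diag(al$correlation), c(1, 1), tolerance = 1e-12)
  expect_lt(abs(al$correlation[1, 2]), 0.03)
  expect_equal(al$cosine[1, 2], 0)

  # grid tasks are more weakly correlated than random linear tasks
  lin <- make_linear_tasks(10, 5, seed = 3)
  grd <- make_grid_tasks(10, 5, 3, seed = 4)
  al_lin <- task_alignment(lin, n_samples = 5e3, seed = 5)$correlation
  al_grd <- task_alignment(grd, n_samples = 5e3, seed = 5)$correlation
  off <- function(m) abs(m[row(m) != col(m)])
  expect_lt(mean(off(al_grd)), mean(off(al_lin)))
})

test_that("label covariance matches the analytic arccos form (Monte-Carlo oracle)", {
  set.seed(42)
  for (rep in 1:3) {
    A <- matrix(rnorm(4 * 5), 4, 5)
    A <- A / sqrt(rowSums(A^2))
    x <- sample_latents(1e5, 5, seed = rep)
    labs <- unclass(evaluate_tasks(
      structure(list(A = A, b = rep(0, 4), C = NULL, kind = "full",
                     sigma_offset = 0, p = 4L, d = 5L, seed = 0L),
                class = c("linear_tasks", "task_set")), x))
    emp <- crossprod(labs) / 1e5
    ana <- 1 - (2 / pi) * acos(pmin(pmax(tcrossprod(A), -1), 1))
    se <- sqrt((1 - ana^2) / 1e5) + 1e-12
    expect_true(all(abs(emp - ana) <= 3 * se + 3e-3))
  }
})

test_that("task output dimensionality tracks min(P, D) for linear tasks but P for grid tasks", {
  x <- sample_latents(5000, 5, seed = 1)
  lin_pr <- task_output_dimensionality(make_linear_tasks(15, 5, seed = 2), x)
  grd_pr <- task_output_dimensionality(make_grid_tasks(15, 5, 3, seed = 3), x)
  expect_lt(lin_pr, 9)       # only slightly above D = 5
  expect_gt(grd_pr, 12)      # approaches P = 15
  expect_gt(grd_pr, lin_pr)

  one <- task_output_dimensionality(make_linear_tasks(1, 5, seed = 4), x)
  expect_equal(one, 1, tolerance = 1e-9)

  ctx <- make_contextual_tasks(3, 5, seed = 5)
  expect_error(task_output_dimensionality(ctx, x), "invalid-input")
})

test_that("mixture task sets concatenate labels and masks", {
  lin <- make_linear_tasks(3, 5, seed = 1)
  ctx <- make_contextual_tasks(2, 5, seed = 2)
  mix <- mixture_tasks(lin, ctx)
  expect_equal(mix$p, 5)
  x <- sample_latents(100, 5, seed = 3)
  tgt <- evaluate_tasks(mix, x)
  expect_equal(dim(unclass(tgt)), c(100, 5))
  expect_identical(unclass(tgt)[, 1:3],
                   unclass(evaluate_tasks(lin, x))[, 1:3])
  expect_identical(attr(tgt, "mask")[, 4:5],
                   attr(evaluate_tasks(ctx, x), "mask"))
  expect_error(mixture_tasks(lin, make_linear_tasks(2, 4, seed = 4)),
               "invalid-config")
})
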