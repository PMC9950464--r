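test_that("participation ratio matches closed-form spectra", {
  expect_equal(pr_from_eigenvalues(c(3, 1)), 1.6)
  expect_equal(pr_from_eigenvalues(c(2, 0, 0)), 1)
  expect_equal(pr_from_eigenvalues(rep(1, 7)), 7)
  expect_error(pr_from_eigenvalues(c(0, 0)), "invalid-input")

  # rank-one data
  one_dim <- outer(rnorm(100), c(1, 2, 3))
  expect_equal(participation_ratio(one_dim), 1, tolerance = 1e-9)

  # isotropic gaussian approaches d
  x <- sample_latents(5e4, 5, seed = 1)
  expect_equal(participation_ratio(x), 5, tolerance = 0.02)

  expect_error(participation_ratio(matrix(1, 10, 3)), "invalid-input")
  expect_error(participation_ratio(matrix(1, 1, 3)), "invalid-input")
})

test_that("sparseness matches closed-form cases", {
  expect_equal(sparseness(matrix(2, 100, 3))$per_unit, rep(0, 3))

  # a unit active on exactly 1 of n stimuli has S = 1 - 1/n
  act <- matrix(0, 1000, 2)
  act[1, 1] <- 5
  act[, 2] <- 1
  s <- sparseness(act)
  expect_equal(s$per_unit[1], 1 - 1 / 1000)
  expect_equal(s$per_unit[2], 0)

  silent <- cbind(act, 0)
  expect_equal(sparseness(silent)$n_silent, 1)
  expect_true(is.na(sparseness(silent)$per_unit[3]))
  expect_error(sparseness(matrix(c(-1, 1), 2, 1)), "invalid-input")
})

test_that("generalization metrics are near-perfect on the latents themselves", {
  id <- identity_representation(5)
  cg <- classifier_generalization(id, 5, n_splits = 3, seed = 1)
  rg <- regression_generalization(id, 5, n_splits = 3, seed = 2)
  expect_gt(cg$generalization_score, 0.97)
  expect_gt(rg$generalization_score, 0.99)
  expect_gt(cg$standard_score, 0.97)
})

test_that("both metrics are invariant to invertible linear mixing of the representation", {
  # a rotation combined with anisotropic axis scaling: every unit becomes a
  # linear mixture of all latent variables (well-conditioned, so the weakly
  # regularized decoders are unaffected)
  set.seed(3)
  B <- qr.Q(qr(matrix(rnorm(25), 5, 5))) %*% diag(seq(0.5, 2, length.out = 5))
  mixed <- new_representation_map(function(x) x %*% B, 5, "identity")
  cg <- classifier_generalization(mixed, 5, n_splits = 3, seed = 1)
  rg <- regression_generalization(mixed, 5, n_splits = 3, seed = 2)
  id_cg <- classifier_generalization(identity_representation(5), 5,
                                     n_splits = 3, seed = 1)
  id_rg <- regression_generalization(identity_representation(5), 5,
                                     n_splits = 3, seed = 2)
  expect_equal(cg$generalization_score, id_cg$generalization_score,
               tolerance = 0.02)
  expect_equal(rg$generalization_score, id_rg$generalization_score,
               tolerance = 0.02)
})

test_that("chance anchors: shuffled-label classification is 0.5 and mean prediction gives r2 = 0", {
  # shuffling the category labels of the training stimuli puts the linear
  # classifier at chance on held-out stimuli
  set.seed(4)
  x <- unclass(sample_latents(1000, 5, seed = 41))
  xt <- unclass(sample_latents(2000, 5, seed = 42))
  sp <- make_split(5, seed = 43)
  ytr <- factor(sample(drop(x %*% sp$target_normal) > 0))
  yte <- drop(xt %*% sp$target_normal) > 0
  accs <- replicate(20, {
    fit <- glmnet::glmnet(x, sample(ytr), family = "binomial", alpha = 0,
                          lambda = 1e-3)
    mean((drop(predict(fit, xt, type = "class")) == "TRUE") == yte)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.02)

  # always predicting the mean of the latents gives r2 = 0
  mu <- colMeans(x)
  mse <- colMeans((matrix(mu, 2000, 5, byrow = TRUE) - xt)^2)
  r2 <- mean(1 - mse / apply(xt, 2, var))
  expect_lt(abs(r2), 0.02)

  # degenerate constant encodings fall back to chance with a warning
  const <- new_representation_map(function(x) matrix(1, nrow(x), 4), 4,
                                  "identity")
  expect_warning(cgc <- classifier_generalization(const, 5, n_splits = 2,
                                                  seed = 6))
  expect_equal(cgc$generalization_score, 0.5)
  expect_warning(rgc <- regression_generalization(const, 5, n_splits = 2,
                                                  seed = 7))
  expect_equal(rgc$generalization_score, 0)
})

test_that("standard performance bounds generalization performance on average", {
  inp <- std_input()
  cg <- classifier_generalization(inp, 5, n_splits = 10, seed = 11)
  rg <- regression_generalization(inp, 5, n_splits = 10, seed = 12)
  se_c <- sd(cg$per_split_generalization) / sqrt(10)
  se_r <- sd(rg$per_split_generalization) / sqrt(10)
  expect_gt(cg$standard_score, cg$generalization_score - 3 * se_c)
  expect_gt(rg$standard_score, rg$generalization_score - 3 * se_r)
})

test_that("few-shot curves are ordered and beat chance even at k = 2 for clean representations", {
  id <- identity_representation(5)
  task <- make_linear_tasks(1, 5, seed = 21)
  expect_warning(
    fs <- few_shot_novel_task(id, id, 5, task,
                              sample_counts = c(1, 2, 8, 32, 128),
                              n_test = 1000, seed = 22),
    "skipped")
  expect_equal(fs$sample_counts, c(2, 8, 32, 128))
  expect_true(all(fs$upper_bound_scores >= fs$lower_bound_scores - 0.05))
  expect_gt(fs$model_scores[1], 0.55)        # k = 2, separated means
  expect_gt(tail(fs$model_scores, 1), 0.9)
})
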