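test_that("a small multi-tasking model trains, predicts, and exposes its layers", {
  fit <- small_model()
  expect_s3_class(fit, "multitask_model")
  expect_length(fit$history$loss, 30)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  expect_true(all(fit$history$task_accuracy > 0.9))

  x <- sample_latents(40, 3, seed = 1)
  out <- predict(fit, x)
  expect_equal(dim(out), c(40, 4))
  expect_true(all(out >= 0 & out <= 1))

  rep <- predict(fit, x, type = "representation")
  expect_equal(ncol(rep), 20)          # representation = last hidden layer
  expect_identical(rep, extract_representation(fit, x))

  # logits pass through the sigmoid to the response
  z <- predict(fit, x, type = "logit")
  expect_equal(1 / (1 + exp(-z)), out, tolerance = 1e-12)

  # layer 0 is the input encoding unchanged
  expect_identical(extract_representation(fit, x, layer = 0),
                   encode_latents(fit$input, x))
  expect_error(extract_representation(fit, x, layer = 5), "invalid-input")

  # representation_map wraps the same computation
  rm <- representation_map(fit)
  expect_equal(rm$m_units, 20)
  expect_identical(encode_latents(rm, x), rep)

  expect_output(print(fit), "Multi-tasking network")
  expect_output(print(summary(fit)), "task")
  expect_length(coef(fit)$W, 3)
})

test_that("training is reproducible under fixed seeds", {
  inp <- make_rf_input(3, m_units = 40L, rf_width = 0.5, seed = 4)
  run <- function() {
    multitask_model(inp, make_linear_tasks(3, 3, seed = 5),
                    spec = network_spec(c(30L, 10L), seed = 6),
                    config = train_config(n_examples = 500L, epochs = 5L,
                                          seed = 7))
  }
  f1 <- run(); f2 <- run()
  expect_equal(f1$history$loss, f2$history$loss, tolerance = 1e-12)
  expect_equal(f1$weights$W, f2$weights$W, tolerance = 1e-12)
})

test_that("masked targets contribute exactly zero gradient", {
  inp <- make_rf_input(3, m_units = 40L, rf_width = 0.5, seed = 4)
  tasks <- make_contextual_tasks(4, 3, seed = 5)
  spec <- network_spec(c(30L, 10L), seed = 6)
  cfg <- train_config(n_examples = 400L, epochs = 2L, seed = 7)

  # masked entries replaced by arbitrary finite values give bit-identical fits
  lat <- sample_latents(cfg$n_examples, 3, seed = cfg$seed)
  tgt <- evaluate_tasks(tasks, lat)
  mask <- attr(tgt, "mask") * 1
  y <- unclass(tgt)
  y01 <- (y + 1) / 2
  ya <- y01; ya[mask == 0] <- 0
  yb <- y01; yb[mask == 0] <- 0.731  # arbitrary finite junk
  x <- encode_latents(inp, lat)
  fa <- abstractrep:::cpp_mlp_train(x, ya, mask, c(30L, 10L), 1L, 1e-3, 2L, 100L, 6L,
                      0, 0, 2L, 0, -1L, NULL, 0L)
  fb <- abstractrep:::cpp_mlp_train(x, yb, mask, c(30L, 10L), 1L, 1e-3, 2L, 100L, 6L,
                      0, 0, 2L, 0, -1L, NULL, 0L)
  expect_identical(fa$weights$W, fb$weights$W)

  # with every target masked, training leaves the initial weights untouched
  zero_mask <- mask * 0
  fz <- abstractrep:::cpp_mlp_train(x, ya, zero_mask, c(30L, 10L), 1L, 1e-3, 2L, 100L, 6L,
                      0, 0, 2L, 0, -1L, NULL, 0L)
  expect_identical(fz$weights$W, fz$initial$W)
  expect_equal(fz$skipped_batches, 8)
})

test_that("single-task training collapses the representation dimensionality", {
  inp <- std_input()
  f1 <- trained_model("p1_collapse", function() {
    multitask_model(inp, make_linear_tasks(1, 5, seed = 31),
                    spec = network_spec(seed = 32),
                    config = train_config(epochs = 60L, seed = 33))
  })
  x <- sample_latents(3000, 5, seed = 34)
  pr1 <- participation_ratio(extract_representation(f1, x))
  expect_lt(pr1, 3)   # collapse toward one task dimension

  # output projection: a single-task model separates its categories bimodally
  proj <- task_output_projection(f1, x, 1)
  expect_lt(proj$overlap, 0.05)

  # an untrained model's output projection overlaps heavily
  f0 <- multitask_model(inp, make_linear_tasks(1, 5, seed = 31),
                        spec = network_spec(seed = 32),
                        config = train_config(epochs = 0L, seed = 33))
  proj0 <- task_output_projection(f0, x, 1)
  expect_gt(proj0$overlap, 0.2)
})

test_that("invalid configurations are rejected", {
  expect_error(network_spec(c(0L, 10L)))
  expect_error(train_config(batch_size = 0))
  fit <- small_model()
  x <- sample_latents(10, 3, seed = 1)
  expect_error(task_output_projection(fit, x, 9), "invalid-input")
})
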