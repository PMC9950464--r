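# Sweeps are exercised at miniature scale: tiny networks, few epochs, and a
# handful of metric splits. The full-scale behavior of the sweeps is covered
# by the acceptance tests.

tiny_spec <- function() network_spec(c(30L, 12L), seed = 1)
tiny_config <- function() train_config(n_examples = 600L, epochs = 8L, seed = 2)

test_that("task sweeps produce tidy tables with deterministic replicate seeding", {
  inp <- make_rf_input(3, m_units = 50L, rf_width = 0.5, seed = 3)
  tab <- run_task_sweep(inp, p_grid = c(0, 2), task_kind = "full", d = 3,
                        n_replicates = 2L, spec = tiny_spec(),
                        config = tiny_config(), metric_splits = 2L,
                        base_seed = 5)
  expect_equal(nrow(tab), 4)
  expect_setequal(names(tab),
                  c("task_kind", "p", "replicate", "classifier_standard",
                    "classifier_generalization", "regression_standard",
                    "regression_generalization", "pr", "sparseness"))
  expect_true(all(is.finite(tab$classifier_generalization)))

  # identical call reproduces the identical table (replicate seeds are
  # derived from the base seed, not from global RNG state)
  tab2 <- run_task_sweep(inp, p_grid = c(0, 2), task_kind = "full", d = 3,
                         n_replicates = 2L, spec = tiny_spec(),
                         config = tiny_config(), metric_splits = 2L,
                         base_seed = 5)
  expect_equal(tab, tab2)
})

test_that("sweeps are resumable from their on-disk cache", {
  inp <- make_rf_input(3, m_units = 50L, rf_width = 0.5, seed = 3)
  cache <- file.path(tempdir(), "sweepcache")
  unlink(cache, recursive = TRUE)
  tab <- run_task_sweep(inp, p_grid = 2, task_kind = "full", d = 3,
                        n_replicates = 1L, spec = tiny_spec(),
                        config = tiny_config(), metric_splits = 2L,
                        base_seed = 5, out_dir = cache)
  files <- list.files(cache)
  expect_length(files, 1)

  # poison the cache file; a re-run must read it rather than recompute
  poisoned <- utils::read.csv(file.path(cache, files))
  poisoned$classifier_generalization <- -99
  utils::write.csv(poisoned, file.path(cache, files), row.names = FALSE)
  tab2 <- run_task_sweep(inp, p_grid = 2, task_kind = "full", d = 3,
                         n_replicates = 1L, spec = tiny_spec(),
                         config = tiny_config(), metric_splits = 2L,
                         base_seed = 5, out_dir = cache)
  expect_equal(tab2$classifier_generalization, -99)
  unlink(cache, recursive = TRUE)
})

test_that("mixture sweeps cover all task-family variants of the cell builder", {
  inp <- make_rf_input(3, m_units = 50L, rf_width = 0.5, seed = 3)
  tab <- run_mixture_sweep(inp, n_linear = 2L, grid_counts = c(0L, 3L),
                           grid_n = 2L, d = 3, spec = tiny_spec(),
                           config = tiny_config(), metric_splits = 2L,
                           base_seed = 7)
  expect_equal(tab$n_grid, c(0, 3))
  expect_true(all(is.finite(tab$classifier_generalization)))

  # every named task family trains through the sweep machinery
  for (kind in c("unbalanced", "contextual", "partial", "grid", "gp")) {
    t1 <- run_task_sweep(inp, p_grid = 2, task_kind = kind, d = 3,
                         n_replicates = 1L, spec = tiny_spec(),
                         config = tiny_config(), grid_n = 2L,
                         metric_splits = 1L, base_seed = 9)
    expect_true(is.finite(t1$classifier_generalization), label = kind)
  }
})

test_that("the length-scale grid crosses inputs with tasks including anchors", {
  tab <- run_lengthscale_grid(input_scales = c("0.8"), task_scales = c("linear", "1"),
                              p = 2L, d = 3, spec = tiny_spec(),
                              config = tiny_config(), metric_splits = 1L,
                              base_seed = 11)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$task_scale, c("linear", "1"))
})

test_that("configurations round-trip through YAML with defaults filled in", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("latents:", "  d: 3", "tasks:", "  kind: grid", "  p: 4",
               "  grid_n: 2"), path)
  cfg <- read_config(path)
  expect_equal(cfg$latents$d, 3)
  expect_equal(cfg$tasks$kind, "grid")
  expect_equal(cfg$train$epochs, 200L)   # untouched default

  ts <- tasks_from_config(cfg)
  expect_s3_class(ts, "grid_tasks")
  expect_equal(ts$p, 4)

  cfg$input$kind <- "rf"
  cfg$input$m_units <- 30L
  inp <- input_from_config(cfg)
  expect_s3_class(inp, "representation_map")
  expect_equal(inp$m_units, 30L)

  # model save/load round trip
  f <- tempfile(fileext = ".rds")
  save_model(inp, f)
  inp2 <- load_model(f)
  x <- sample_latents(10, 3, seed = 1)
  expect_identical(encode_latents(inp2, x), encode_latents(inp, x))
})
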