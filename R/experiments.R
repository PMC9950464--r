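#' Abstraction versus number of tasks
#'
#' Trains one multi-tasking model per (task count, replicate) cell on the
#' given input and reports the abstraction metrics of its representation
#' layer as a tidy long table. Replicate `r` derives all its seeds from
#' `base_seed + r`, so cells are independent of execution order. If
#' `out_dir` is given, each finished cell is flushed to its own CSV and
#' re-running the sweep recomputes nothing already on disk.
#'
#' @param input A frozen `representation_map` shared by all cells.
#' @param p_grid Task counts to sweep over (0 means an untrained network).
#' @param task_kind `"full"`, `"unbalanced"`, `"contextual"`, `"partial"`,
#'   `"grid"`, or `"gp"`.
#' @param d Latent dimensionality.
#' @param n_replicates Replicates per task count.
#' @param spec,config Network and training settings applied to every cell
#'   (the cell's seeds override the seeds inside them).
#' @param sigma_offset,grid_n,length_scale Task-family parameters.
#' @param metric_splits Random splits per metric evaluation.
#' @param base_seed Base seed.
#' @param out_dir Optional cache/output directory.
#' @return A data.frame with one row per cell: `p`, `replicate`, the four
#'   metric scores, and the representation's `pr` and mean `sparseness`.
#' @export
run_task_sweep <- function(input, p_grid, task_kind = "full", d = 5,
                           n_replicates = 10L, spec = network_spec(),
                           config = train_config(), sigma_offset = 0.4,
                           grid_n = 3L, length_scale = 1,
                           metric_splits = 10L, base_seed = 1L,
                           out_dir = NULL) {
  cells <- expand.grid(p = p_grid, replicate = seq_len(n_replicates))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    p <- cells$p[i]; r <- cells$replicate[i]
    run_cached(out_dir, sprintf("sweep_%s_p%d_r%d", task_kind, p, r), {
      seed_r <- base_seed + r
      res <- tryCatch(
        sweep_cell(input, p, task_kind, d, spec, config, sigma_offset,
                   grid_n, length_scale, metric_splits, seed_r),
        error = function(e) {
          warning("cell p=", p, " r=", r, " failed: ", conditionMessage(e))
          data.frame(classifier_standard = NA_real_,
                     classifier_generalization = NA_real_,
                     regression_standard = NA_real_,
                     regression_generalization = NA_real_,
                     pr = NA_real_, sparseness = NA_real_)
        })
      cbind(data.frame(task_kind = task_kind, p = p, replicate = r), res)
    })
  })
  do.call(rbind, rows)
}

sweep_cell <- function(input, p, task_kind, d, spec, config, sigma_offset,
                       grid_n, length_scale, metric_splits, seed_r) {
  partial <- NULL
  if (p > 0) {
    tasks <- switch(task_kind,
      full = make_linear_tasks(p, d, seed = seed_r),
      unbalanced = make_unbalanced_tasks(p, d, sigma_offset, seed = seed_r),
      contextual = make_contextual_tasks(p, d, seed = seed_r),
      partial = make_linear_tasks(p, d, seed = seed_r),
      grid = make_grid_tasks(p, d, grid_n, seed = seed_r),
      gp = make_gp_tasks(p, d, length_scale, seed = seed_r),
      stop("invalid-config: unknown task kind ", task_kind))
    if (task_kind == "partial") partial <- list(mode = "one-per-sample")
    spec$seed <- seed_r + 11L
    config$seed <- seed_r + 23L
    model <- multitask_model(input, tasks, spec, config, partial = partial)
    rep <- representation_map(model)
  } else {
    # untrained baseline: a freshly initialised network on one placeholder task
    spec$seed <- seed_r + 11L
    config0 <- config
    config0$seed <- seed_r + 23L
    config0$epochs <- 0L
    model <- multitask_model(input, make_linear_tasks(1, d, seed = seed_r),
                             spec, config0)
    rep <- representation_map(model)
  }
  measure_representation(rep, d, metric_splits, seed_r)
}

measure_representation <- function(rep, d, metric_splits, seed_r) {
  cls <- classifier_generalization(rep, d, n_splits = metric_splits,
                                   seed = seed_r + 31L)
  reg <- regression_generalization(rep, d, n_splits = metric_splits,
                                   seed = seed_r + 37L)
  act <- encode_latents(rep, sample_latents(2000, d, seed = seed_r + 41L))
  sp <- if (all(act >= 0)) sparseness(act)$mean else NA_real_
  data.frame(classifier_standard = cls$standard_score,
             classifier_generalization = cls$generalization_score,
             regression_standard = reg$standard_score,
             regression_generalization = reg$generalization_score,
             pr = participation_ratio(act), sparseness = sp)
}

#' Linear tasks mixed with a growing number of grid tasks
#'
#' Trains models on `n_linear` latent-aligned linear tasks plus each count in
#' `grid_counts` of grid tasks, and reports the abstraction metrics — the
#' experiment showing that latent-aligned tasks protect abstraction even when
#' heavily outnumbered by misaligned grid tasks.
#'
#' @inheritParams run_task_sweep
#' @param n_linear Number of linear tasks in every cell.
#' @param grid_counts Numbers of added grid tasks (0 reduces to the plain
#'   linear run).
#' @export
run_mixture_sweep <- function(input, n_linear = 15L, grid_counts = c(0L, 45L),
                              grid_n = 3L, d = 5, n_replicates = 1L,
                              spec = network_spec(), config = train_config(),
                              metric_splits = 10L, base_seed = 1L,
                              out_dir = NULL) {
  cells <- expand.grid(k = grid_counts, replicate = seq_len(n_replicates))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    k <- cells$k[i]; r <- cells$replicate[i]
    run_cached(out_dir, sprintf("mixture_g%d_r%d", k, r), {
      seed_r <- base_seed + r
      lin <- make_linear_tasks(n_linear, d, seed = seed_r)
      tasks <- if (k > 0)
        mixture_tasks(lin, make_grid_tasks(k, d, grid_n, seed = seed_r + 5L))
      else lin
      spec$seed <- seed_r + 11L
      config$seed <- seed_r + 23L
      model <- multitask_model(input, tasks, spec, config)
      res <- measure_representation(representation_map(model), d,
                                    metric_splits, seed_r)
      cbind(data.frame(n_linear = n_linear, n_grid = k, replicate = r), res)
    })
  })
  do.call(rbind, rows)
}

#' Input length scale against task length scale
#'
#' Crosses Gaussian-process input encodings (rows) with Gaussian-process
#' tasks (columns), including the standard input and linear tasks as
#' anchors, and reports both generalization metrics per cell.
#'
#' @inheritParams run_task_sweep
#' @param input_scales Input length scales; the string `"standard"` inserts
#'   the PR-maximized standard input as an anchor row.
#' @param task_scales Task length scales; the string `"linear"` inserts
#'   random hyperplane tasks as an anchor column.
#' @param p Number of tasks per cell.
#' @param standard_input A trained standard input for the anchor row
#'   (trained on the fly when needed and not supplied).
#' @export
run_lengthscale_grid <- function(input_scales, task_scales, p = 15L, d = 5,
                                 n_replicates = 1L, spec = network_spec(),
                                 config = train_config(),
                                 standard_input = NULL, metric_splits = 10L,
                                 base_seed = 1L, out_dir = NULL) {
  cells <- expand.grid(input_scale = input_scales, task_scale = task_scales,
                       replicate = seq_len(n_replicates),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    isc <- cells$input_scale[i]; tsc <- cells$task_scale[i]
    r <- cells$replicate[i]
    run_cached(out_dir, sprintf("lsgrid_i%s_t%s_r%d", isc, tsc, r), {
      seed_r <- base_seed + r
      input <- if (identical(isc, "standard")) {
        if (is.null(standard_input))
          train_standard_input(d = d, seed = base_seed)
        else standard_input
      } else make_gp_input(d, length_scale = as.numeric(isc),
                           seed = seed_r + 3L)
      tasks <- if (identical(tsc, "linear"))
        make_linear_tasks(p, d, seed = seed_r)
      else make_gp_tasks(p, d, as.numeric(tsc), seed = seed_r)
      spec$seed <- seed_r + 11L
      config$seed <- seed_r + 23L
      model <- multitask_model(input, tasks, spec, config)
      res <- measure_representation(representation_map(model), d,
                                    metric_splits, seed_r)
      cbind(data.frame(input_scale = as.character(isc),
                       task_scale = as.character(tsc), replicate = r), res)
    })
  })
  do.call(rbind, rows)
}

# flush a finished cell to disk and skip it on re-runs
run_cached <- function(out_dir, name, expr) {
  if (is.null(out_dir)) return(force(expr))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- file.path(out_dir, paste0(name, ".csv"))
  if (file.exists(path))
    return(utils::read.csv(path, stringsAsFactors = FALSE))
  out <- force(expr)
  utils::write.csv(out, path, row.names = FALSE)
  out
}
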