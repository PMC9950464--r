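#' Default configuration
#'
#' The full default configuration tree used by [read_config()] and the
#' command-line entry points. Keys mirror the module structure: `latents`
#' (d, distribution, n_train, seed), `input` (kind, m_units, length_scale,
#' rf_width, pr_lambda, epochs, seed), `tasks` (kind, p, sigma_offset,
#' grid_n, length_scale, missing_mode, seed), `model` (layer widths,
#' output nonlinearity, activity penalties), and `train` (batch size,
#' examples, epochs, learning rate).
#'
#' @export
config_defaults <- function() {
  list(
    latents = list(d = 5L, distribution = "gaussian", n_train = 10000L,
                   seed = 1L),
    input = list(kind = "standard", m_units = 500L, length_scale = 1,
                 rf_width = 0.3, pr_lambda = 0.0015, epochs = 30L,
                 seed = 1L),
    tasks = list(kind = "full", p = 10L, sigma_offset = 0.4, grid_n = 3L,
                 length_scale = 1, missing_mode = "one-per-sample",
                 seed = 2L),
    model = list(layer_widths = c(250L, 150L, 100L, 50L),
                 output_nonlinearity = "sigmoid", l1_activity = 0,
                 l2_activity = 0, seed = 3L),
    train = list(batch_size = 100L, n_examples = 10000L, epochs = 200L,
                 learning_rate = 1e-3, weight_decay = 0, seed = 4L)
  )
}

#' Read a YAML configuration file
#'
#' Reads a structured config file and merges it (recursively) over
#' [config_defaults()]; keys not present in the file keep their defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @export
read_config <- function(path = NULL) {
  defaults <- config_defaults()
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  merge_config(defaults, user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Build an input model from a configuration
#'
#' @param cfg A configuration list (see [config_defaults()]).
#' @export
input_from_config <- function(cfg) {
  lt <- cfg$latents; inp <- cfg$input
  switch(inp$kind,
    standard = train_standard_input(d = lt$d, m_units = inp$m_units,
                                    n_train = lt$n_train,
                                    epochs = inp$epochs,
                                    pr_lambda = inp$pr_lambda,
                                    distribution = lt$distribution,
                                    seed = inp$seed),
    rf = make_rf_input(lt$d, inp$m_units, inp$rf_width,
                       distribution = lt$distribution, seed = inp$seed),
    gp = make_gp_input(lt$d, inp$m_units, inp$length_scale,
                       distribution = lt$distribution, seed = inp$seed),
    identity = identity_representation(lt$d),
    stop("invalid-config: unknown input kind ", inp$kind))
}

#' Build a task set from a configuration
#'
#' @param cfg A configuration list. The `tasks` block may also be a list of
#'   blocks, which are combined with [mixture_tasks()].
#' @export
tasks_from_config <- function(cfg) {
  d <- cfg$latents$d
  blocks <- cfg$tasks
  if (!is.null(blocks$kind)) blocks <- list(blocks)
  parts <- lapply(blocks, function(tk) {
    switch(tk$kind,
      full = make_linear_tasks(tk$p, d, seed = tk$seed),
      unbalanced = make_unbalanced_tasks(tk$p, d, tk$sigma_offset,
                                         seed = tk$seed),
      contextual = make_contextual_tasks(tk$p, d, seed = tk$seed),
      partial = make_linear_tasks(tk$p, d, seed = tk$seed),
      grid = make_grid_tasks(tk$p, d, tk$grid_n, seed = tk$seed),
      gp = make_gp_tasks(tk$p, d, tk$length_scale, seed = tk$seed),
      stop("invalid-config: unknown task kind ", tk$kind))
  })
  if (length(parts) == 1) parts[[1]] else mixture_tasks(parts)
}

#' Save or load a trained object
#'
#' Thin serialization wrappers for frozen input models and trained networks.
#'
#' @param object A `representation_map`, `multitask_model`, or
#'   `rl_multitask_model`.
#' @param path File path.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, c("representation_map", "multitask_model",
                               "rl_multitask_model")))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("representation_map", "multitask_model",
                       "rl_multitask_model")))
    stop("invalid-input: file does not contain a saved model")
  obj
}
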