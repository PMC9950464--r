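#' Network architecture specification
#'
#' Describes the feedforward multi-tasking network: rectified-linear hidden
#' layers, with the last hidden layer serving as the representation layer
#' whose geometry is analyzed, and a sigmoid (default) or linear output head
#' with one unit per task.
#'
#' @param layer_widths Hidden layer widths; the last entry is the
#'   representation width (defaults follow the standard architecture:
#'   250, 150, 100, 50).
#' @param output_nonlinearity `"sigmoid"` (cross-entropy loss) or `"linear"`
#'   (squared-error loss, the form used in the dimensionality theory).
#' @param l1_activity,l2_activity Activity-regularization penalties on the
#'   representation layer (default 0; "weak" presets are around 1e-3).
#' @param seed Seed for weight initialisation.
#' @export
network_spec <- function(layer_widths = c(250L, 150L, 100L, 50L),
                         output_nonlinearity = c("sigmoid", "linear"),
                         l1_activity = 0, l2_activity = 0, seed = 1L) {
  stopifnot(all(layer_widths >= 1))
  structure(list(layer_widths = as.integer(layer_widths),
                 representation_width = as.integer(utils::tail(layer_widths, 1)),
                 output_nonlinearity = match.arg(output_nonlinearity),
                 l1_activity = l1_activity, l2_activity = l2_activity,
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' Training configuration
#'
#' @param batch_size Minibatch size (default 100).
#' @param n_examples Number of training examples, drawn once and iterated
#'   over for `epochs` passes (default 10000).
#' @param epochs Number of passes over the training set (default 200).
#' @param learning_rate Adam learning rate.
#' @param weight_decay Decoupled (AdamW-style) weight decay on connection
#'   weights, default 0. Exposed because mild decay counteracts the
#'   late-training sharpening of task boundaries (see the package vignette);
#'   it is off by default to keep the standard training conditions minimal.
#' @param dropout Dropout probability on hidden activations during training
#'   (default 0).
#' @param seed Seed for the latent draws and batch shuffling.
#' @export
train_config <- function(batch_size = 100L, n_examples = 10000L,
                         epochs = 200L, learning_rate = 1e-3,
                         weight_decay = 0, dropout = 0, seed = 1L) {
  stopifnot(batch_size >= 1, n_examples >= 1, epochs >= 0,
            weight_decay >= 0, dropout >= 0, dropout < 1)
  structure(list(batch_size = as.integer(batch_size),
                 n_examples = as.integer(n_examples),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, optimizer = "adam",
                 weight_decay = weight_decay, dropout = dropout,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Fit a multi-tasking network
#'
#' Trains a feedforward network to perform every task in `tasks` on latent
#' variables it only observes through the frozen `input` encoding. Fresh
#' latent samples are drawn once (`config$n_examples`), encoded, labeled by
#' the task set, and iterated over for `config$epochs` passes with a masked
#' loss: absent targets (contextual tasks outside their context, or targets
#' removed by `partial` information) contribute exactly zero gradient.
#'
#' The object returned is the package's central model class; use
#' [extract_representation()] or [representation_map()] to access layer
#' activations, and [classifier_generalization()] /
#' [regression_generalization()] on the extracted representation to quantify
#' abstraction.
#'
#' @param input A frozen `representation_map` providing the network's input.
#' @param tasks A `task_set` on the same latent space.
#' @param spec A [network_spec()].
#' @param config A [train_config()].
#' @param partial Optional partial-information rule: a list with `mode`
#'   (`"one-per-sample"` or `"fraction"`) and, for fraction mode,
#'   `missing_fraction`.
#' @param distribution Latent distribution.
#' @param d Latent dimensionality (defaults to the task set's).
#' @return An object of class `multitask_model` with the frozen weights,
#'   the per-epoch loss history, final per-task training accuracies, and the
#'   full provenance (input, tasks, spec, config).
#' @examples
#' \dontrun{
#' inp <- train_standard_input(d = 5, seed = 1)
#' ts <- make_linear_tasks(10, 5, seed = 2)
#' fit <- multitask_model(inp, ts)
#' classifier_generalization(representation_map(fit), d = 5)
#' }
#' @export
multitask_model <- function(input, tasks, spec = network_spec(),
                            config = train_config(), partial = NULL,
                            distribution = c("gaussian", "uniform"),
                            d = tasks$d) {
  stopifnot(inherits(input, "representation_map"),
            inherits(tasks, "task_set"), inherits(spec, "network_spec"),
            inherits(config, "train_config"))
  distribution <- match.arg(distribution)
  latents <- sample_latents(config$n_examples, d, distribution,
                            seed = config$seed)
  targets <- evaluate_tasks(tasks, latents)
  if (!is.null(partial))
    targets <- apply_partial_information(
      targets, mode = partial$mode,
      missing_fraction = partial$missing_fraction %||% 0.9,
      seed = config$seed + 101L)
  x <- encode_latents(input, latents)
  mask <- attr(targets, "mask") * 1
  y <- unclass(targets)
  y[is.na(y)] <- -1
  y01 <- (y + 1) / 2                      # {0, 1} for the sigmoid head
  out_act <- if (spec$output_nonlinearity == "sigmoid") 1L else 0L
  if (out_act == 0L) y01 <- y             # squared error fits +/-1 directly
  n_hidden <- length(spec$layer_widths)
  fit <- cpp_mlp_train(x, y01, mask, spec$layer_widths, out_act,
                       config$learning_rate, config$epochs,
                       config$batch_size, spec$seed,
                       spec$l1_activity, spec$l2_activity, n_hidden,
                       0, -1L, NULL, 0L, 0L, config$dropout %||% 0,
                       config$weight_decay %||% 0)
  structure(list(weights = fit$weights, initial_weights = fit$initial,
                 spec = spec, config = config, input = input, tasks = tasks,
                 d = d, distribution = distribution,
                 history = list(loss = fit$loss,
                                task_accuracy = fit$task_accuracy,
                                skipped_batches = fit$skipped_batches),
                 out_act = out_act),
            class = "multitask_model")
}

#' @export
print.multitask_model <- function(x, ...) {
  cat("Multi-tasking network\n")
  cat("  tasks:", x$tasks$p, paste0("(", class(x$tasks)[1], ")"),
      " latent dims:", x$d, "\n")
  cat("  architecture:", x$input$m_units, "->",
      paste(x$spec$layer_widths, collapse = " -> "), "->", x$tasks$p,
      paste0("(", x$spec$output_nonlinearity, ")"), "\n")
  cat(sprintf("  trained %d epochs; final loss %.4f; mean task accuracy %.3f\n",
              x$config$epochs, utils::tail(x$history$loss, 1),
              mean(x$history$task_accuracy, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.multitask_model <- function(object, ...) {
  out <- list(p = object$tasks$p, d = object$d,
              layer_widths = object$spec$layer_widths,
              final_loss = utils::tail(object$history$loss, 1),
              task_accuracy = object$history$task_accuracy)
  class(out) <- "summary.multitask_model"
  out
}

#' @export
print.summary.multitask_model <- function(x, ...) {
  cat("Multi-tasking network:", x$p, "tasks on", x$d, "latent dims\n")
  cat("final training loss:", signif(x$final_loss, 4), "\n")
  cat("per-task training accuracy:\n")
  print(round(x$task_accuracy, 3))
  invisible(x)
}

#' @export
coef.multitask_model <- function(object, ...) {
  W <- object$weights$W
  b <- object$weights$b
  names(W) <- names(b) <- paste0("layer", seq_along(W))
  list(W = W, b = b)
}

#' Predict task outputs or layer activations
#'
#' @param object A fitted `multitask_model`.
#' @param latents Latent samples to evaluate on.
#' @param type `"response"` (task output after the output nonlinearity),
#'   `"logit"` (pre-nonlinearity output), or `"representation"` (the
#'   representation-layer activations).
#' @param ... Unused.
#' @export
predict.multitask_model <- function(object, latents,
                                    type = c("response", "logit",
                                             "representation"), ...) {
  type <- match.arg(type)
  x <- encode_latents(object$input, latents)
  acts <- cpp_mlp_forward(object$weights, x, object$out_act)
  n_hidden <- length(object$spec$layer_widths)
  switch(type,
    response = acts[[length(acts)]],
    representation = acts[[n_hidden + 1L]],
    logit = {
      r <- acts[[n_hidden + 1L]]
      L <- length(object$weights$W)
      sweep(r %*% object$weights$W[[L]], 2, object$weights$b[[L]], "+")
    })
}

#' @export
plot.multitask_model <- function(x, ...) {
  graphics::plot(seq_along(x$history$loss), x$history$loss, type = "l",
                 xlab = "epoch", ylab = "training loss",
                 main = "multi-tasking model training", ...)
  invisible(x)
}

#' Activations of a network layer
#'
#' Evaluates the activations of a trained model at any layer for the given
#' latents. Layer 0 is the (frozen) input encoding itself; hidden layers are
#' numbered from 1; the default is the representation layer (the last hidden
#' layer, the one preceding the task outputs).
#'
#' @param model A fitted `multitask_model` or `rl_multitask_model`.
#' @param latents Latent samples.
#' @param layer Layer index, or `"representation"`.
#' @return An `n x width` activation matrix.
#' @export
extract_representation <- function(model, latents, layer = "representation") {
  UseMethod("extract_representation")
}

#' @export
extract_representation.multitask_model <- function(model, latents,
                                                   layer = "representation") {
  n_hidden <- length(model$spec$layer_widths)
  layer <- resolve_layer(layer, n_hidden)
  x <- encode_latents(model$input, latents)
  if (layer == 0) return(x)
  cpp_mlp_forward(model$weights, x, model$out_act)[[layer + 1L]]
}

resolve_layer <- function(layer, n_hidden) {
  if (identical(layer, "representation")) return(n_hidden)
  layer <- as.integer(layer)
  if (is.na(layer) || layer < 0 || layer > n_hidden)
    stop("invalid-input: layer index out of range")
  layer
}

#' A trained layer as a frozen representation map
#'
#' Wraps a layer of a trained model (input encoding plus network forward
#' pass) as a `representation_map`, so it can be fed to the abstraction
#' metrics exactly like an input model.
#'
#' @param model A fitted model.
#' @param layer Layer index or `"representation"` (default).
#' @export
representation_map <- function(model, layer = "representation") {
  UseMethod("representation_map")
}

#' @export
representation_map.multitask_model <- function(model,
                                               layer = "representation") {
  n_hidden <- length(model$spec$layer_widths)
  lay <- resolve_layer(layer, n_hidden)
  widths <- c(model$input$m_units, model$spec$layer_widths)
  new_representation_map(
    function(x) extract_representation(model, x, layer = lay),
    m_units = widths[lay + 1L], kind = "network-layer",
    meta = list(layer = lay))
}

#' Distribution of a task's output activation by category
#'
#' Returns the pre-sigmoid output activation of one task, split by the true
#' task category — suitable for histogramming. Well-trained small-`P` models
#' show strongly separated bimodal distributions; larger task counts yield
#' more continuous, overlapping outputs.
#'
#' @param model A fitted `multitask_model`.
#' @param latents Latent samples.
#' @param task_index Which task's output to project (1-based).
#' @return A list with `positive` and `negative` activation vectors and an
#'   `overlap` statistic (fraction of each category on the wrong side of the
#'   midpoint between category means).
#' @export
task_output_projection <- function(model, latents, task_index = 1L) {
  if (task_index < 1 || task_index > model$tasks$p)
    stop("invalid-input: task_index out of range")
  z <- predict(model, latents, type = "logit")[, task_index]
  truth <- unclass(evaluate_tasks(model$tasks, latents))[, task_index]
  pos <- z[!is.na(truth) & truth > 0]
  neg <- z[!is.na(truth) & truth < 0]
  mid <- (mean(pos) + mean(neg)) / 2
  overlap <- (mean(pos < mid) + mean(neg > mid)) / 2
  list(positive = pos, negative = neg, overlap = overlap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
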