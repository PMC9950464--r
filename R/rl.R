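#' Configuration for the reinforcement-learning multi-tasking model
#'
#' The RL variant trains the same multi-tasking architecture with a modified
#' deep deterministic policy gradient (DDPG) scheme: a single actor maps the
#' input encoding to a `P`-vector of bounded actions (one categorization per
#' task), and one small critic per task learns to predict the thresholded
#' reward from the stimulus and that task's action. Episodes are single-step,
#' so the critic's bootstrap term vanishes and critics regress the observed
#' reward directly; replay buffer, exploration noise, and the deterministic
#' policy gradient through the critics follow the standard recipe.
#'
#' The default `epochs = 2000` (each epoch is `batches_per_epoch` collected
#' and replayed batches) is a deliberately scaled-down training regime that
#' exhibits the qualitative learning phenomena; full-scale runs use far more.
#'
#' @param actor_widths Actor hidden widths; the last is the representation
#'   width.
#' @param critic_stimulus_widths,critic_action_widths,critic_shared_widths
#'   Critic trunk widths: the stimulus trunk and the (linear) action trunk
#'   are concatenated into the shared trunk, which ends in a scalar reward
#'   prediction.
#' @param batch_size Transitions collected and replayed per update.
#' @param epochs Training epochs.
#' @param batches_per_epoch Updates per epoch.
#' @param initial_batches Random-action batches used to prefill the replay
#'   buffer.
#' @param critic_warmup Update steps during which only the critics learn
#'   (the actor is frozen); applying the policy gradient before the critics
#'   track the reward landscape pins the bounded actions at wrong extremes.
#' @param buffer_capacity Replay buffer size.
#' @param reward_threshold Action magnitude required for reward/punishment.
#' @param noise_sd Exploration noise standard deviation.
#' @param lr_actor,lr_critic Adam learning rates.
#' @param n_examples Size of the stimulus pool sampled from the latent
#'   distribution.
#' @param seed Integer seed.
#' @export
rl_config <- function(actor_widths = c(250L, 150L, 50L),
                      critic_stimulus_widths = c(10L, 5L),
                      critic_action_widths = 1L,
                      critic_shared_widths = 5L,
                      batch_size = 200L, epochs = 2000L,
                      batches_per_epoch = 1L,
                      initial_batches = 20000L, critic_warmup = 200L,
                      buffer_capacity = 100000L,
                      reward_threshold = 0.33, noise_sd = 0.2,
                      lr_actor = 1e-4, lr_critic = 1e-3,
                      n_examples = 10000L, seed = 1L) {
  stopifnot(reward_threshold > 0)
  structure(list(actor_widths = as.integer(actor_widths),
                 representation_width = as.integer(utils::tail(actor_widths, 1)),
                 critic_stimulus_widths = as.integer(critic_stimulus_widths),
                 critic_action_widths = as.integer(critic_action_widths),
                 critic_shared_widths = as.integer(critic_shared_widths),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 initial_batches = as.integer(initial_batches),
                 critic_warmup = as.integer(critic_warmup),
                 buffer_capacity = as.integer(buffer_capacity),
                 reward_threshold = reward_threshold, noise_sd = noise_sd,
                 lr_actor = lr_actor, lr_critic = lr_critic,
                 n_examples = as.integer(n_examples),
                 seed = as.integer(seed)),
            class = "rl_config")
}

#' Thresholded categorization reward
#'
#' An action earns +1 when its sign matches the true category and its
#' magnitude exceeds the threshold, -1 when its magnitude exceeds the
#' threshold with the wrong sign, and 0 (no outcome) below threshold.
#'
#' @param action Numeric vector (or matrix) of actions in `[-1, 1]`.
#' @param true_labels Matching vector/matrix of `+1/-1` category labels.
#' @param threshold Positive reward/punishment threshold.
#' @return Rewards in `{-1, 0, +1}` with the shape of `action`.
#' @export
reward_function <- function(action, true_labels, threshold = 0.33) {
  if (threshold <= 0) stop("invalid-config: threshold must be positive")
  out <- ifelse(abs(action) > threshold,
                ifelse(sign(action) == sign(true_labels), 1, -1), 0)
  out
}

#' Train the multi-tasking model with reinforcement learning
#'
#' Runs the modified DDPG scheme (see [rl_config()]) on full linear tasks:
#' the actor categorizes each stimulus on all `P` tasks at once with bounded
#' actions, receives a thresholded reward per task, and learns only through
#' the per-task critics' predicted reward.
#'
#' @param input A frozen `representation_map`.
#' @param taskset A full (non-contextual) `linear_tasks` set.
#' @param cfg An [rl_config()].
#' @param distribution Latent distribution.
#' @return An object of class `rl_multitask_model` with the frozen actor and
#'   critic weights and the per-epoch, per-task average-reward history.
#' @export
train_rl <- function(input, taskset, cfg = rl_config(),
                     distribution = c("gaussian", "uniform")) {
  stopifnot(inherits(input, "representation_map"),
            inherits(taskset, "linear_tasks"), inherits(cfg, "rl_config"))
  if (taskset$kind == "contextual")
    stop("invalid-config: RL training requires full (non-contextual) tasks")
  distribution <- match.arg(distribution)
  latents <- sample_latents(cfg$n_examples, taskset$d, distribution,
                            seed = cfg$seed)
  S <- encode_latents(input, latents)
  labels <- unclass(evaluate_tasks(taskset, latents))
  fit <- cpp_train_ddpg(S, labels, cfg$actor_widths,
                        cfg$critic_stimulus_widths, cfg$critic_action_widths,
                        cfg$critic_shared_widths,
                        cfg$epochs * cfg$batches_per_epoch, cfg$batch_size,
                        cfg$buffer_capacity, cfg$initial_batches,
                        cfg$reward_threshold, cfg$noise_sd, cfg$lr_actor,
                        cfg$lr_critic, cfg$seed, cfg$critic_warmup)
  hist <- fit$reward_history
  if (cfg$batches_per_epoch > 1) {
    grp <- rep(seq_len(cfg$epochs), each = cfg$batches_per_epoch)
    hist <- apply(hist, 2, function(col) tapply(col, grp, mean))
  }
  structure(list(actor = fit$actor, critics = fit$critics,
                 history = hist, cfg = cfg, input = input, tasks = taskset,
                 d = taskset$d, distribution = distribution),
            class = "rl_multitask_model")
}

#' @export
print.rl_multitask_model <- function(x, ...) {
  fl <- utils::tail(fraction_learned(x$history), 1)
  cat("RL multi-tasking network (DDPG):", x$tasks$p, "tasks\n")
  cat(sprintf("  %d epochs; final fraction of tasks learned (avg reward > 0.8): %.2f\n",
              nrow(x$history), fl))
  invisible(x)
}

#' @export
predict.rl_multitask_model <- function(object, latents,
                                       type = c("response",
                                                "representation"), ...) {
  type <- match.arg(type)
  x <- encode_latents(object$input, latents)
  acts <- cpp_mlp_forward(object$actor, x, 2L)
  n_hidden <- length(object$cfg$actor_widths)
  if (type == "response") acts[[length(acts)]] else acts[[n_hidden + 1L]]
}

#' @export
extract_representation.rl_multitask_model <- function(model, latents,
                                                      layer = "representation") {
  n_hidden <- length(model$cfg$actor_widths)
  layer <- resolve_layer(layer, n_hidden)
  x <- encode_latents(model$input, latents)
  if (layer == 0) return(x)
  cpp_mlp_forward(model$actor, x, 2L)[[layer + 1L]]
}

#' @export
representation_map.rl_multitask_model <- function(model,
                                                  layer = "representation") {
  n_hidden <- length(model$cfg$actor_widths)
  lay <- resolve_layer(layer, n_hidden)
  widths <- c(model$input$m_units, model$cfg$actor_widths)
  new_representation_map(
    function(x) extract_representation(model, x, layer = lay),
    m_units = widths[lay + 1L], kind = "network-layer",
    meta = list(layer = lay, rl = TRUE))
}

#' Fraction of tasks learned over training
#'
#' For each epoch, the fraction of tasks whose trailing-window average
#' reward exceeds the criterion.
#'
#' @param history An `epochs x P` reward-history matrix (or an
#'   `rl_multitask_model`).
#' @param criterion Average-reward criterion for "learned" (default 0.8).
#' @param window Trailing window length in epochs.
#' @return Numeric vector of per-epoch learned fractions.
#' @export
fraction_learned <- function(history, criterion = 0.8, window = 10L) {
  if (inherits(history, "rl_multitask_model")) history <- history$history
  history <- as.matrix(history)
  n <- nrow(history)
  vapply(seq_len(n), function(ep) {
    lo <- max(1L, ep - window + 1L)
    mean(colMeans(history[lo:ep, , drop = FALSE]) > criterion)
  }, numeric(1))
}

#' Predicted reward from a trained critic
#'
#' @param model A trained `rl_multitask_model`.
#' @param task_index Which task's critic to query.
#' @param latents Latent samples.
#' @param actions Actions for that task (vector, one per sample).
#' @export
critic_predict <- function(model, task_index, latents, actions) {
  stopifnot(task_index >= 1, task_index <= model$tasks$p)
  S <- encode_latents(model$input, latents)
  drop(cpp_critic_predict(model$critics[[task_index]], S,
                          as.numeric(actions)))
}
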