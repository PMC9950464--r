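#' Representation maps
#'
#' A representation map is a frozen, deterministic mapping from `n x d` latent
#' matrices to `n x m_units` activation matrices: either one of the input
#' models (the PR-maximized "standard input", Gaussian receptive fields, or
#' frozen random Gaussian-process projections) or a layer of a trained
#' network. Construct them with [train_standard_input()], [make_rf_input()],
#' [make_gp_input()], [identity_representation()], or
#' [representation_map.multitask_model()] via [extract_representation()].
#'
#' @param encode Function mapping a latent matrix to activations.
#' @param m_units Output width.
#' @param kind Tag: `"standard"`, `"rf"`, `"gp"`, `"identity"`, or
#'   `"network-layer"`.
#' @param meta Provenance record (training config, seed, ...).
#' @return An object of class `representation_map`.
#' @export
new_representation_map <- function(encode, m_units, kind, meta = list()) {
  structure(list(encode = encode, m_units = m_units, kind = kind,
                 meta = meta),
            class = "representation_map")
}

#' @export
print.representation_map <- function(x, ...) {
  cat("<representation_map> kind:", x$kind, " units:", x$m_units, "\n")
  invisible(x)
}

#' Encode latents through a representation map
#'
#' @param rep A `representation_map`.
#' @param latents An `n x d` latent matrix.
#' @return An `n x m_units` activation matrix.
#' @export
encode_latents <- function(rep, latents) {
  stopifnot(inherits(rep, "representation_map"))
  rep$encode(as.matrix(unclass(latents)))
}

#' The identity representation of the latent variables
#'
#' Returns the latents unchanged; the fully abstract reference against which
#' the input models and trained networks are compared.
#'
#' @param d Latent dimensionality.
#' @export
identity_representation <- function(d) {
  new_representation_map(function(x) x, m_units = d, kind = "identity")
}

#' Train the participation-ratio-maximized standard input
#'
#' The standard input is a symmetric autoencoder (encoder layers of 100 and
#' 200 rectified-linear units into a rectified representation layer of
#' `m_units` units, mirrored decoder) trained on latent samples with two
#' objectives: reconstruct the latents, and maximize the participation ratio
#' of its representation-layer activity. The result is a frozen,
#' high-dimensional, sparse, non-abstract encoding of the latents: with the
#' defaults, roughly 4-5% of units respond to any one stimulus, per-unit
#' sparseness is about 0.96, and the population participation ratio is near
#' 190.
#'
#' The combined loss is `MSE(x, xhat) - pr_lambda * PR(batch activations)`,
#' with the PR bonus applied to the representation layer. `pr_lambda` and the
#' epoch count are the two knobs that set where on the
#' dimensionality/sparseness continuum the input lands; the defaults were
#' chosen to land in the regime described above and should rarely need
#' changing.
#'
#' @param d Latent dimensionality.
#' @param m_units Representation width (default 500).
#' @param hidden Encoder hidden widths, mirrored in the decoder.
#' @param n_train Number of training latent samples.
#' @param epochs,batch_size,learning_rate Optimisation settings (Adam).
#' @param pr_lambda Weight of the participation-ratio bonus.
#' @param l1_activity Optional L1 penalty on representation activations.
#' @param recon_ceiling Maximum admissible held-out reconstruction MSE
#'   (averaged over dimensions); training past this ceiling signals failure.
#' @param distribution Latent distribution.
#' @param seed Integer seed (latent draws and weight initialisation).
#' @return A `representation_map` of kind `"standard"`. Its `meta` carries
#'   the trained weights, the per-epoch loss history, the held-out
#'   reconstruction MSE and per-dimension r-squared, and a `reconstruct`
#'   function exposing the autoencoder's own decoder.
#' @export
train_standard_input <- function(d = 5, m_units = 500L, hidden = c(100L, 200L),
                                 n_train = 10000L, epochs = 30L,
                                 batch_size = 100L, learning_rate = 1e-3,
                                 pr_lambda = 0.0015, l1_activity = 0,
                                 recon_ceiling = 0.05,
                                 distribution = c("gaussian", "uniform"),
                                 seed = 1L) {
  if (d < 1) stop("invalid-config: d must be >= 1")
  distribution <- match.arg(distribution)
  x <- unclass(sample_latents(n_train, d, distribution, seed = seed))
  widths <- c(hidden, m_units, rev(hidden))
  rep_layer <- length(hidden) + 1L
  fit <- cpp_mlp_train(x, x, matrix(1, nrow(x), d), widths, 0L,
                       learning_rate, as.integer(epochs),
                       as.integer(batch_size), as.integer(seed),
                       l1_activity, 0, rep_layer, pr_lambda, rep_layer, NULL)
  heldout <- unclass(sample_latents(2000L, d, distribution, seed = seed + 7L))
  acts <- cpp_mlp_forward(fit$weights, heldout, 0L)
  recon <- acts[[length(acts)]]
  mse <- mean((recon - heldout)^2)
  r2 <- 1 - colMeans((recon - heldout)^2) / apply(heldout, 2, stats::var)
  if (mse > recon_ceiling)
    stop("training-failure: held-out reconstruction MSE ", signif(mse, 3),
         " exceeds ceiling ", recon_ceiling,
         " (pr_lambda too high or too few epochs)")
  weights <- fit$weights
  encode <- function(x) {
    cpp_mlp_forward(weights, as.matrix(x), 0L)[[rep_layer + 1L]]
  }
  reconstruct <- function(x) {
    a <- cpp_mlp_forward(weights, as.matrix(x), 0L)
    a[[length(a)]]
  }
  new_representation_map(
    encode, m_units = m_units, kind = "standard",
    meta = list(d = d, seed = seed, distribution = distribution,
                weights = weights, rep_layer = rep_layer,
                loss_history = fit$loss, pr_history = fit$pr,
                heldout_mse = mse, heldout_r2 = r2,
                reconstruct = reconstruct,
                config = list(hidden = hidden, n_train = n_train,
                              epochs = epochs, batch_size = batch_size,
                              learning_rate = learning_rate,
                              pr_lambda = pr_lambda,
                              l1_activity = l1_activity)))
}

#' Gaussian receptive-field input
#'
#' Encodes latents with `m_units` randomly positioned Gaussian receptive
#' fields: unit `i` responds `exp(-||x - c_i||^2 / (2 rf_width^2))`. Centers
#' are drawn uniformly over the central bulk of the latent distribution (the
#' `[-2, 2]` hypercube for Gaussian latents, the support for uniform ones).
#' Narrow fields give a sparse, high-dimensional, highly local code.
#'
#' @param d Latent dimensionality.
#' @param m_units Number of receptive fields.
#' @param rf_width Receptive-field width, in latent-space standard deviations.
#' @param distribution Latent distribution (sets the center range).
#' @param seed Integer seed.
#' @export
make_rf_input <- function(d, m_units = 500L, rf_width = 0.3,
                          distribution = c("gaussian", "uniform"),
                          seed = 1L) {
  if (m_units < 1 || rf_width <= 0)
    stop("invalid-config: m_units must be >= 1 and rf_width > 0")
  distribution <- match.arg(distribution)
  lim <- if (distribution == "gaussian") 2 else 1
  centers <- with_seed(seed,
                       matrix(stats::runif(m_units * d, -lim, lim), m_units, d))
  encode <- function(x) {
    x <- as.matrix(x)
    d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
      2 * tcrossprod(x, centers)
    exp(-pmax(d2, 0) / (2 * rf_width^2))
  }
  new_representation_map(encode, m_units = m_units, kind = "rf",
                         meta = list(d = d, centers = centers,
                                     rf_width = rf_width, seed = seed))
}

#' Frozen random Gaussian-process input
#'
#' Encodes latents with `m_units` independent frozen random Gaussian-process
#' functions sharing an RBF kernel of the given length scale (see
#' [make_gp_functions()]). Short length scales produce high-dimensional,
#' tangled encodings; long ones produce smooth, nearly linear (and hence more
#' abstract) encodings.
#'
#' @param d Latent dimensionality.
#' @param m_units Number of GP output dimensions (default 500).
#' @param length_scale RBF kernel length scale.
#' @param n_anchors Support points per function.
#' @param distribution Latent distribution.
#' @param seed Integer seed.
#' @export
make_gp_input <- function(d, m_units = 500L, length_scale = 1, n_anchors = 500L,
                          distribution = c("gaussian", "uniform"),
                          seed = 1L) {
  distribution <- match.arg(distribution)
  gp <- make_gp_functions(m_units, d, length_scale, n_anchors, distribution,
                          seed)
  encode <- function(x) evaluate_gp(gp, x)
  new_representation_map(encode, m_units = m_units, kind = "gp",
                         meta = list(d = d, length_scale = length_scale,
                                     gp = gp, seed = seed))
}

#' Summary statistics and abstraction metrics for an input encoding
#'
#' Computes the participation ratio, mean per-unit sparseness (rectified
#' encodings only), and active-unit fraction of a representation over fresh
#' latent samples, together with the classifier and regression generalization
#' metrics applied directly to the raw encoding.
#'
#' @param rep A `representation_map`.
#' @param d Latent dimensionality.
#' @param n_samples Sample size for the population statistics.
#' @param distribution Latent distribution.
#' @param n_splits Random splits to average the metrics over.
#' @param seed Integer seed.
#' @return A list with `pr`, `mean_sparseness`, `active_fraction`,
#'   `classifier` and `regression` ([generalization results][classifier_generalization]).
#' @export
input_diagnostics <- function(rep, d, n_samples = 5000L,
                              distribution = c("gaussian", "uniform"),
                              n_splits = 10L, seed = 1L) {
  distribution <- match.arg(distribution)
  x <- sample_latents(n_samples, d, distribution, seed = seed)
  act <- encode_latents(rep, x)
  sp <- NA_real_
  if (all(act >= 0)) sp <- sparseness(act)$mean
  else warning("encoding has negative activations; sparseness not defined")
  list(pr = participation_ratio(act),
       mean_sparseness = sp,
       active_fraction = mean(act > 0),
       classifier = classifier_generalization(rep, d,
                                              distribution = distribution,
                                              n_splits = n_splits,
                                              seed = seed + 1L),
       regression = regression_generalization(rep, d,
                                              distribution = distribution,
                                              n_splits = n_splits,
                                              seed = seed + 2L))
}
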