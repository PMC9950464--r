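# abstractrep

Simulation framework for studying how **abstract representations** of
continuous latent variables emerge in feedforward neural networks trained to
perform many binary classification tasks — and for *measuring* abstractness
in any population code with cross-condition generalization metrics.

A representation of `D` latent variables is abstract (the machine-learning
literature says *disentangled*) when a linear decoder for one variable,
trained in one region of latent space, keeps working in regions it never saw.
This package builds the full synthetic pipeline around that idea:

- **Latents** — `sample_latents()` draws `D = 5` (by default) independent
  Gaussian or centered-uniform latent dimensions; `make_split()` /
  `sample_in_half()` define the orthogonal pair of balanced half-space
  divisions used by the metrics.
- **Non-abstract input models** — `train_standard_input()` (an autoencoder
  trained to reconstruct the latents *and* maximize the participation ratio
  of its 500-unit rectified code: sparse, ~190-dimensional, tangled),
  `make_rf_input()` (Gaussian receptive fields), `make_gp_input()` (frozen
  random Gaussian-process projections).
- **Task families** — `make_linear_tasks()` (`sign(Ax)` for random
  hyperplanes), `make_unbalanced_tasks()` (`sign(Ax + b)`),
  `make_contextual_tasks()` (labels only where `Cx > 0`),
  `apply_partial_information()` (one informative task per example),
  `make_grid_tasks()` (random categories on equal-probability chambers),
  `make_gp_tasks()` (signs of random GP functions), `mixture_tasks()`.
- **The multi-tasking model** — `multitask_model()` trains the feedforward
  network (250/150/100/50 rectified hidden layers, sigmoid output per task,
  masked cross-entropy, Adam) on any (input model, task set) pair; absent
  targets contribute exactly zero gradient. Standard S3 methods
  (`print`, `summary`, `predict`, `coef`, `plot`) plus
  `extract_representation()` / `representation_map()` for layer geometry.
- **Abstraction metrics** — `classifier_generalization()` and
  `regression_generalization()` (train on one half of latent space, test on
  the other; chance 0.5 and r² = 0), `participation_ratio()`,
  `sparseness()`, `few_shot_novel_task()`.
- **Theory** — `sign_covariance()` computes the closed-form covariance of
  task label vectors, `M_ij = 1 − (2/π)·arccos(A_i·A_j)`, its linear
  approximation `(2/π)AAᵀ` of rank `min(P, D)`, and Monte-Carlo
  verification; this is the analytic account of why training amplifies a
  `min(P, D)`-dimensional latent-aligned component.
- **Reinforcement learning** — `train_rl()` trains the same architecture
  with a single-step deep deterministic policy gradient scheme (one critic
  per task, ±0.33 reward threshold).
- **Experiments** — `run_task_sweep()`, `run_mixture_sweep()`,
  `run_lengthscale_grid()` orchestrate the sweeps with deterministic
  replicate seeding and resumable on-disk caches. A thin CLI wrapper over
  these functions ships in `inst/scripts/abstractrep`.

The network trainers (masked multi-task MLP, participation-ratio-regularized
autoencoder, DDPG actor–critic) are implemented in RcppArmadillo; everything
runs on a single CPU in minutes.

## Worked example

Train the standard input, train a 10-task model on it, and measure
abstraction (a few minutes on one CPU):

```r
library(abstractrep)

inp <- train_standard_input(d = 5, seed = 100)
x   <- sample_latents(5000, 5, seed = 9)
act <- encode_latents(inp, x)
participation_ratio(act)      # 197.2  -- ~200-dimensional code
sparseness(act)$mean          # 0.964  -- each unit responds rarely
mean(act > 0)                 # 0.049  -- ~5% of units active per stimulus

fit <- multitask_model(inp, make_linear_tasks(10, 5, seed = 101),
                       spec = network_spec(seed = 102),
                       config = train_config(seed = 103))
fit
#> Multi-tasking network
#>   tasks: 10 (linear_tasks)  latent dims: 5
#>   architecture: 500 -> 250 -> 150 -> 100 -> 50 -> 10 (sigmoid)
#>   trained 200 epochs; final loss 0.0002; mean task accuracy 1.000

rep <- representation_map(fit)        # the 50-unit representation layer
classifier_generalization(rep, d = 5)
#> <classifier generalization> standard: 0.897  generalization: 0.861  (10 splits)
regression_generalization(rep, d = 5)
#> <regression generalization> standard: 0.807  generalization: 0.497  (10 splits)

# compare: the raw input is decodable in-region but does not generalize
classifier_generalization(inp, d = 5)
#> <classifier generalization> standard: 0.941  generalization: 0.709  (10 splits)
```

The classifier generalization score of 0.86 — far above the raw input's
0.71 and approaching its own in-region score — says a category learned in
one half of latent space transfers to the other half: training on ten
classification tasks has pulled a largely abstract, latent-aligned code out
of a tangled input (it keeps rising with more tasks, reaching about 0.89 by
fifteen). The same metrics applied to the raw input (bottom) show high
in-region decodability but poor generalization — the signature of a
non-abstract code.

The analytic side, in closed form:

```r
A <- make_linear_tasks(20, 5, seed = 1)$A
sc <- sign_covariance(A, n_samples = 1e5, seed = 2)
sc$rank["linear"]   # 5  = min(P, D), exactly
sc$pr               # soft ranks of the analytic / linear / empirical matrices
```

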