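# Shared, lazily built fixtures. Network training is the expensive part of
# this suite, so trained objects are built once per test run and reused by
# every file that needs them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# the standard input used across the suite
std_input <- function() {
  fixture("std_input", function() train_standard_input(d = 5, seed = 100))
}

# a small, quickly trained multi-tasking model for structural tests
small_model <- function() {
  fixture("small_model", function() {
    inp <- make_rf_input(3, m_units = 60L, rf_width = 0.5, seed = 4)
    multitask_model(inp, make_linear_tasks(4, 3, seed = 5),
                    spec = network_spec(c(40L, 20L), seed = 6),
                    config = train_config(n_examples = 2000L, epochs = 30L,
                                          seed = 7))
  })
}

# full-scale multi-tasking models for the acceptance criteria, keyed by
# task family and count
trained_model <- function(key, builder) {
  fixture(paste0("model_", key), builder)
}

default_model <- function(tasks, partial = NULL, seed = 1000L,
                          epochs = 200L) {
  multitask_model(std_input(), tasks,
                  spec = network_spec(seed = seed + 1L),
                  config = train_config(epochs = epochs, seed = seed + 2L),
                  partial = partial)
}
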