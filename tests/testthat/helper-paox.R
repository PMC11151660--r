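# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_fixtures <- function() {
  get_fixture("small_fixtures", function() make_fixtures(seed = 42, n = 400))
}

# a tiny trained masked-LSTM on baseline spectra, reused by masking and
# prediction-contract tests
tiny_lstm <- function() {
  get_fixture("tiny_lstm", function() {
    ds <- zscore_dataset(small_fixtures()$base)
    h <- lstm_hyperparams(epochs = 3, batch_size = 128, seed = 11)
    train(build_lstm(h), ds)
  })
}

# build a dataset directly from an amplitude matrix (mask all-present by
# default), with arbitrary labels
ds_from_matrix <- function(amps, mask = NULL, so2 = NULL,
                           normalized = FALSE) {
  n <- nrow(amps)
  if (is.null(mask)) mask <- matrix(TRUE, n, 41)
  if (is.null(so2)) so2 <- rep(0.5, n)
  spectra_dataset(amps, mask, so2, normalized = normalized)
}

# noiseless spectra that are pure blood absorption at saturation s, with a
# per-spectrum scale factor (removed by z-scoring)
analytic_spectra <- function(s, scale = 1) {
  tab <- chromophore_table()
  t(vapply(seq_along(s),
           function(i) scale[[min(i, length(scale))]] *
             blood_absorption(s[i], 1, tab),
           numeric(41)))
}

# internal counter RNG, used to build test inputs deterministically
pa_runif_stream <- paox:::pa_runif_stream
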