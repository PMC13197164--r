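# Session-level cache so expensive solves (Kalman recursions, Nash gain
# sequences, noise-free probe batches) are shared across test files.
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

default_params <- function() cached("params", model_params())

default_kalman <- function() {
  cached("kalman", {
    p <- default_params()
    dyn <- build_dynamics(p)
    obs <- build_observation(p)
    list(k1 = compute_kalman_gains(dyn, obs$C1, obs$V, params = p),
         k2 = compute_kalman_gains(dyn, obs$C2, obs$V, params = p))
  })
}

cached_model <- function(condition, hypothesis) {
  cached(paste("model", condition, hypothesis), {
    build_model(condition, hypothesis, default_params(),
                kalman = default_kalman())
  })
}

# noise-free probe batch over all four conditions for one hypothesis
cached_noisefree_batch <- function(hypothesis, experiment = 1L) {
  cached(paste("nfbatch", hypothesis, experiment), {
    run_batch(hypothesis, conditions(), default_params(), n_trials = 1L,
              experiment = experiment, noise = FALSE,
              kalman = default_kalman())
  })
}

noisefree_involuntary <- function(hypothesis, experiment = 1L) {
  vapply(cached_noisefree_batch(hypothesis, experiment),
         `[[`, numeric(1), "involuntary_mean")
}
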