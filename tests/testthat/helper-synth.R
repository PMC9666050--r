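# Shared synthetic data sets, generated once per test run.

.synth_cache <- new.env(parent = emptyenv())

cached_recordings <- function(delta = 2, trials = 6L, seed = 42L,
                              duration = 6) {
  key <- paste(delta, trials, seed, duration, sep = "|")
  if (is.null(.synth_cache[[key]]))
    .synth_cache[[key]] <- generate_recordings(
      synth_spec(n_trials_per_class = trials, delta = delta,
                 duration = duration),
      seed = seed)
  .synth_cache[[key]]
}
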