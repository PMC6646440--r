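# The scaled label-recovery experiment is shared by several acceptance
# checks; memoise it so it trains once per test run.
acceptance_experiment <- local({
  env <- new.env(parent = emptyenv())
  function() {
    if (is.null(env$res)) {
      env$res <- label_recovery_experiment(seed = 42)
    }
    env$res
  }
})
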