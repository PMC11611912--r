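# The benchmark study is expensive; build it once per test session.
acceptance_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_stall_study(seed = 42L)
    cache
  }
})
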