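# Noise-free test-day records lying exactly on a Wood curve
exact_records <- function(params, days, cow_id = "c1", trait = "milk") {
  df <- data.frame(cow_id = cow_id, herd_id = "h1", day = days)
  df[[trait]] <- wood_eval(params, days)
  df
}

# Reference herd-level curve used throughout (full-lactation fit of a
# high-yield primiparous herd)
t1_params <- wood_params(13.7833, 0.3056, 0.0029)

# A small deterministic herd, cached per options so suites stay fast
small_herd <- local({
  cache <- list()
  function(n_cows = 80, seed = 1, ...) {
    key <- paste(n_cows, seed, ..., sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <<- simulate_herd(herd_sim_config(n_cows = n_cows,
                                                     seed = seed, ...))
    cache[[key]]
  }
})
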