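# Build a complete 14-parameter feature table in which every parameter
# column carries the same per-call values. Lets toy group structures drive
# the statistics without fabricating 14 independent columns.
toy_table <- function(values, ids) {
  stopifnot(length(values) == length(ids))
  tab <- data.frame(call_id = sprintf("c%03d", seq_along(values)),
                    individual_id = ids)
  for (p in cooid:::FEATURE_NAMES) tab[[p]] <- values
  read_feature_table(tab)
}

# A random but valid feature table: independent positive columns.
random_table <- function(n, ids, seed = 1) {
  set.seed(seed)
  tab <- data.frame(call_id = sprintf("c%03d", seq_len(n)),
                    individual_id = rep_len(ids, n))
  for (p in cooid:::FEATURE_NAMES) tab[[p]] <- 100 + rnorm(n)
  read_feature_table(tab)
}

# Short synthetic call reused across acoustic tests.
test_call <- local({
  cache <- NULL
  function(noise_gain = 0.08, seed = 11, f0 = 350, shape = "arc") {
    key <- paste(noise_gain, seed, f0, shape)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$rec)
    p <- individual_profile("T", mean_f0 = f0, contour_shape = shape,
                            vocal_tract_length = 9, noise_gain = noise_gain,
                            mean_duration = 0.35)
    rec <- synthesize_call(p, seed)
    cache <<- list(key = key, rec = rec)
    rec
  }
})
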