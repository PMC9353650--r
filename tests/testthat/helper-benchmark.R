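# The desk-scale benchmark (5 paired seeds) is shared between the end-to-end
# accuracy test and the token-localization test; run it once per session.

.bench_cache <- new.env(parent = emptyenv())

benchmark_runs <- function() {
  if (is.null(.bench_cache$runs)) {
    runs <- lapply(1:5, function(s) {
      data <- desk_dataset(s)
      list(ct = run_desk_experiment(seed = s, epochs = 30, ssl = TRUE,
                                    data = data),
           sup = run_desk_experiment(seed = s, epochs = 30, ssl = FALSE,
                                     data = data))
    })
    .bench_cache$runs <- runs
  }
  .bench_cache$runs
}
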