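# shared fixtures: templates are deterministic, so build each mode once
.fixtures <- new.env(parent = emptyenv())

get_template <- function(mode = "full_478") {
  key <- paste0("tpl_", mode)
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- generate_template(mode)
  .fixtures[[key]]
}

# sweep config with strided indices, for tests that exercise registration
# but do not depend on fine scale resolution
fast_cfg <- function(mode = "full_478", stride = 25L, ...) {
  n <- if (mode == "full_478") 478L else 68L
  registration_config(sweep_indices = seq(0L, n - 1L, by = stride), ...)
}

# the seed-fixed method-comparison benchmark shared by the acceptance tests:
# full scale sweep, coarse initializations at every 10th index
bench_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_method_benchmark(n_cases = 20L,
                                     noise_levels = c(0, 0.005, 0.01),
                                     init_stride = 10L, seed = 100L)
    cache
  }
})

expect_transform_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a$matrix - b$matrix)), tol)
}
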