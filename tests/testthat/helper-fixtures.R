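# Shared fixtures: a tiny model configuration that exercises every component
# at minimal cost, and small random-tensor helpers.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(num_patches = 5, layers = 2, heads = 4, adjusted_channels = 8,
                   num_class = 2, input_side = 16, stem = "tiny", seed = 1)
  do.call(fbanet_config, utils::modifyList(defaults, args))
}

# desk-scale configuration used for learning experiments
desk_config <- function(...) {
  args <- list(...)
  defaults <- list(num_patches = 5, layers = 6, heads = 8, adjusted_channels = 16,
                   num_class = 2, input_side = 32, stem = "tiny", seed = 0)
  do.call(fbanet_config, utils::modifyList(defaults, args))
}

rand_tensor <- function(dims, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(prod(dims)), dims)
}

rand_batch <- function(side, n, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(side * side * 3 * n), c(side, side, 3, n))
}

# small labeled synthetic corpus, memoised per test run
small_htp <- local({
  cache <- new.env()
  function(n = 24, seed = 7, canvas = 128, ...) {
    key <- paste(n, seed, canvas, ...)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_htp_like(htp_gen_params(
        n_samples = n, canvas_side = canvas, seed = seed, ...))
    cache[[key]]
  }
})
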