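# Shared fixtures: small, fast phantoms and volumes built in code.

random_volume <- function(dims, domain = "image", seed = 1) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    n <- prod(dims)
    complex_volume(array(complex(real = rnorm(n), imaginary = rnorm(n)),
                         dim = dims), domain = domain)
  })
}

small_phantom_spec <- function(...) {
  args <- list(...)
  defaults <- list(matrix_size = c(32L, 30L, 8L), n_structures = 4L,
                   noise_sigma = 0, seed = 7L)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

tiny_net <- function(h = 16L, depth = 2L, base = 4L, residual = TRUE,
                     seed = 3L) {
  build_model(network_config(c(h, h, 2L), depth, base, residual), seed = seed)
}
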