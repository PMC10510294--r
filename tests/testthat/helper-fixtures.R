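# Shared fixtures: small deterministic arrays and a cached small phantom.

rand_vol <- function(dims, seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  mac_volume(array(stats::runif(prod(dims)), dims), spacing = spacing)
}

# A small phantom reused across tests (generated once per session).
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(
        generate_phantom(phantom_config(size = c(32L, 32L, 24L), seed = 11)))
    cache
  }
})

const_field <- function(dims, disp, spacing = c(1, 1, 1)) {
  a <- array(0, c(dims, 3L))
  for (c in 1:3) a[, , , c] <- disp[c]
  mac_field(a, spacing)
}
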