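# Shared fixtures, all built in code.

# coarse phantom presets that keep unit tests fast
small_spec <- function(seed = 1, dims = c(32, 32, 24), spacing = c(8, 8, 8),
                       ...) {
  phantom_spec(seed = seed, dims = dims, spacing = spacing, ...)
}

tiny_spec <- function(seed = 1) {
  phantom_spec(seed = seed, dims = c(24, 24, 24), spacing = c(10, 10, 10))
}

# full engine on a coarse grid; memoised per session because several
# files need the same operator
small_engine <- local({
  cache <- new.env()
  function(seed = 1) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      ph <- generate_phantom(small_spec(seed))
      infl <- build_influence(ph$grid, ph$vois$body, beam_set())
      cache[[key]] <- list(ph = ph, infl = infl)
    }
    cache[[key]]
  }
})

# hand-built influence toy: explicit matrix, one voxel per grid cell
toy_influence <- function(M, spacing = 1) {
  n <- nrow(M)
  influence_from_matrix(M, voxel_grid(c(n, 1, 1), rep(spacing, 3)))
}

# a 3-voxel / 3-bixel toy with disjoint-support structure used by the
# DMR separability checks:
#   voxel 1 (v): bixels 1 (a=1.0) and 2 (a=0.5)
#   voxel 2 (r): bixels 2 (a=0.5) and 3 (a=1.0)
#   voxel 3    : bixel 3 only (a=0.2)
separable_toy <- function(w = c(10, 10, 10)) {
  M <- rbind(c(1, 0.5, 0),
             c(0, 0.5, 1),
             c(0, 0, 0.2))
  infl <- toy_influence(M)
  vois <- list(body = voi("body", "body", array(TRUE, c(3, 1, 1))))
  list(infl = infl, state = plan_state(infl, w, vois))
}

random_toy_plan <- function(nvox = 12, nbix = 8, seed = 1) {
  set.seed(seed)
  M <- matrix(runif(nvox * nbix) * (runif(nvox * nbix) < 0.4), nvox, nbix)
  infl <- toy_influence(M)
  vois <- list(body = voi("body", "body", array(TRUE, c(nvox, 1, 1))))
  plan_state(infl, runif(nbix, 1, 5), vois)
}
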