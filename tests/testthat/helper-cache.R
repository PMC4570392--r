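# Shared, lazily built objects. The default scene and its renders are used
# by several test files; building them once keeps the suite fast.
cache_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = cache_env, inherits = FALSE)) {
    assign(key, force(expr), envir = cache_env)
  }
  get(key, envir = cache_env, inherits = FALSE)
}

# default scenario (seed 42) and its ground truth
default_scene <- function() {
  cached("scene", {
    sc <- field_scenario()
    list(sc = sc, truth = generate_scene(sc))
  })
}

# 30 m multispectral baseline render (1.6 cm/px, R/NIR)
baseline_render <- function() {
  cached("render30", {
    s <- default_scene()
    render_image(s$truth, s$sc, 1.6, "RNIR")
  })
}

# the paired 60 m analogue: rendered at 3.25 cm vs NN-resampled 1.6 -> 3.25,
# with the OBIA map of each
paired_maps <- function() {
  cached("maps", {
    base <- baseline_render()
    s <- default_scene()
    rs <- nn_resample(base, resample_spec(1.6, 3.25))
    uav <- render_image(s$truth, s$sc, 3.25, "RNIR")
    list(rs = rs, uav = uav, map_rs = run_obia(rs), map_uav = run_obia(uav))
  })
}

# small deterministic two-band test image
tiny_image <- function(seed = 7, nr = 31, nc = 29) {
  dn <- function(k) matrix(as.integer((seq_len(nr * nc) * k + seed) %% 256),
                           nr, nc)
  ortho_image(list(R = dn(7), NIR = dn(13)), gsd = 2)
}
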