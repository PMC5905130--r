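# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env))
    assign(key, force(expr), envir = fixture_env)
  get(key, envir = fixture_env)
}

tiny_spec <- function(...) {
  args <- list(width = 324L, height = 243L, n_seeds = 50L, rng_seed = 11L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scene_spec, args)
}

# default-noise scene + classifier trained on a sibling scene
tiny_scene <- function() cached("tiny_scene", generate_scene(tiny_spec()))

tiny_clf <- function() cached("tiny_clf", {
  sc <- generate_scene(tiny_spec(rng_seed = 99L))
  train_pixel_classifier(sc$images$white, scribble_labels(sc, seed = 0L),
                         seed = 0L)
})

tiny_prob <- function() cached("tiny_prob",
  predict_pixels(tiny_clf(), tiny_scene()$images$white))

# noise-free pair (no pixel noise, no texture, no debris)
clean_spec <- function(...) tiny_spec(noise_sd = 0, texture_sd = 0,
                                      n_debris = 0L, ...)

clean_scene <- function() cached("clean_scene",
  generate_scene(clean_spec(rng_seed = 21L)))

clean_clf <- function() cached("clean_clf", {
  sc <- generate_scene(clean_spec(rng_seed = 22L))
  train_pixel_classifier(sc$images$white, scribble_labels(sc, seed = 0L),
                         seed = 0L)
})

# ground-truth pixel classes: 1 seed interior, 2 rim, 3 background
truth_pixel_classes <- function(scene) {
  out <- matrix(3L, nrow(scene$truth$label_mask),
                ncol(scene$truth$label_mask))
  out[scene$truth$label_mask > 0L] <- 1L
  out[scene$truth$rim_mask] <- 2L
  out
}

# probability map of hand-placed ellipses (for declump tests):
# interior -> Seed, a 2 px rim ring -> SeedEdge, elsewhere Background
ellipse_prob_map <- function(nr, nc, centres, a, b) {
  ps <- matrix(0.02, nr, nc); pe <- matrix(0.03, nr, nc)
  for (k in seq_len(nrow(centres))) {
    dx <- outer(seq_len(nr) - centres[k, 1], rep(1, nc))
    dy <- outer(rep(1, nr), seq_len(nc) - centres[k, 2])
    full <- (dx / a[k])^2 + (dy / b[k])^2 <= 1
    inner <- (dx / max(a[k] - 2, 1))^2 + (dy / max(b[k] - 2, 1))^2 <= 1
    ps[inner] <- 0.95
    pe[full & !inner] <- 0.9
  }
  pb <- pmax(1 - ps - pe, 0)
  tot <- ps + pe + pb
  array(c(ps / tot, pe / tot, pb / tot), dim = c(nr, nc, 3L),
        dimnames = list(NULL, NULL, c("Seed", "SeedEdge", "Background")))
}
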