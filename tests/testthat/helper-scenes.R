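# Small fixtures shared across test files (all generated in code).

tiny_scene_config <- function(hw = c(96L, 96L), counts = c(5L, 15L)) {
  scene_config(image_hw = hw, count_range = counts,
               parent_intensity = 5e-4, cluster_sd = 15)
}

tiny_scenes <- function(n, seed = 11L, hw = c(96L, 96L), counts = c(5L, 15L)) {
  cfg <- tiny_scene_config(hw, counts)
  lapply(seq_len(n), function(i) generate_scene(cfg, seed = seed * 100L + i))
}

# seeded dot set kept at least `margin` pixels from every border
interior_dots <- function(n, hw, margin, seed = 5L) {
  withr::with_seed(seed, data.frame(
    x = runif(n, margin, hw[2] - margin - 1),
    y = runif(n, margin, hw[1] - margin - 1)))
}
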