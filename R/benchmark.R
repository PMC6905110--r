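#' Desk-scale synthetic counting benchmark
#'
#' A fixed, seeded benchmark small enough to train on one CPU while keeping
#' the canonical 94/16/15 window geometry meaningful: 192 x 192 scenes
#' (stride-aligned), 10-50 clustered objects each, full jitter. Train/test
#' scenes come from disjoint seed streams derived from `seed`. The
#' benchmark exists to compare model variants under identical conditions —
#' orderings between variants, not absolute errors, are its output.
#'
#' @param n_train,n_test Number of scenes per split.
#' @param seed Master seed.
#' @return `list(train, test)` of scene lists.
#' @export
benchmark_scenes <- function(n_train = 18L, n_test = 8L, seed = 1L) {
  cfg <- benchmark_scene_config()
  train <- lapply(seq_len(n_train),
                  function(i) generate_scene(cfg, seed = seed * 1000L + i))
  test <- lapply(seq_len(n_test),
                 function(i) generate_scene(cfg, seed = seed * 1000L + 500L + i))
  list(train = train, test = test)
}

#' @rdname benchmark_scenes
#' @export
benchmark_scene_config <- function() {
  scene_config(image_hw = c(192L, 192L), count_range = c(10L, 50L),
               parent_intensity = 2e-4, cluster_sd = 25)
}

#' Training configurations used by the benchmark
#'
#' Fully convolutional variants train whole images in minibatches of 4 for
#' 14 epochs; patch variants sample 12 grid cells per image per epoch in
#' minibatches of 8 for 16 epochs (patch models see one window per sample
#' instead of a whole grid, so they need more passes to consume comparable
#' supervision). Both members of each compared pair share their
#' configuration exactly.
#'
#' @param input_kind `"image"` or `"patch"`.
#' @param seed Seed forwarded to [train_config()].
#' @return A [train_config()].
#' @export
benchmark_train_config <- function(input_kind = c("image", "patch"),
                                   seed = 1L) {
  input_kind <- match.arg(input_kind)
  if (input_kind == "image")
    train_config(epochs = 14L, batch_size = 4L, seed = seed)
  else
    train_config(epochs = 16L, batch_size = 8L, patches_per_image = 12L,
                 seed = seed)
}

#' Train benchmark variants and compare their test errors
#'
#' Trains each requested variant on the shared benchmark training scenes
#' with the matched [benchmark_train_config()], predicts every test scene's
#' count through the merge-and-normalize pipeline, and reports MAE/RMSE per
#' variant. Used to reproduce the two ablation orderings: regressing the
#' central 64x64 window beats regressing the whole 94x94 receptive field
#' (context is necessary), and training with context beats training
#' without it.
#'
#' @param variants Character vector of variant names.
#' @param seed Master seed (scenes, initialization, sampling).
#' @param n_train,n_test Benchmark split sizes.
#' @param verbose Log per-epoch training lines.
#' @return Data frame: variant, mae, rmse; attribute `"predictions"` holds
#'   the per-scene predicted/true counts.
#' @export
run_benchmark <- function(variants = c("tasselnetv2", "tasselnetv2_del_c",
                                       "tasselnet", "tasselnet_ctx"),
                          seed = 1L, n_train = 18L, n_test = 8L,
                          verbose = FALSE) {
  sc <- benchmark_scenes(n_train = n_train, n_test = n_test, seed = seed)
  gt <- vapply(sc$test, function(s) as.numeric(s$count), numeric(1))
  preds <- list()
  rows <- lapply(variants, function(v) {
    kind <- variant_geometry(v)$input_kind
    cfg <- benchmark_train_config(kind, seed = seed)
    cfg$verbose <- verbose
    model <- train_model(v, sc$train, cfg)
    pred <- vapply(sc$test, function(s) predict_count(model, s$image),
                   numeric(1))
    preds[[v]] <<- data.frame(variant = v, pred = pred, gt = gt)
    ev <- evaluate_counts(data.frame(pred = pred, gt = gt))
    data.frame(variant = v, mae = ev$mae, rmse = ev$rmse)
  })
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- do.call(rbind, preds)
  out
}
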