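abort_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("spikecount_validation_error",
                                             "error", "condition")))
}

abort_geometry <- function(...) {
  stop(errorCondition(paste0(...), class = c("spikecount_geometry_error",
                                             "error", "condition")))
}

MODEL_VARIANTS <- c("tasselnet", "tasselnet_ctx", "tasselnetv2",
                    "tasselnetv2_del_c")

# Target/input geometry of each variant. All variants share the same output
# grid (floor((H + 2 pad - rf) / 16) + 1 per side); they differ in what one
# output unit sees (patch vs whole image, padded vs context) and in which
# window's count it regresses (central 64x64 vs full 94x94 receptive field).
variant_geometry <- function(variant) {
  switch(variant,
    tasselnet = list(input_kind = "patch", patch_size = 64L, window = 64L,
                     context = 0L, pad = 0L, stride = 16L),
    tasselnet_ctx = list(input_kind = "patch", patch_size = 94L, window = 64L,
                         context = 15L, pad = 15L, stride = 16L),
    tasselnetv2 = list(input_kind = "image", patch_size = 94L, window = 64L,
                       context = 15L, pad = 15L, stride = 16L),
    tasselnetv2_del_c = list(input_kind = "image", patch_size = 94L,
                             window = 94L, context = 0L, pad = 15L,
                             stride = 16L),
    abort_validation("unknown variant '", variant, "'; valid names: ",
                     paste(MODEL_VARIANTS, collapse = ", ")))
}

variant_spec <- function(variant) {
  switch(variant,
    tasselnet = canonical_spec("tasselnet"),
    tasselnet_ctx = canonical_spec("tasselnet_ctx"),
    tasselnetv2 = ,
    tasselnetv2_del_c = canonical_spec("tasselnetv2"))
}

#' Build a counting network with freshly initialized weights
#'
#' Weights are drawn with the improved Xavier (He) scheme,
#' `N(0, sqrt(2 / fan_in))`; every convolution except the final 1x1 count
#' read-out is followed by batch normalization and ReLU; the read-out has a
#' bias and a non-negativity clamp applied at inference only. Initialization
#' is fully determined by `seed`.
#'
#' @param variant One of `"tasselnet"` (64x64 padded patches),
#'   `"tasselnet_ctx"` (94x94 patches, padding stripped), `"tasselnetv2"`
#'   (fully convolutional, per-layer padding) or `"tasselnetv2_del_c"`
#'   (same network as tasselnetv2 but regressing the count of the whole
#'   94x94 receptive field instead of its central 64x64 window).
#' @param seed Integer seed for the weight draw.
#' @return A `count_model`.
#' @examples
#' m <- build_model("tasselnetv2", seed = 7)
#' count_model_parameters(m)$weights  # 638000
#' @export
build_model <- function(variant, seed = 1L) {
  geom <- variant_geometry(variant)
  spec <- variant_spec(variant)
  structure(list(variant = variant, spec = spec, geometry = geom,
                 net = init_net(spec, seed),
                 norm_means = c(0, 0, 0), history = NULL, config = NULL),
            class = "count_model")
}

#' @export
print.count_model <- function(x, ...) {
  g <- x$geometry
  cat("count_model '", x$variant, "': ", g$input_kind, " input, window ",
      g$window, ", stride ", g$stride, ", context ", g$context, ", pad ",
      g$pad, "\n", sep = "")
  p <- count_model_parameters(x)
  cat("  parameters: ", p$weights, " conv weights (", p$total,
      " incl. bias/batch-norm)\n", sep = "")
  if (!is.null(x$history) && any(!is.na(x$history$val_mae)))
    cat("  trained ", nrow(x$history), " epochs, best val MAE ",
        signif(min(x$history$val_mae, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

#' Parameter counts of a runnable model
#'
#' @param model A [build_model()] `count_model`.
#' @return `list(weights, overhead, total)`: convolution weights only (the
#'   headline figure), learnable bias + batch-norm parameters, and their sum.
#' @export
count_model_parameters <- function(model) {
  stopifnot(inherits(model, "count_model"))
  weights <- 0; overhead <- 0
  for (ly in model$net) {
    if (ly$kind != "conv") next
    weights <- weights + length(ly$W)
    if (!is.null(ly$b)) overhead <- overhead + length(ly$b)
    if (isTRUE(ly$bn)) overhead <- overhead + length(ly$gamma) + length(ly$beta)
  }
  stopifnot(weights == count_parameters(model$spec))
  list(weights = weights, overhead = overhead, total = weights + overhead)
}

check_image_array <- function(image) {
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3L))
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    abort_validation("image must be an H x W x 3 array")
  image
}

subtract_means <- function(image, means) {
  d <- dim(image)
  image - rep(means, each = d[1] * d[2])
}

# patch anchored at (top, left) (0-based, may be negative) on the original
# image, zero-filled outside -- the zero fill matches the zeros that the
# fully convolutional form pads internally
extract_patch <- function(image, top, left, size) {
  d <- dim(image)
  patch <- array(0, c(size, size, d[3]))
  r0 <- max(0L, top); r1 <- min(d[1], top + size)
  c0 <- max(0L, left); c1 <- min(d[2], left + size)
  if (r1 > r0 && c1 > c0)
    patch[(r0 - top + 1L):(r1 - top), (c0 - left + 1L):(c1 - left), ] <-
      image[(r0 + 1L):r1, (c0 + 1L):c1, ]
  patch
}

# net used for single-patch evaluation: fully convolutional weights are
# applied with per-layer padding stripped so one 94x94 receptive field maps
# to one output unit
patch_net <- function(model) {
  if (model$geometry$input_kind == "patch") return(model$net)
  lapply(model$net, function(e) {
    if (e$kind == "conv" && e$pad > 0) {
      e2 <- as.environment(as.list(e)); e2$pad <- 0L; e2
    } else e
  })
}

#' Forward one local patch to its predicted count
#'
#' The patch must match the variant's expected input exactly (64x64 for
#' `tasselnet`, 94x94 for the context variants): evaluating a model on
#' patches of the wrong geometry — e.g. feeding context patches to a network
#' trained without context — is refused unless the model was explicitly
#' converted with [with_test_time_context()].
#'
#' @param model A `count_model`.
#' @param patch `size x size x 3` array (raw pixel values; channel means are
#'   subtracted internally).
#' @param train Internal: run batch norm in training mode.
#' @return A single non-negative count (negative raw outputs are clamped at
#'   inference).
#' @export
forward_patch <- function(model, patch, train = FALSE) {
  stopifnot(inherits(model, "count_model"))
  patch <- check_image_array(patch)
  ps <- model$geometry$patch_size
  d <- dim(patch)
  if (d[1] != ps || d[2] != ps)
    abort_geometry("variant '", model$variant, "' expects ", ps, "x", ps,
                   " patches, got ", d[1], "x", d[2],
                   " (use with_test_time_context() to override geometry)")
  x <- subtract_means(patch, model$norm_means)
  out <- net_forward1(patch_net(model), x, train = train)$out
  if (length(out) != 1L)
    abort_geometry("patch produced a ", dim(out)[1], "x", dim(out)[2],
                   " grid instead of a single count")
  v <- out[1, 1, 1]
  if (!train) v <- max(0, v)
  v
}

#' Fully convolutional forward pass over a whole image
#'
#' Runs the image through the network once; the per-layer zero paddings
#' accumulate to the 15-pixel border that keeps every local area 94x94, so
#' no explicit canvas padding or patch extraction happens.
#'
#' @param model A fully convolutional `count_model` (`tasselnetv2` or
#'   `tasselnetv2_del_c`).
#' @param image `H x W x 3` array.
#' @param train Internal: training-mode batch norm, no clamp.
#' @return A [raw_count_grid()] of local counts, one per output cell.
#' @export
forward_image <- function(model, image, train = FALSE) {
  stopifnot(inherits(model, "count_model"))
  if (model$geometry$input_kind != "image")
    abort_geometry("variant '", model$variant,
                   "' is patch-based; use predict_grid() for dense inference")
  image <- check_image_array(image)
  output_shape(model$spec, dim(image)[1:2])  # errors naming the layer if too small
  out <- net_forward1(model$net, subtract_means(image, model$norm_means),
                      train = train)$out
  v <- out[, , 1, drop = TRUE]
  v <- matrix(v, dim(out)[1], dim(out)[2])
  if (!train) v[v < 0] <- 0
  raw_count_grid(v, dim(image)[1:2], window = model$geometry$window,
                 stride = model$geometry$stride, pad = model$geometry$pad,
                 context = model$geometry$context)
}

#' Dense local-count predictions for any variant
#'
#' For fully convolutional variants this is a single [forward_image()] pass;
#' for patch variants it extracts every grid patch and forwards them one by
#' one — same grid, redundant computation.
#'
#' @param model A `count_model`.
#' @param image `H x W x 3` array.
#' @return A [raw_count_grid()].
#' @export
predict_grid <- function(model, image) {
  image <- check_image_array(image)
  if (model$geometry$input_kind == "image") return(forward_image(model, image))
  g <- model$geometry
  hw <- dim(image)[1:2]
  rf <- g$window + 2L * g$context
  n_h <- (hw[1] + 2L * g$pad - rf) %/% g$stride + 1L
  n_w <- (hw[2] + 2L * g$pad - rf) %/% g$stride + 1L
  if (n_h < 1L || n_w < 1L)
    abort_geometry("image ", hw[1], "x", hw[2], " too small for variant '",
                   model$variant, "'")
  vals <- matrix(0, n_h, n_w)
  net <- patch_net(model)
  x <- subtract_means(image, model$norm_means)
  cells <- expand.grid(i = 0:(n_h - 1L), j = 0:(n_w - 1L))
  for (start in seq(1L, nrow(cells), by = 32L)) {
    sel <- start:min(nrow(cells), start + 31L)
    patches <- lapply(sel, function(k)
      extract_patch(x, cells$i[k] * g$stride - g$pad,
                    cells$j[k] * g$stride - g$pad, g$patch_size))
    outs <- net_forward(net, patches, train = FALSE)$outs
    vals[cbind(cells$i[sel] + 1L, cells$j[sel] + 1L)] <-
      pmax(0, vapply(outs, function(o) o[1, 1, 1], numeric(1)))
  }
  raw_count_grid(vals, hw, window = g$window, stride = g$stride, pad = g$pad,
                 context = g$context)
}

#' Predict the object count of one image
#'
#' Dense local counts are merged into a normalized count map and integrated.
#'
#' @param model A `count_model`.
#' @param image `H x W x 3` array.
#' @return Non-negative scalar count estimate.
#' @export
predict_count <- function(model, image) {
  image_count(merge_normalize(predict_grid(model, image)))
}

#' Explicitly evaluate a padded-trained network on context patches
#'
#' Reproduces the "context only at test time" information-asymmetry setting:
#' the padding of a `tasselnet` model is stripped so that the same weights
#' receive 94x94 context patches they were never trained on. This geometry
#' mismatch degrades accuracy and is therefore never applied silently;
#' calling this converter is the required explicit override.
#'
#' @param model A trained `tasselnet` `count_model`.
#' @return A `count_model` with `tasselnet_ctx` input geometry, same weights.
#' @export
with_test_time_context <- function(model) {
  stopifnot(inherits(model, "count_model"))
  if (model$variant != "tasselnet")
    abort_validation("test-time context override applies to 'tasselnet' models")
  model$spec <- strip_padding(model$spec)
  model$geometry <- variant_geometry("tasselnet_ctx")
  model$net <- lapply(model$net, function(e) {
    e2 <- as.environment(as.list(e))
    if (e2$kind == "conv") e2$pad <- 0L
    e2
  })
  model$variant <- "tasselnet_ctx"
  model$context_override <- TRUE
  model
}

#' Training configuration
#'
#' @param epochs Number of passes over the training images.
#' @param lr Initial learning rate (0.1, reduced on plateau).
#' @param lr_factor Multiplicative decay applied when validation MAE fails to
#'   improve for `patience` epochs.
#' @param patience Plateau patience in epochs.
#' @param batch_size Gradient-accumulation size (images for fully
#'   convolutional variants, patches for patch variants).
#' @param patches_per_image Patches sampled per image per epoch for
#'   patch-based variants.
#' @param split Training fraction of the train/validation split.
#' @param seed Seed governing the split, initialization and sampling.
#' @param loss `"l1"` (mean absolute deviation on local counts) or `"l2"`.
#' @param momentum Classical momentum coefficient (0 = plain SGD).
#' @param weight_decay L2 penalty on convolution weights (batch-norm
#'   parameters and the read-out bias are not decayed). With batch
#'   normalization absorbing all scale, undecayed weights drift upward and
#'   de-calibrate the running inference statistics, so a small standard
#'   decay is on by default.
#' @param sigma Gaussian bandwidth for the density-map targets.
#' @param verbose Print one log line per epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30L, lr = 0.1, lr_factor = 0.1,
                         patience = 10L, batch_size = 8L,
                         patches_per_image = 16L, split = 0.9, seed = 1L,
                         loss = c("l1", "l2"), momentum = 0,
                         weight_decay = 5e-4, sigma = 4, verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(split > 0, split < 1, epochs >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs), lr = lr, lr_factor = lr_factor,
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 patches_per_image = as.integer(patches_per_image),
                 split = split, seed = as.integer(seed), loss = loss,
                 momentum = momentum, weight_decay = weight_decay,
                 sigma = sigma, verbose = verbose),
            class = "train_config")
}

loss_and_grad <- function(pred, target, loss) {
  n <- length(target)
  diff <- pred - target
  if (loss == "l1") list(loss = mean(abs(diff)), d = sign(diff) / n)
  else list(loss = mean(diff^2), d = 2 * diff / n)
}

#' Train a counting network on annotated scenes
#'
#' Regression targets (Gaussian density maps integrated over the variant's
#' windows) are built from the dot annotations before the first step, and
#' their grid is checked against the network's output geometry. Optimization
#' is stochastic gradient descent on the mean absolute deviation between
#' predicted and target local counts, learning rate 0.1 reduced on
#' validation plateau; the weights with the best validation image-count MAE
#' are retained. Per-channel means of the training images are subtracted
#' from every input. No augmentation is applied.
#'
#' @param variant A variant name (see [build_model()]) or an existing
#'   `count_model` to continue training.
#' @param scenes List of scenes: each `list(image = H x W x 3 array,
#'   dots = data.frame(x, y))` (as produced by [generate_scene()] /
#'   [load_dataset()]).
#' @param config A [train_config()].
#' @return A trained `count_model` with a `history` data frame
#'   (epoch, lr, train_loss, val_mae).
#' @export
train_model <- function(variant, scenes, config = train_config()) {
  stopifnot(inherits(config, "train_config"), length(scenes) >= 1L)
  model <- if (inherits(variant, "count_model")) variant
           else build_model(variant, seed = config$seed)
  g <- model$geometry

  # targets: one local-count grid per scene, geometry-checked up front
  prepared <- lapply(scenes, function(sc) {
    image <- check_image_array(sc$image)
    hw <- dim(image)[1:2]
    dots <- dot_annotation(sc$dots, hw)
    dens <- density_from_dots(dots, sigma = config$sigma)
    lcm <- local_counts(dens, window = g$window, stride = g$stride,
                        pad = g$pad, context = g$context)
    expect <- output_shape(model$spec, hw)
    if (g$input_kind == "image" && !all(dim(lcm$values) == expect))
      abort_geometry("target grid ", nrow(lcm$values), "x", ncol(lcm$values),
                     " vs network output ", expect[1], "x", expect[2])
    list(image = image, target = lcm$values, count = nrow(dots$points))
  })

  withr::with_seed(config$seed + 1L, {
    n <- length(prepared)
    n_train <- max(1L, floor(config$split * n))
    idx <- sample(n)
    tr <- idx[seq_len(n_train)]
    va <- if (n_train < n) idx[(n_train + 1L):n] else integer(0)

    means <- rowMeans(vapply(prepared[tr], function(p)
      apply(p$image, 3L, mean), numeric(3)))
    model$norm_means <- means
    for (s in seq_along(prepared))
      prepared[[s]]$xnorm <- subtract_means(prepared[[s]]$image, means)

    lr <- config$lr
    best <- Inf; best_state <- NULL; since <- 0L
    hist <- data.frame(epoch = integer(0), lr = numeric(0),
                       train_loss = numeric(0), val_mae = numeric(0))

    for (epoch in seq_len(config$epochs)) {
      # the epoch's sample stream: whole images for fully convolutional
      # variants, randomly drawn grid cells for patch variants, shuffled
      # across images so every minibatch mixes scenes
      if (g$input_kind == "image") {
        samples <- lapply(sample(tr), function(s) list(s = s))
      } else {
        samples <- list()
        for (s in tr) {
          nc <- dim(prepared[[s]]$target)
          ks <- sample(prod(nc), min(config$patches_per_image, prod(nc)))
          cells <- arrayInd(ks, nc)
          samples <- c(samples, lapply(seq_len(nrow(cells)), function(r)
            list(s = s, i = cells[r, 1] - 1L, j = cells[r, 2] - 1L)))
        }
        samples <- samples[sample(length(samples))]
      }
      losses <- numeric(0)
      B <- config$batch_size
      for (start in seq(1L, length(samples), by = B)) {
        batch <- samples[start:min(length(samples), start + B - 1L)]
        b <- length(batch)
        xs <- lapply(batch, function(smp) {
          p <- prepared[[smp$s]]
          if (g$input_kind == "image") p$xnorm
          else extract_patch(p$xnorm, smp$i * g$stride - g$pad,
                             smp$j * g$stride - g$pad, g$patch_size)
        })
        fw <- net_forward(model$net, xs, train = TRUE)
        douts <- vector("list", b)
        bl <- numeric(b)
        for (k in seq_len(b)) {
          out <- fw$outs[[k]]
          pred <- matrix(out[, , 1], dim(out)[1], dim(out)[2])
          target <- if (g$input_kind == "image") prepared[[batch[[k]]$s]]$target
                    else prepared[[batch[[k]]$s]]$target[batch[[k]]$i + 1L,
                                                         batch[[k]]$j + 1L]
          lg <- loss_and_grad(pred, target, config$loss)
          bl[k] <- lg$loss
          douts[[k]] <- array(lg$d / b, dim(out))
        }
        bw <- net_backward(model$net, fw$caches, douts)
        sgd_step(model$net, bw$grads, lr, config$momentum,
                 config$weight_decay)
        losses <- c(losses, mean(bl))
      }
      train_loss <- mean(losses)

      val_mae <- NA_real_
      if (length(va) > 0) {
        errs <- vapply(va, function(s)
          abs(predict_count(model, prepared[[s]]$image) -
                prepared[[s]]$count), numeric(1))
        val_mae <- mean(errs)
      }
      crit <- if (is.na(val_mae)) train_loss else val_mae
      if (crit < best - 1e-9) {
        best <- crit; best_state <- net_state(model$net); since <- 0L
      } else {
        since <- since + 1L
        if (since >= config$patience) {
          lr <- lr * config$lr_factor
          since <- 0L
        }
      }
      hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                     train_loss = train_loss,
                                     val_mae = val_mae))
      if (config$verbose)
        message(sprintf("epoch %3d  lr %.4g  train_loss %.4f  val_mae %s",
                        epoch, lr, train_loss,
                        ifelse(is.na(val_mae), "NA", sprintf("%.3f", val_mae))))
    }
    if (!is.null(best_state)) model$net <- net_from_state(best_state)
    model$history <- hist
    model$config <- config
  })
  model
}

#' Save or load a model checkpoint
#'
#' The checkpoint archives weights, architecture description, normalization
#' means, geometry and training history in one file.
#'
#' @param model A `count_model`.
#' @param path File path (`.rds`).
#' @return `load_checkpoint()` returns the restored `count_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "count_model"))
  obj <- unclass(model)
  obj$net <- net_state(model$net)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  obj$net <- net_from_state(obj$net)
  structure(obj, class = "count_model")
}
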