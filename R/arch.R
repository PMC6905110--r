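#' Describe one layer of a sequential convolutional architecture
#'
#' A layer is either a convolution or a max-pooling stage. The description is
#' pure data: geometry ([receptive_field()], [output_shape()]), cost
#' ([count_mult_flops()], [count_parameters()]) and the runnable model
#' ([build_model()]) are all derived from it.
#'
#' @param name Layer name, e.g. `"conv1"`.
#' @param kind `"conv"` or `"maxpool"`.
#' @param kernel Kernel size, a single integer or `c(height, width)`.
#' @param stride Positive integer stride.
#' @param padding Non-negative symmetric zero padding per side.
#' @param in_channels,out_channels Channel counts (conv layers only).
#' @return A `layer_spec` object (named list).
#' @examples
#' layer_spec("conv1", "conv", kernel = 3, stride = 1, padding = 1,
#'            in_channels = 3, out_channels = 16)
#' @export
layer_spec <- function(name, kind = c("conv", "maxpool"), kernel, stride = 1L,
                       padding = 0L, in_channels = NULL, out_channels = NULL) {
  kind <- match.arg(kind)
  kernel <- as.integer(rep(kernel, length.out = 2L))
  stride <- as.integer(stride)
  padding <- as.integer(padding)
  if (any(kernel < 1L)) stop("kernel dims must be >= 1 in layer '", name, "'")
  if (stride < 1L) stop("stride must be >= 1 in layer '", name, "'")
  if (padding < 0L) stop("padding must be >= 0 in layer '", name, "'")
  if (kind == "conv") {
    if (is.null(in_channels) || is.null(out_channels))
      stop("conv layer '", name, "' needs in_channels and out_channels")
    in_channels <- as.integer(in_channels)
    out_channels <- as.integer(out_channels)
    if (in_channels < 1L || out_channels < 1L)
      stop("channel counts must be positive in layer '", name, "'")
  } else {
    in_channels <- out_channels <- NULL
  }
  structure(list(name = name, kind = kind, kernel = kernel, stride = stride,
                 padding = padding, in_channels = in_channels,
                 out_channels = out_channels),
            class = "layer_spec")
}

#' Assemble an ordered sequential network description
#'
#' @param layers List of [layer_spec()] objects, in forward order.
#' @param input_channels Number of input channels (3 for RGB).
#' @param name Optional network name.
#' @return A `network_spec` object.
#' @export
network_spec <- function(layers, input_channels = 3L, name = "network") {
  stopifnot(length(layers) >= 1L)
  ch <- as.integer(input_channels)
  for (ly in layers) {
    if (!inherits(ly, "layer_spec")) stop("all layers must be layer_spec objects")
    if (ly$kind == "conv") {
      if (ly$in_channels != ch)
        stop("layer '", ly$name, "' expects ", ly$in_channels,
             " input channels but receives ", ch)
      ch <- ly$out_channels
    }
  }
  structure(list(name = name, layers = layers,
                 input_channels = as.integer(input_channels),
                 output_channels = ch),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("network_spec '", x$name, "' (", length(x$layers), " layers, ",
      x$input_channels, " input channels)\n", sep = "")
  for (ly in x$layers) {
    cat(sprintf("  %-8s %-7s %dx%d /%d pad %d", ly$name, ly$kind,
                ly$kernel[1], ly$kernel[2], ly$stride, ly$padding))
    if (ly$kind == "conv")
      cat(sprintf("  %d -> %d", ly$in_channels, ly$out_channels))
    cat("\n")
  }
  invisible(x)
}

# Shared AlexNet-like backbone of the wheat-spike counting networks.
# `conv_padding` pads conv1..conv5 by 1 each (the padded, patch-based form
# and the fully convolutional form); the context variant strips all padding.
spike_backbone <- function(conv_padding, name) {
  p <- as.integer(conv_padding)
  network_spec(list(
    layer_spec("conv1", "conv", 3, 1, p, 3, 16),
    layer_spec("pool1", "maxpool", 2, 2),
    layer_spec("conv2", "conv", 3, 1, p, 16, 32),
    layer_spec("pool2", "maxpool", 2, 2),
    layer_spec("conv3", "conv", 3, 1, p, 32, 64),
    layer_spec("conv4", "conv", 3, 1, p, 64, 64),
    layer_spec("conv5", "conv", 3, 1, p, 64, 64),
    layer_spec("pool3", "maxpool", 2, 2),
    layer_spec("conv6", "conv", 8, 2, 0, 64, 128),
    layer_spec("conv7", "conv", 1, 1, 0, 128, 128),
    layer_spec("conv8", "conv", 1, 1, 0, 128, 1)
  ), input_channels = 3L, name = name)
}

#' Canonical counting-network architectures
#'
#' Three sequential AlexNet-like stacks share kernels and channels and differ
#' only in zero padding (hence in how much context each output unit sees):
#' `tasselnet` pads conv1-conv5 by 1 and maps a 64x64 patch to its count;
#' `tasselnet_ctx` strips all padding so the same stack maps a 94x94 patch
#' (the 64x64 window plus a 15-pixel context annulus) to the central count;
#' `tasselnetv2` keeps the per-layer padding and runs fully convolutionally,
#' its accumulated padding supplying the 15-pixel border context.
#'
#' Each output unit has a 94x94 receptive field, the output grid strides by
#' 16 input pixels (four stride-2 layers), and all three variants have the
#' same 638,000 convolution weights.
#'
#' @param variant One of `"tasselnet"`, `"tasselnet_ctx"`, `"tasselnetv2"`.
#' @return A [network_spec()].
#' @examples
#' geometry_totals(canonical_spec("tasselnetv2"))
#' @export
canonical_spec <- function(variant = c("tasselnetv2", "tasselnet", "tasselnet_ctx")) {
  variant <- match.arg(variant)
  switch(variant,
         tasselnet     = spike_backbone(1L, "tasselnet"),
         tasselnet_ctx = spike_backbone(0L, "tasselnet_ctx"),
         tasselnetv2   = spike_backbone(1L, "tasselnetv2"))
}

#' Receptive field, jump and accumulated padding of a sequential network
#'
#' Computes, per layer, the receptive field `r` (side of the input square
#' that can influence one unit), the jump `j` (spacing in input pixels
#' between adjacent units, the product of preceding strides) and the
#' accumulated zero padding `p` expressed in input pixels, via the standard
#' recursions \eqn{r_l = r_{l-1} + (k_l - 1) j_{l-1}},
#' \eqn{j_l = j_{l-1} s_l}, \eqn{p_l = p_{l-1} + pad_l j_{l-1}},
#' with \eqn{r_0 = j_0 = 1, p_0 = 0}.
#'
#' @param spec A [network_spec()].
#' @return A `geometry_report`: data frame of per-layer values plus a
#'   `totals` attribute `list(rf, stride, padding)`.
#' @examples
#' rf <- receptive_field(canonical_spec("tasselnetv2"))
#' attr(rf, "totals")  # rf 94, stride 16, padding 15
#' @export
receptive_field <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  n <- length(spec$layers)
  r <- j <- p <- numeric(n)
  r_prev <- 1; j_prev <- 1; p_prev <- 0
  for (l in seq_len(n)) {
    ly <- spec$layers[[l]]
    k <- max(ly$kernel)
    r[l] <- r_prev + (k - 1) * j_prev
    p[l] <- p_prev + ly$padding * j_prev
    j[l] <- j_prev * ly$stride
    r_prev <- r[l]; j_prev <- j[l]; p_prev <- p[l]
  }
  out <- data.frame(layer = vapply(spec$layers, `[[`, "", "name"),
                    receptive_field = r, jump = j, accumulated_padding = p)
  attr(out, "totals") <- list(rf = r[n], stride = j[n], padding = p[n])
  class(out) <- c("geometry_report", "data.frame")
  out
}

#' Total receptive field, stride and padding of a network
#'
#' @param spec A [network_spec()].
#' @return `list(rf, stride, padding)` in input pixels.
#' @export
geometry_totals <- function(spec) attr(receptive_field(spec), "totals")

#' Spatial output shape of a sequential network
#'
#' Applies the floor arithmetic `floor((n + 2 pad - k) / stride) + 1` layer
#' by layer.
#'
#' @param spec A [network_spec()].
#' @param input_hw Input size `c(height, width)` in pixels.
#' @param per_layer If `TRUE`, return the shape after every layer.
#' @return `c(height, width)` of the final feature map, or a matrix of
#'   per-layer shapes.
#' @examples
#' output_shape(canonical_spec("tasselnetv2"), c(912, 1216))  # 54 x 73
#' @export
output_shape <- function(spec, input_hw, per_layer = FALSE) {
  stopifnot(inherits(spec, "network_spec"), length(input_hw) == 2L)
  hw <- as.integer(input_hw)
  shapes <- matrix(NA_integer_, length(spec$layers), 2L,
                   dimnames = list(vapply(spec$layers, `[[`, "", "name"),
                                   c("height", "width")))
  for (l in seq_along(spec$layers)) {
    ly <- spec$layers[[l]]
    hw <- (hw + 2L * ly$padding - ly$kernel) %/% ly$stride + 1L
    if (any(hw < 1L))
      stop("input too small: layer '", ly$name, "' would output ",
           hw[1], "x", hw[2])
    shapes[l, ] <- hw
  }
  if (per_layer) shapes else hw
}

#' Count single-precision multiplications of a forward pass
#'
#' Each convolutional layer contributes
#' `k_h * k_w * C_in * C_out * H_out * W_out` multiplications; pooling,
#' bias additions, batch normalization and activations contribute none.
#' All arithmetic is exact (doubles hold these integers exactly).
#'
#' @param spec A [network_spec()].
#' @param input_hw Input size `c(height, width)`.
#' @param n_patches Multiplier for patch-based accounting: the per-input cost
#'   is multiplied by this number of patches (default 1, whole-image mode).
#' @return A `cost_report` data frame (layer, multiplications) with a
#'   `total` attribute.
#' @examples
#' fl <- count_mult_flops(canonical_spec("tasselnetv2"), c(912, 1216))
#' signif(attr(fl, "total"), 3)  # 1.03e10
#' @export
count_mult_flops <- function(spec, input_hw, n_patches = 1) {
  shapes <- output_shape(spec, input_hw, per_layer = TRUE)
  mults <- numeric(length(spec$layers))
  for (l in seq_along(spec$layers)) {
    ly <- spec$layers[[l]]
    if (ly$kind == "conv")
      mults[l] <- prod(ly$kernel) * ly$in_channels * ly$out_channels *
        shapes[l, 1] * shapes[l, 2] * n_patches
  }
  out <- data.frame(layer = rownames(shapes), multiplications = mults)
  attr(out, "total") <- sum(mults)
  class(out) <- c("cost_report", "data.frame")
  out
}

#' Count learnable convolution weights
#'
#' Sums `k_h * k_w * C_in * C_out` over conv layers. Biases and batch-norm
#' parameters are excluded from this headline figure (the convention under
#' which the canonical networks have 638,000 parameters); see
#' [count_model_parameters()] for the full runtime count.
#'
#' @param spec A [network_spec()].
#' @return Integer-valued scalar.
#' @examples
#' count_parameters(canonical_spec("tasselnetv2"))  # 638000
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  sum(vapply(spec$layers, function(ly) {
    if (ly$kind == "conv") prod(ly$kernel) * ly$in_channels * ly$out_channels
    else 0
  }, numeric(1)))
}

#' Strip all zero padding from a network description
#'
#' Padding affects coverage geometry, not capacity: the stripped variant has
#' the same parameter count and the same receptive-field size.
#'
#' @param spec A [network_spec()].
#' @return A [network_spec()] with every `padding` set to 0.
#' @export
strip_padding <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  spec$layers <- lapply(spec$layers, function(ly) { ly$padding <- 0L; ly })
  spec$name <- paste0(spec$name, "_nopad")
  spec
}

#' Read or write a network description as YAML
#'
#' One document per network: `name`, `input_channels` and a `layers` list
#' whose fields are exactly those of [layer_spec()].
#'
#' @param spec A [network_spec()].
#' @param path File path.
#' @return `read_network_spec()` returns a [network_spec()];
#'   `write_network_spec()` returns `path` invisibly.
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  doc <- list(name = spec$name, input_channels = spec$input_channels,
              layers = lapply(spec$layers, function(ly) {
                out <- list(name = ly$name, kind = ly$kind,
                            kernel = as.integer(ly$kernel),
                            stride = ly$stride, padding = ly$padding)
                if (ly$kind == "conv") {
                  out$in_channels <- ly$in_channels
                  out$out_channels <- ly$out_channels
                }
                out
              }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  layers <- lapply(doc$layers, function(ly)
    layer_spec(ly$name, ly$kind, ly$kernel, ly$stride, ly$padding,
               ly$in_channels, ly$out_channels))
  network_spec(layers, input_channels = doc$input_channels, name = doc$name)
}

#' Analyze an architecture: geometry and cost in one report
#'
#' @param spec A [network_spec()].
#' @param input_hw Input size `c(height, width)`.
#' @return Invisibly, `list(geometry, totals, flops, flops_total, parameters)`;
#'   prints an aligned text report.
#' @export
analyze_network <- function(spec, input_hw = c(912L, 1216L)) {
  geo <- receptive_field(spec)
  tot <- attr(geo, "totals")
  fl <- count_mult_flops(spec, input_hw)
  shapes <- output_shape(spec, input_hw, per_layer = TRUE)
  cat("Architecture:", spec$name, " input", input_hw[1], "x", input_hw[2], "\n")
  cat(sprintf("%-8s %5s %5s %4s %12s %14s\n",
              "layer", "rf", "jump", "pad", "out HxW", "mults"))
  for (l in seq_len(nrow(geo)))
    cat(sprintf("%-8s %5d %5d %4d %7dx%-5d %14s\n", geo$layer[l],
                geo$receptive_field[l], geo$jump[l], geo$accumulated_padding[l],
                shapes[l, 1], shapes[l, 2],
                format(signif(fl$multiplications[l], 3), scientific = TRUE)))
  cat(sprintf("totals: rf %d, stride %d, padding %d, mults %s, weights %d\n",
              tot$rf, tot$stride, tot$padding,
              format(signif(attr(fl, "total"), 3), scientific = TRUE),
              count_parameters(spec)))
  invisible(list(geometry = geo, totals = tot, flops = fl,
                 flops_total = attr(fl, "total"),
                 parameters = count_parameters(spec)))
}
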