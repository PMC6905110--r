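#' Dot annotations: one point per object instance
#'
#' Coordinates are 0-based pixel-center coordinates, `x` = column, `y` = row,
#' sub-pixel values allowed; every point must lie in `[0, W) x [0, H)`.
#'
#' @param points Data frame or matrix with columns `x`, `y` (may have 0 rows).
#' @param image_hw Image size `c(height, width)` in pixels.
#' @return A `dot_annotation` object.
#' @export
dot_annotation <- function(points, image_hw) {
  stopifnot(length(image_hw) == 2L)
  hw <- as.integer(image_hw)
  if (is.null(points) || NROW(points) == 0L) {
    pts <- data.frame(x = numeric(0), y = numeric(0))
  } else {
    points <- as.data.frame(points)
    stopifnot(all(c("x", "y") %in% names(points)))
    pts <- data.frame(x = as.numeric(points$x), y = as.numeric(points$y))
    bad <- pts$x < 0 | pts$x >= hw[2] | pts$y < 0 | pts$y >= hw[1]
    if (any(bad))
      stop(sum(bad), " dot(s) outside the ", hw[1], "x", hw[2], " image")
  }
  structure(list(points = pts, image_hw = hw), class = "dot_annotation")
}

#' Gaussian density map from dot annotations
#'
#' Places one isotropic Gaussian kernel of bandwidth `sigma` at each dot,
#' truncated at `truncate * sigma`, and renormalizes every kernel to unit
#' mass after truncation and border clipping, so that the map's integral
#' equals the dot count regardless of how close dots sit to the border.
#' This makes the downstream local-count targets insensitive to the exact
#' kernel choice at image edges.
#'
#' @param dots A [dot_annotation()].
#' @param sigma Gaussian bandwidth in pixels (default 4, the configuration
#'   tuned for wheat-spike imagery).
#' @param truncate Kernel support radius in units of `sigma`.
#' @return A `density_map`: `list(values = H x W matrix, sigma)`.
#' @examples
#' d <- density_from_dots(dot_annotation(data.frame(x = 32, y = 32), c(64, 64)))
#' abs(sum(d$values) - 1) < 1e-3
#' @export
density_from_dots <- function(dots, sigma = 4, truncate = 4) {
  stopifnot(inherits(dots, "dot_annotation"), sigma > 0)
  H <- dots$image_hw[1]; W <- dots$image_hw[2]
  values <- matrix(0, H, W)
  r <- ceiling(truncate * sigma)
  for (i in seq_len(nrow(dots$points))) {
    x0 <- dots$points$x[i]; y0 <- dots$points$y[i]
    ys <- max(0L, floor(y0 - r)):min(H - 1L, ceiling(y0 + r))
    xs <- max(0L, floor(x0 - r)):min(W - 1L, ceiling(x0 + r))
    ky <- exp(-((ys - y0)^2) / (2 * sigma^2))
    kx <- exp(-((xs - x0)^2) / (2 * sigma^2))
    kern <- outer(ky, kx)
    kern <- kern / sum(kern)                 # unit mass after clipping
    values[ys + 1L, xs + 1L] <- values[ys + 1L, xs + 1L] + kern
  }
  structure(list(values = values, sigma = sigma), class = "density_map")
}

# Summed-area table with a leading zero row/column: sat[r+1, c+1] holds the
# sum over 0-based rows < r, cols < c, so a half-open window [i1,i2)x[j1,j2)
# integrates as sat[i2+1,j2+1] - sat[i1+1,j2+1] - sat[i2+1,j1+1] + sat[i1+1,j1+1].
summed_area_table <- function(m) {
  H <- nrow(m); W <- ncol(m)
  cs <- if (H > 1L) apply(m, 2L, cumsum) else m
  cs <- matrix(cs, H, W)
  for (j in seq_len(W)[-1L]) cs[, j] <- cs[, j] + cs[, j - 1L]
  sat <- matrix(0, H + 1L, W + 1L)
  sat[-1L, -1L] <- cs
  sat
}

# integral of m over half-open pixel window rows [a, a+h) x cols [b, b+w),
# 0-based, clipped to the matrix; exact via the summed-area table
window_sums <- function(sat, a, b, h, w, H, W) {
  i1 <- pmax(a, 0L); i2 <- pmin(a + h, H)
  j1 <- pmax(b, 0L); j2 <- pmin(b + w, W)
  ok <- i2 > i1 & j2 > j1
  out <- numeric(length(a))
  if (any(ok))
    out[ok] <- sat[cbind(i2[ok] + 1L, j2[ok] + 1L)] -
      sat[cbind(i1[ok] + 1L, j2[ok] + 1L)] -
      sat[cbind(i2[ok] + 1L, j1[ok] + 1L)] + sat[cbind(i1[ok] + 1L, j1[ok] + 1L)]
  out
}

#' Window-integrated local-count regression targets
#'
#' Integrates a density map over a sliding window to produce the grid of
#' local counts that the networks regress. The grid is laid out on the
#' zero-padded canvas used by the fully convolutional network, so target
#' grid and network output grid align cell for cell: output cell `(i, j)`
#' (0-based) covers the half-open window
#' `[stride*i + off, stride*i + off + window)` in original image rows (and
#' likewise columns), where `off = context - pad`. With the canonical
#' geometry (window 64, context 15, pad 15) the windows tile the image
#' exactly from its top-left corner.
#'
#' @param density A [density_map][density_from_dots()].
#' @param window Window side in pixels (64 for the central-window target,
#'   94 for the full receptive field).
#' @param stride Grid stride in pixels (16).
#' @param pad Zero padding per border applied to the canvas (15).
#' @param context Context annulus width per side: the receptive field is
#'   `window + 2 * context`.
#' @return A `local_count_map`: `list(values = grid matrix, window, stride,
#'   pad, context, origin_offset, image_hw)`.
#' @examples
#' dots <- dot_annotation(data.frame(x = 100, y = 80), c(192, 192))
#' lc <- local_counts(density_from_dots(dots))
#' sum(lc$values)  # (64/16)^2 = 16 windows cover an interior dot
#' @export
local_counts <- function(density, window = 64L, stride = 16L, pad = 15L,
                         context = (94L - window) %/% 2L) {
  stopifnot(inherits(density, "density_map"), pad >= 0L, stride >= 1L)
  H <- nrow(density$values); W <- ncol(density$values)
  rf <- window + 2L * context
  n_h <- (H + 2L * pad - rf) %/% stride + 1L
  n_w <- (W + 2L * pad - rf) %/% stride + 1L
  if (n_h < 1L || n_w < 1L)
    stop("image ", H, "x", W, " too small for window ", window,
         " with context ", context, " at pad ", pad)
  off <- context - pad
  sat <- summed_area_table(density$values)
  idx <- expand.grid(i = 0:(n_h - 1L), j = 0:(n_w - 1L))
  v <- window_sums(sat, idx$i * stride + off, idx$j * stride + off,
                   window, window, H, W)
  v[v < 0] <- 0   # summed-area cancellation can leave -1e-18 residues
  structure(list(values = matrix(v, n_h, n_w), window = as.integer(window),
                 stride = as.integer(stride), pad = as.integer(pad),
                 context = as.integer(context),
                 origin_offset = as.integer(off), image_hw = c(H, W)),
            class = "local_count_map")
}

#' Check that a target grid matches a network's output geometry
#'
#' @param lcm A [local_counts()] grid.
#' @param spec A [network_spec()].
#' @return Invisibly `TRUE`; errors naming both shapes on mismatch.
#' @export
check_target_geometry <- function(lcm, spec) {
  stopifnot(inherits(lcm, "local_count_map"))
  expect <- output_shape(spec, lcm$image_hw)
  got <- dim(lcm$values)
  if (!all(got == expect))
    stop("target grid ", got[1], "x", got[2], " does not match network output ",
         expect[1], "x", expect[2], " for a ", lcm$image_hw[1], "x",
         lcm$image_hw[2], " image")
  invisible(TRUE)
}
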