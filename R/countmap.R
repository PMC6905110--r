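#' Grid of raw local-count predictions
#'
#' One value per output cell of the network; cell `(i, j)` (0-based) covers
#' the half-open window `[stride*i + off, stride*i + off + window)` on the
#' image canvas, with `off = context - pad` (0 for the canonical geometry).
#'
#' @param values Numeric matrix of local counts (non-negative after the
#'   inference clamp).
#' @param image_hw Original image size `c(height, width)`.
#' @param window,stride,pad,context Window geometry in pixels.
#' @return A `raw_count_grid` object.
#' @export
raw_count_grid <- function(values, image_hw, window = 64L, stride = 16L,
                           pad = 15L, context = (94L - window) %/% 2L) {
  stopifnot(is.matrix(values), length(image_hw) == 2L)
  hw <- as.integer(image_hw)
  rf <- window + 2L * context
  n_h <- (hw[1] + 2L * pad - rf) %/% stride + 1L
  n_w <- (hw[2] + 2L * pad - rf) %/% stride + 1L
  if (nrow(values) != n_h || ncol(values) != n_w)
    abort_geometry("grid ", nrow(values), "x", ncol(values),
                   " inconsistent with expected ", n_h, "x", n_w,
                   " for a ", hw[1], "x", hw[2], " image")
  structure(list(values = values, image_hw = hw, window = as.integer(window),
                 stride = as.integer(stride), pad = as.integer(pad),
                 context = as.integer(context),
                 origin_offset = as.integer(context - pad)),
            class = "raw_count_grid")
}

#' Merge overlapping local counts into a normalized count map
#'
#' Each local count `c` is redistributed uniformly over its window footprint
#' (`c / window^2` per covered pixel, windows clipped to the image canvas),
#' the contributions are accumulated, and every pixel is divided by its
#' coverage multiplicity — the number of windows covering it, computed after
#' clipping so border pixels are not under-weighted. In the interior the
#' multiplicity is `(window / stride)^2` (16 for the canonical geometry),
#' and the integral of the resulting map is the image count estimate.
#'
#' @param grid A [raw_count_grid()].
#' @return A `normalized_count_map`: `list(values = H x W matrix, coverage)`.
#' @examples
#' g <- raw_count_grid(matrix(7, 1, 1), c(64, 64), window = 64, stride = 16,
#'                     pad = 0, context = 0)
#' image_count(merge_normalize(g))  # 7: single window, normalization is identity
#' @export
merge_normalize <- function(grid) {
  stopifnot(inherits(grid, "raw_count_grid"))
  H <- grid$image_hw[1]; W <- grid$image_hw[2]
  w <- grid$window; s <- grid$stride; off <- grid$origin_offset
  acc <- matrix(0, H, W)
  cov <- matrix(0L, H, W)
  share <- grid$values / w^2
  for (j in seq_len(ncol(grid$values))) {
    b <- (j - 1L) * s + off
    c0 <- max(0L, b); c1 <- min(W, b + w)
    if (c1 <= c0) next
    for (i in seq_len(nrow(grid$values))) {
      a <- (i - 1L) * s + off
      r0 <- max(0L, a); r1 <- min(H, a + w)
      if (r1 <= r0) next
      rows <- (r0 + 1L):r1; cols <- (c0 + 1L):c1
      acc[rows, cols] <- acc[rows, cols] + share[i, j]
      cov[rows, cols] <- cov[rows, cols] + 1L
    }
  }
  if (any(cov == 0L))
    stop("internal error: ", sum(cov == 0L), " pixels covered by no window")
  structure(list(values = acc / cov, coverage = cov, image_hw = grid$image_hw),
            class = "normalized_count_map")
}

#' Integrate a count map to the image-level count
#'
#' @param map A [merge_normalize()] `normalized_count_map` (or a
#'   `density_map`).
#' @return Sum of all pixel values.
#' @export
image_count <- function(map) {
  stopifnot(inherits(map, "normalized_count_map") || inherits(map, "density_map"))
  sum(map$values)
}

#' Write a count map as a false-color PNG overlay
#'
#' @param map A `normalized_count_map`.
#' @param path Output PNG path.
#' @param image Optional `H x W x 3` background image to blend with.
#' @param alpha Overlay opacity in `[0, 1]`.
#' @return `path`, invisibly.
#' @export
write_countmap_png <- function(map, path, image = NULL, alpha = 0.6) {
  stopifnot(inherits(map, "normalized_count_map"))
  v <- map$values
  v <- v / max(v, 1e-12)
  # simple blue -> yellow -> red heat ramp
  heat <- array(0, c(nrow(v), ncol(v), 3L))
  heat[, , 1] <- pmin(1, 2 * v)
  heat[, , 2] <- pmin(1, 2 * pmin(v, 1 - v))
  heat[, , 3] <- pmax(0, 1 - 2 * v)
  out <- if (is.null(image)) heat
         else (1 - alpha) * check_image_array(image) + alpha * heat
  png::writePNG(pmin(pmax(out, 0), 1), path)
  invisible(path)
}
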