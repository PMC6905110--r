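#' Configuration of the synthetic field-scene generator
#'
#' Scenes emulate the statistical structure of in-field wheat-spike imagery:
#' dense, mutually occluding elongated objects with size, pose, blur and
#' illumination variation over a low-frequency canopy background, placed by
#' a Thomas-style cluster process that mimics row planting. The defaults
#' match the source imagery's sub-image resolution (912 x 1216) and
#' per-image count range (0-1462).
#'
#' @param image_hw Canvas size `c(height, width)` in pixels.
#' @param count_range `c(min, max)` objects per image; each scene's count is
#'   drawn uniformly from this range.
#' @param object_length Object (spike) length range in pixels.
#' @param aspect Length/width aspect-ratio range.
#' @param parent_intensity Cluster-parent intensity (parents per pixel).
#' @param cluster_sd Gaussian spread of offspring around parents, pixels.
#' @param gain_range,gamma_range Global illumination jitter ranges.
#' @param blur_range Gaussian blur sigma range in pixels.
#' @param noise_sd Per-pixel sensor noise standard deviation.
#' @param jitter Master switch: `FALSE` disables illumination/blur/noise
#'   jitter, yielding clean separable renderings (sanity-ceiling scenes).
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_hw = c(912L, 1216L), count_range = c(0L, 1462L),
                         object_length = c(15, 60), aspect = c(2, 5),
                         parent_intensity = 4e-05, cluster_sd = 40,
                         gain_range = c(0.8, 1.25), gamma_range = c(0.8, 1.25),
                         blur_range = c(0, 3), noise_sd = 0.01,
                         jitter = TRUE) {
  stopifnot(length(image_hw) == 2L, count_range[1] >= 0,
            count_range[2] >= count_range[1])
  structure(list(image_hw = as.integer(image_hw),
                 count_range = as.integer(count_range),
                 object_length = object_length, aspect = aspect,
                 parent_intensity = parent_intensity, cluster_sd = cluster_sd,
                 gain_range = gain_range, gamma_range = gamma_range,
                 blur_range = blur_range, noise_sd = noise_sd,
                 jitter = isTRUE(jitter)),
            class = "scene_config")
}

#' Generate one synthetic field scene
#'
#' Objects are rendered back-to-front with alpha compositing: each is an
#' elongated Gaussian-profile ellipse (random length, aspect and
#' orientation) whose centroid is the ground-truth dot. Centers come from a
#' Thomas-style cluster process (Poisson parents, Gaussian offspring), so
#' objects overlap and occlude each other as in dense canopies. Global
#' gain/gamma jitter, Gaussian blur and sensor noise are applied when
#' `config$jitter` is on. Identical `config` + `seed` give bitwise-identical
#' scenes.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @return A `scene`: `list(image = H x W x 3 array in [0, 1],
#'   dots = data.frame(x, y), config, seed, count)`.
#' @examples
#' sc <- generate_scene(scene_config(image_hw = c(128, 128),
#'                                   count_range = c(5, 5)), seed = 1)
#' nrow(sc$dots)  # 5
#' @export
generate_scene <- function(config, seed = 1L) {
  stopifnot(inherits(config, "scene_config"))
  H <- config$image_hw[1]; W <- config$image_hw[2]
  if (H < 8L || W < 8L) abort_validation("canvas too small")
  withr::with_seed(as.integer(seed), {
    # low-frequency canopy background around a green-brown field tone
    base <- c(0.30, 0.33, 0.18)
    img <- array(0, c(H, W, 3L))
    h0 <- max(2L, ceiling(H / 32)); w0 <- max(2L, ceiling(W / 32))
    for (ch in 1:3) {
      coarse <- matrix(base[ch] + rnorm(h0 * w0, sd = 0.05), h0, w0)
      img[, , ch] <- resize_bilinear(coarse, H, W)
    }

    n <- config$count_range[1]
    if (config$count_range[2] > config$count_range[1])
      n <- config$count_range[1] +
        sample.int(config$count_range[2] - config$count_range[1] + 1L, 1L) - 1L

    dots <- data.frame(x = numeric(0), y = numeric(0))
    if (n > 0) {
      area <- H * W
      n_par <- max(1L, rpois(1L, config$parent_intensity * area))
      px <- runif(n_par, 0, W - 1e-6); py <- runif(n_par, 0, H - 1e-6)
      pk <- sample.int(n_par, n, replace = TRUE)
      x <- pmin(pmax(px[pk] + rnorm(n, sd = config$cluster_sd), 0), W - 1e-3)
      y <- pmin(pmax(py[pk] + rnorm(n, sd = config$cluster_sd), 0), H - 1e-3)
      dots <- data.frame(x = x, y = y)

      for (k in seq_len(n)) {
        len <- runif(1, config$object_length[1], config$object_length[2])
        asp <- runif(1, config$aspect[1], config$aspect[2])
        wid <- len / asp
        theta <- runif(1, 0, pi)
        col <- pmin(pmax(c(0.74, 0.64, 0.34) + rnorm(3, sd = 0.06), 0), 1)
        amax <- runif(1, 0.7, 1)
        r <- ceiling(len / 2)
        ys <- max(0L, floor(y[k] - r)):min(H - 1L, ceiling(y[k] + r))
        xs <- max(0L, floor(x[k] - r)):min(W - 1L, ceiling(x[k] + r))
        dy <- ys - y[k]; dx <- xs - x[k]
        # rotated elliptical coordinates; profile sigma = semi-axis / 2
        u <- outer(dy, dx, function(a, b) a * sin(theta) + b * cos(theta))
        v <- outer(dy, dx, function(a, b) a * cos(theta) - b * sin(theta))
        r2 <- (u / (len / 4))^2 + (v / (wid / 4))^2
        alpha <- amax * exp(-0.5 * r2)
        alpha[r2 > 4] <- 0
        ri <- ys + 1L; ci <- xs + 1L
        for (ch in 1:3)
          img[ri, ci, ch] <- (1 - alpha) * img[ri, ci, ch] + alpha * col[ch]
      }
    }

    if (config$jitter) {
      gain <- runif(1, config$gain_range[1], config$gain_range[2])
      gam <- runif(1, config$gamma_range[1], config$gamma_range[2])
      img <- pmin(pmax(img * gain, 0), 1)^gam
      bsig <- runif(1, config$blur_range[1], config$blur_range[2])
      if (bsig > 0.2) img <- gaussian_blur(img, bsig)
      if (config$noise_sd > 0)
        img <- img + array(rnorm(length(img), sd = config$noise_sd), dim(img))
    }
    img <- pmin(pmax(img, 0), 1)

    structure(list(image = img, dots = dots, config = config,
                   seed = as.integer(seed), count = n),
              class = "scene")
  })
}

resize_bilinear <- function(m, H, W) {
  ys <- seq(1, nrow(m), length.out = H)
  xs <- seq(1, ncol(m), length.out = W)
  y0 <- pmin(floor(ys), nrow(m) - 1L); fy <- ys - y0
  x0 <- pmin(floor(xs), ncol(m) - 1L); fx <- xs - x0
  top <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    m[y0, x0 + 1L, drop = FALSE] * outer(1 - fy, fx)
  bot <- m[y0 + 1L, x0, drop = FALSE] * outer(fy, 1 - fx) +
    m[y0 + 1L, x0 + 1L, drop = FALSE] * outer(fy, fx)
  top + bot
}

gaussian_blur <- function(img, sigma) {
  out <- EBImage::gblur(img, sigma = sigma)
  array(as.numeric(out), dim(img))
}

#' Write a seeded synthetic dataset to disk
#'
#' Produces one PNG and one dot-annotation CSV per scene plus a JSON
#' manifest recording the configuration and per-scene seeds, so dataset
#' statistics are recoverable and every scene can be regenerated exactly.
#'
#' @param config A [scene_config()].
#' @param n_train,n_val,n_test Scenes per split.
#' @param seed Master seed; per-scene seeds are derived from it.
#' @param dir Output directory.
#' @param overwrite Refuse to write into an existing non-empty directory
#'   unless `TRUE`.
#' @return The manifest, invisibly.
#' @export
generate_dataset <- function(config, n_train, n_val, n_test, seed, dir,
                             overwrite = FALSE) {
  stopifnot(inherits(config, "scene_config"),
            n_train >= 1, n_val >= 0, n_test >= 1)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    abort_validation("output directory '", dir,
                     "' exists and is not empty; pass overwrite = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ns <- c(train = n_train, val = n_val, test = n_test)
  total <- sum(ns)
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L, total))
  splits <- rep(names(ns), ns)
  entries <- vector("list", total)
  for (i in seq_len(total)) {
    sc <- generate_scene(config, seed = seeds[i])
    stem <- sprintf("%s_%03d", splits[i], i)
    png::writePNG(sc$image, file.path(dir, paste0(stem, ".png")))
    write_dots_csv(sc$dots, paste0(stem, ".png"),
                   file.path(dir, paste0(stem, ".csv")))
    entries[[i]] <- list(image = paste0(stem, ".png"),
                         annotations = paste0(stem, ".csv"),
                         split = splits[i], seed = seeds[i], count = sc$count)
  }
  manifest <- list(config = unclass(config), seed = as.integer(seed),
                   scenes = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @param split Optional split filter (`"train"`, `"val"`, `"test"`).
#' @return List of scenes (`image`, `dots`, `count`, `split`).
#' @export
load_dataset <- function(dir, split = NULL) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = FALSE)
  scenes <- lapply(mf$scenes, function(e) {
    if (!is.null(split) && e$split != split) return(NULL)
    img <- png::readPNG(file.path(dir, e$image))
    dots <- read_dots_csv(file.path(dir, e$annotations))
    list(image = img, dots = dots, count = e$count, split = e$split)
  })
  scenes[!vapply(scenes, is.null, logical(1))]
}
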