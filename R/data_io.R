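# Annotation and result file formats.
#
# Dot annotations travel either as CSV with header image,x,y (one row per
# dot) or as JSON {"image": ..., "points": [[x, y], ...]}. Coordinates are
# 0-based pixel centers, x = column, y = row.

#' Read and write dot annotations
#'
#' @param dots Data frame with columns `x`, `y`.
#' @param image Image file name recorded alongside the dots.
#' @param path CSV or JSON file path.
#' @return Readers return a data frame with columns `x`, `y` (attribute
#'   `image` carries the recorded image name).
#' @export
write_dots_csv <- function(dots, image, path) {
  df <- data.frame(image = rep(image, NROW(dots)),
                   x = as.numeric(dots$x), y = as.numeric(dots$y))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dots_csv
#' @export
read_dots_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("x", "y") %in% names(df)))
  out <- data.frame(x = as.numeric(df$x), y = as.numeric(df$y))
  if ("image" %in% names(df) && nrow(df) > 0)
    attr(out, "image") <- df$image[1]
  out
}

#' @rdname write_dots_csv
#' @export
write_dots_json <- function(dots, image, path) {
  pts <- unname(lapply(seq_len(NROW(dots)),
                       function(i) c(dots$x[i], dots$y[i])))
  jsonlite::write_json(list(image = image, points = pts), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dots_csv
#' @export
read_dots_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- obj$points
  out <- if (length(pts) == 0) data.frame(x = numeric(0), y = numeric(0))
         else data.frame(x = as.numeric(pts[, 1]), y = as.numeric(pts[, 2]))
  attr(out, "image") <- obj$image
  out
}

#' Persist a density map or local-count grid with its metadata
#'
#' Values go to a plain-text matrix file (one row per line, space separated)
#' with a JSON sidecar holding window/stride/pad metadata.
#'
#' @param x A `density_map` or `local_count_map`.
#' @param path Output path for the values; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_grid <- function(x, path) {
  v <- x$values
  write.table(v, path, row.names = FALSE, col.names = FALSE)
  meta <- x[setdiff(names(x), "values")]
  meta$class <- class(x)[1]
  meta$dim <- dim(v)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- as.matrix(read.table(path))
  dimnames(v) <- NULL
  cls <- meta$class
  meta$class <- NULL; meta$dim <- NULL
  structure(c(list(values = v), meta), class = cls)
}

#' Write per-image predicted counts as CSV
#'
#' @param counts Data frame with columns `image`, `count`.
#' @param path Output CSV.
#' @export
write_counts_csv <- function(counts, path) {
  write.csv(counts, path, row.names = FALSE)
  invisible(path)
}
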