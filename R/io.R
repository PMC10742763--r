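# Reading/writing the package's external formats: 8-bit grayscale PNG for
# images and masks, JSON for contours and offset fields, CSV for manifests.

#' Write an image matrix as 8-bit grayscale PNG
#' @param img matrix with values in 0..255 (or 0/1 for masks).
#' @param path output path.
#' @export
write_image_png <- function(img, path) {
  v <- img
  if (max(v) <= 1) v <- v * 255
  png::writePNG(pmin(pmax(v / 255, 0), 1), path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG as a matrix in 0..255
#' @param path PNG path.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  round(a * 255)
}

#' Write a contour to JSON
#'
#' Format: `{"points": [[x, y], ...], "closed": true}`, coordinates 0-based.
#' @param contour n x 2 matrix (x, y).
#' @param path output path.
#' @export
write_contour_json <- function(contour, path) {
  jsonlite::write_json(list(points = unname(as.matrix(contour)), closed = TRUE),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a contour from JSON
#' @param path JSON path written by [write_contour_json()].
#' @return n x 2 matrix (x, y).
#' @export
read_contour_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as.matrix(obj$points)
  colnames(m) <- c("x", "y")
  m
}

#' Write a phantom's artifacts (image, mask, contour) to a directory
#' @param phantom a [make_phantom()] result.
#' @param dir output directory (created if missing).
#' @param id file-name stem.
#' @return Named character vector of the written paths.
#' @export
write_phantom <- function(phantom, dir, id) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- c(image = file.path(dir, paste0(id, ".png")),
         mask = file.path(dir, paste0(id, "_mask.png")),
         contour = file.path(dir, paste0(id, "_contour.json")))
  write_image_png(phantom$image, p[["image"]])
  write_image_png(phantom$gt_mask * 255, p[["mask"]])
  write_contour_json(phantom$gt_contour, p[["contour"]])
  p
}

#' Read a JSON/YAML configuration file into nested lists
#'
#' Sections (`preprocessing`, `offsets`, `env`, `rewards`, `aggregation`,
#' `ppo`, `curriculum`, `pipeline`) override the corresponding config
#' constructors' defaults.
#' @param path `.json` or `.yaml`/`.yml` file.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
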