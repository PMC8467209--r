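#' Spherical raster container
#'
#' A `spherical_raster` is a pixel grid tagged with its spherical geometry.
#' Two geometries are supported: `"equirectangular"` (longitude and latitude
#' linear in pixel coordinates, 2:1 aspect, every pixel valid) and `"hammer"`
#' (the Hammer equal-area ellipse inscribed in a 2:1 bounding box, with a
#' validity mask marking pixels whose centers invert to a sphere point).
#' The grid carries either RGB values (`kind = "rgb"`, an height x width x 3
#' array of channel values 0-255) or categorical labels (`kind = "label"`,
#' an integer matrix, optionally with a `categories` attribute naming the
#' integer codes).
#'
#' Pixel-center convention: column `k` (1-based) of an equirectangular
#' raster of width `W` has longitude `-pi + (k - 0.5) * 2*pi / W`; row 1 is
#' the top of the image and has latitude near `+pi/2` (sky up), i.e. row `r`
#' of height `H` has latitude `pi/2 - (r - 0.5) * pi / H`.
#'
#' Geometry `"planar"` carries no projection semantics (any shape, all
#' pixels valid unless masked); the area-ratio metrics are geometry
#' agnostic and accept it, the projection operations do not.
#'
#' @param values numeric/integer matrix (labels) or 3-slice array (RGB)
#' @param geometry `"equirectangular"`, `"hammer"` or `"planar"`
#' @param mask logical matrix of valid pixels; defaults to all-valid for
#'   equirectangular geometry and to the ellipse interior for hammer
#' @param categories optional character vector naming integer label codes
#'   `1..length(categories)`
#' @return an object of class `spherical_raster`
#' @export
spherical_raster <- function(values,
                             geometry = c("equirectangular", "hammer",
                                          "planar"),
                             mask = NULL, categories = NULL) {
  geometry <- match.arg(geometry)
  if (is.matrix(values)) {
    kind <- "label"
    if (!is.integer(values)) {
      if (any(values[is.finite(values)] %% 1 != 0))
        stop("label raster values must be whole numbers")
      storage.mode(values) <- "integer"
    }
    h <- nrow(values); w <- ncol(values)
  } else if (is.array(values) && length(dim(values)) == 3L &&
             dim(values)[3] == 3L) {
    kind <- "rgb"
    h <- dim(values)[1]; w <- dim(values)[2]
    if (min(values) < 0 || max(values) > 255)
      stop("RGB channel values must lie in [0, 255]")
  } else {
    stop("values must be a matrix (labels) or an H x W x 3 array (RGB)")
  }
  if (geometry != "planar" && w != 2L * h)
    stop(geometry, " raster must have 2:1 aspect (width = 2 * height), ",
         "got ", w, " x ", h)
  if (is.null(mask)) {
    mask <- if (geometry == "hammer") hammer_mask(w, h)
            else matrix(TRUE, h, w)
  }
  stopifnot(is.logical(mask), nrow(mask) == h, ncol(mask) == w)
  structure(
    list(values = values, geometry = geometry, mask = mask,
         width = w, height = h, kind = kind, categories = categories),
    class = "spherical_raster"
  )
}

#' @export
print.spherical_raster <- function(x, ...) {
  cat(sprintf("<spherical_raster> %s %s, %d x %d, %d valid px",
              x$geometry, x$kind, x$width, x$height, sum(x$mask)))
  if (!is.null(x$categories))
    cat(" | categories:", paste(x$categories, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @export
dim.spherical_raster <- function(x) c(x$height, x$width)

is_label_raster <- function(x) {
  inherits(x, "spherical_raster") && x$kind == "label"
}

is_rgb_raster <- function(x) {
  inherits(x, "spherical_raster") && x$kind == "rgb"
}

#' Pixel-center longitudes and latitudes of an equirectangular grid
#'
#' @param width,height grid size in pixels (width = 2 * height)
#' @return list with `lon` (length `width`) and `lat` (length `height`),
#'   both in radians; `lat[1]` is the top row (near `+pi/2`)
#' @export
equirect_centers <- function(width, height) {
  list(
    lon = -pi + (seq_len(width) - 0.5) * 2 * pi / width,
    lat = pi / 2 - (seq_len(height) - 0.5) * pi / height
  )
}

#' Read / write label rasters as whitespace-delimited integer text
#'
#' Masked-out pixels are stored as the reserved value 255.
#'
#' @param path file path
#' @param x a label `spherical_raster`
#' @name label_raster_io
#' @export
read_label_raster <- function(path, geometry = "equirectangular") {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  mask <- m != 255L
  m[!mask] <- NA_integer_
  spherical_raster(m, geometry = geometry,
                   mask = if (all(mask)) NULL else mask)
}

#' @rdname label_raster_io
#' @export
write_label_raster <- function(x, path) {
  stopifnot(is_label_raster(x))
  m <- x$values
  m[!x$mask] <- 255L
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write RGB panoramas as PNG
#'
#' @param path PNG file path
#' @param x an RGB `spherical_raster`
#' @name png_io
#' @export
read_panorama_png <- function(path, geometry = "equirectangular") {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  spherical_raster(round(a * 255), geometry = geometry)
}

#' @rdname png_io
#' @export
write_panorama_png <- function(x, path) {
  stopifnot(is_rgb_raster(x))
  a <- x$values / 255
  a[a < 0] <- 0; a[a > 1] <- 1
  png::writePNG(a, path)
  invisible(path)
}
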