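#' Six color classes used for the color layer of a scene audit
#' @export
COLOR_CLASSES <- c("red", "green", "blue", "gray", "white", "black")

#' Convert RGB channel values to HSV
#'
#' Standard hexcone conversion (via [grDevices::rgb2hsv()]): value is
#' `max/255`, saturation is `(max - min)/max` (0 for black), hue is in
#' degrees `[0, 360)` and reported as 0 for achromatic pixels.
#'
#' @param r,g,b channel values in 0-255 (vectorized)
#' @return data.frame with columns `h` (degrees), `s`, `v` (fractions)
#' @export
#' @examples
#' rgb_to_hsv(255, 0, 0)   # h = 0, s = 1, v = 1
#' rgb_to_hsv(30, 60, 200) # h ~ 229.4, s ~ 0.85, v ~ 0.784
rgb_to_hsv <- function(r, g, b) {
  if (any(c(r, g, b) < 0 | c(r, g, b) > 255))
    stop("RGB channel values must lie in [0, 255]")
  m <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  data.frame(h = m["h", ] * 360, s = m["s", ], v = m["v", ],
             row.names = NULL)
}

#' Color classification rules over HSV space
#'
#' An ordered list of interval rules, evaluated first-match, that partitions
#' HSV space into the six color classes of [COLOR_CLASSES].  Each rule
#' restricts hue (degrees, half-open `[lo, hi)`, wrapping allowed), and/or
#' saturation and value (half-open `[lo, hi)`, except that an upper bound at
#' the top of the range is inclusive).  The rule set must be exhaustive:
#' this is verified on a dense HSV grid at construction, and non-exhaustive
#' sets are rejected.
#'
#' @param rules list of rules; each a list with fields `class` and any of
#'   `h`, `s`, `v`, each a length-2 numeric interval
#' @return object of class `color_rules`
#' @seealso [default_color_rules()], [classify_hsv()]
#' @export
color_rules <- function(rules) {
  rules <- lapply(rules, function(r) {
    stopifnot(!is.null(r$class), r$class %in% COLOR_CLASSES)
    r$h <- if (is.null(r$h)) c(0, 360) else as.numeric(r$h)
    r$s <- if (is.null(r$s)) c(0, 1) else as.numeric(r$s)
    r$v <- if (is.null(r$v)) c(0, 1) else as.numeric(r$v)
    stopifnot(length(r$h) == 2L, length(r$s) == 2L, length(r$v) == 2L)
    r
  })
  obj <- structure(list(rules = rules), class = "color_rules")
  miss <- rules_coverage_gap(obj)
  if (!is.null(miss))
    stop("color rules are not exhaustive; e.g. unmatched HSV triple (",
         paste(signif(miss, 4), collapse = ", "), ")")
  obj
}

# dense-grid exhaustiveness probe; returns an unmatched (h,s,v) or NULL
rules_coverage_gap <- function(obj) {
  h <- seq(0, 359.75, by = 0.25)
  sv <- seq(0, 1, by = 0.05)
  grid <- expand.grid(h = h, s = sv, v = sv)
  cl <- classify_hsv(grid$h, grid$s, grid$v, obj, .check = FALSE)
  i <- which(is.na(cl))[1]
  if (is.na(i)) NULL else as.numeric(grid[i, ])
}

#' Default six-class HSV threshold rules
#'
#' Darkness dominates (`v < 0.15` is black regardless of hue); then
#' low-saturation pixels split into white (`v >= 0.80`) and gray; remaining
#' chromatic pixels fall into three 120-degree hue sectors: red
#' `[300, 360) U [0, 60)`, green `[60, 180)`, blue `[180, 300)`.  The
#' thresholds are an editable configuration, not ground truth: encode your
#' own cut points with [color_rules()] or a YAML file when you have them.
#'
#' @return a `color_rules` object
#' @export
default_color_rules <- function() {
  color_rules(list(
    list(class = "black", v = c(0, 0.15)),
    list(class = "white", s = c(0, 0.15), v = c(0.80, 1)),
    list(class = "gray", s = c(0, 0.15)),
    list(class = "red", h = c(300, 60)),
    list(class = "green", h = c(60, 180)),
    list(class = "blue", h = c(180, 300))
  ))
}

#' @export
print.color_rules <- function(x, ...) {
  cat("<color_rules>", length(x$rules), "ordered rules:\n")
  for (r in x$rules)
    cat(sprintf("  %-5s h [%g, %g)  s [%g, %g]  v [%g, %g]\n",
                r$class, r$h[1], r$h[2], r$s[1], r$s[2], r$v[1], r$v[2]))
  invisible(x)
}

#' Read / write color rules as YAML
#'
#' @param path YAML file path
#' @param x a `color_rules` object
#' @name color_rules_io
#' @export
read_color_rules <- function(path) {
  color_rules(yaml::read_yaml(path))
}

#' @rdname color_rules_io
#' @export
write_color_rules <- function(x, path) {
  stopifnot(inherits(x, "color_rules"))
  yaml::write_yaml(x$rules, path)
  invisible(path)
}

# interval membership: [lo, hi), upper bound inclusive at the range cap;
# hue intervals with lo > hi wrap through 0
in_interval <- function(x, lo, hi, cap) {
  if (lo > hi) return(x >= lo | x < hi)
  x >= lo & (x < hi | (hi >= cap & x <= hi))
}

#' Classify HSV pixels into the six color classes
#'
#' @param h hue in degrees `[0, 360)`; `s`, `v` fractions in `[0, 1]`
#'   (vectorized)
#' @param rules a `color_rules` object
#' @param .check internal; skip input validation
#' @return integer vector of class codes into [COLOR_CLASSES] (factor-like;
#'   use `COLOR_CLASSES[result]` for names)
#' @export
classify_hsv <- function(h, s, v, rules = default_color_rules(),
                         .check = TRUE) {
  if (.check) {
    stopifnot(inherits(rules, "color_rules"))
    if (any(h < 0 | h >= 360, na.rm = TRUE))
      stop("hue must lie in [0, 360)")
    if (any(s < 0 | s > 1 | v < 0 | v > 1, na.rm = TRUE))
      stop("saturation and value must lie in [0, 1]")
  }
  out <- rep(NA_integer_, length(h))
  for (r in rules$rules) {
    hit <- is.na(out) &
      in_interval(h, r$h[1], r$h[2], 360) &
      in_interval(s, r$s[1], r$s[2], 1) &
      in_interval(v, r$v[1], r$v[2], 1)
    out[hit] <- match(r$class, COLOR_CLASSES)
  }
  out
}

#' Classify one pixel
#'
#' @param r,g,b channel values 0-255, or pass `h`,`s`,`v` directly
#' @inheritParams classify_hsv
#' @return class name, one of [COLOR_CLASSES]
#' @export
classify_pixel <- function(r, g, b, rules = default_color_rules()) {
  p <- rgb_to_hsv(r, g, b)
  COLOR_CLASSES[classify_hsv(p$h, p$s, p$v, rules)]
}

#' Classify every pixel of an RGB raster into a color-class label raster
#'
#' Classification operates pixel-wise, so it commutes with nearest-neighbor
#' reprojection; the package classifies on the equirectangular raster and
#' reprojects the label raster, avoiding classification of interpolated
#' colors.
#'
#' @param src an RGB `spherical_raster`
#' @param rules a `color_rules` object
#' @param verbose log the class histogram to stderr
#' @return a label `spherical_raster` with the six color classes
#' @export
classify_raster <- function(src, rules = default_color_rules(),
                            verbose = FALSE) {
  if (!is_rgb_raster(src)) stop("classify_raster needs an RGB raster")
  p <- rgb_to_hsv(as.vector(src$values[, , 1]),
                  as.vector(src$values[, , 2]),
                  as.vector(src$values[, , 3]))
  cl <- classify_hsv(p$h, p$s, p$v, rules)
  m <- matrix(cl, src$height, src$width)
  m[!src$mask] <- NA_integer_
  if (verbose) {
    tab <- table(factor(COLOR_CLASSES[m[src$mask]], levels = COLOR_CLASSES))
    message("color class histogram: ",
            paste(names(tab), tab, sep = "=", collapse = " "))
  }
  spherical_raster(m, geometry = src$geometry, mask = src$mask,
                   categories = COLOR_CLASSES)
}
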