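#' Hammer equal-area projection: forward transform
#'
#' Maps sphere points to the Hammer ellipse.  The Hammer projection is an
#' equal-area cartographic projection onto a 2:1 ellipse, so equal pixel
#' counts on the projected grid correspond to equal solid angles on the
#' sphere -- the property the scene-auditing metrics rely on.
#'
#' With `D = sqrt(1 + cos(lat) * cos(lon/2))`:
#' `x = 2*sqrt(2) * cos(lat) * sin(lon/2) / D`, `y = sqrt(2) * sin(lat) / D`.
#' `x` spans `[-2*sqrt(2), 2*sqrt(2)]` and `y` spans `[-sqrt(2), sqrt(2)]`.
#'
#' @param lon longitude in radians, in `[-pi, pi]` (vectorized)
#' @param lat latitude in radians, in `[-pi/2, pi/2]` (vectorized)
#' @return list with numeric vectors `x` and `y`
#' @seealso [hammer_inverse()]
#' @export
#' @examples
#' hammer_forward(pi / 2, 0)  # x ~ 1.5307, y = 0
hammer_forward <- function(lon, lat) {
  if (any(lon < -pi - 1e-12 | lon > pi + 1e-12, na.rm = TRUE))
    stop("lon out of range [-pi, pi]")
  if (any(lat < -pi / 2 - 1e-12 | lat > pi / 2 + 1e-12, na.rm = TRUE))
    stop("lat out of range [-pi/2, pi/2]")
  D <- sqrt(1 + cos(lat) * cos(lon / 2))
  list(x = 2 * sqrt(2) * cos(lat) * sin(lon / 2) / D,
       y = sqrt(2) * sin(lat) / D)
}

#' Hammer projection: inverse transform
#'
#' Recovers the sphere point of a Hammer plane point.  Points outside the
#' projection ellipse `(x / (2*sqrt(2)))^2 + (y / sqrt(2))^2 <= 1` return
#' `NA` coordinates (used to build validity masks).  Latitudes are clamped
#' to `pi/2 - 1e-12` in magnitude so the longitude stays determinate at the
#' poles.
#'
#' @param x,y Hammer plane coordinates (vectorized)
#' @return list with `lon`, `lat` in radians (`NA` outside the ellipse)
#' @export
hammer_inverse <- function(x, y) {
  inside <- (x / (2 * sqrt(2)))^2 + (y / sqrt(2))^2 <= 1 + 1e-12
  z2 <- 1 - (x / 4)^2 - (y / 2)^2
  z2[z2 < 0] <- 0
  z <- sqrt(z2)
  lon <- 2 * atan2(z * x, 2 * (2 * z2 - 1))
  sl <- z * y
  sl[sl > 1] <- 1; sl[sl < -1] <- -1
  lat <- asin(sl)
  cap <- pi / 2 - 1e-12
  lat[lat > cap] <- cap
  lat[lat < -cap] <- -cap
  lon[!inside] <- NA_real_
  lat[!inside] <- NA_real_
  list(lon = lon, lat = lat)
}

# Plane coordinates of pixel centers for a W x H hammer grid (W = 2H):
# x spans the ellipse's bounding box [-2*sqrt(2), 2*sqrt(2)], y likewise,
# row 1 at +y (north up).
hammer_grid <- function(width, height) {
  list(
    x = -2 * sqrt(2) + (seq_len(width) - 0.5) * 4 * sqrt(2) / width,
    y = sqrt(2) - (seq_len(height) - 0.5) * 2 * sqrt(2) / height
  )
}

#' Validity mask of a Hammer pixel grid
#'
#' TRUE for pixels whose centers lie inside the projection ellipse.  The
#' TRUE fraction of the 2:1 bounding box approaches `pi/4` (the ellipse
#' area ratio) as resolution grows.
#'
#' @param width,height grid size in pixels (width = 2 * height)
#' @return logical height x width matrix
#' @export
hammer_mask <- function(width, height) {
  g <- hammer_grid(width, height)
  outer(g$y, g$x, function(y, x)
    (x / (2 * sqrt(2)))^2 + (y / sqrt(2))^2 <= 1)
}

#' Reproject an equirectangular raster to the Hammer equal-area grid
#'
#' Every valid output pixel is sampled at the sphere point obtained by
#' inverting its center.  Categorical rasters must use nearest-neighbor
#' sampling (interpolation must never invent labels); RGB rasters may use
#' bilinear interpolation with longitude wrap-around.
#'
#' @param src an equirectangular `spherical_raster`
#' @param out_width output width in pixels (height is `out_width / 2`);
#'   defaults to the source width, preserving nominal resolution
#' @param interpolation `"nearest"` or `"bilinear"`
#' @return a `spherical_raster` with hammer geometry and ellipse mask
#' @export
equirect_to_hammer <- function(src, out_width = NULL,
                               interpolation = c("nearest", "bilinear")) {
  stopifnot(inherits(src, "spherical_raster"))
  if (src$geometry != "equirectangular")
    stop("source raster must be equirectangular")
  interpolation <- match.arg(interpolation)
  if (src$kind == "label" && interpolation != "nearest")
    stop("categorical rasters require nearest-neighbor interpolation")
  if (is.null(out_width)) out_width <- src$width
  if (out_width %% 2L != 0L) out_width <- out_width + 1L
  out_h <- out_width %/% 2L

  g <- hammer_grid(out_width, out_h)
  x <- matrix(g$x, out_h, out_width, byrow = TRUE)
  y <- matrix(g$y, out_h, out_width)
  ll <- hammer_inverse(as.vector(x), as.vector(y))
  mask <- matrix(!is.na(ll$lon), out_h, out_width)

  W <- src$width; H <- src$height
  # fractional source pixel coordinates (1-based centers)
  uc <- (ll$lon + pi) / (2 * pi) * W + 0.5
  vc <- (pi / 2 - ll$lat) / pi * H + 0.5

  if (interpolation == "nearest") {
    ci <- pmin(pmax(round(uc), 1L), W)
    ri <- pmin(pmax(round(vc), 1L), H)
    take <- function(m) {
      out <- rep(NA_real_, length(ri))
      ok <- !is.na(ri)
      out[ok] <- m[cbind(ri[ok], ci[ok])]
      matrix(out, out_h, out_width)
    }
    if (src$kind == "label") {
      vals <- take(src$values)
      vals[!mask] <- NA_integer_
      storage.mode(vals) <- "integer"
      return(spherical_raster(vals, "hammer", mask = mask,
                              categories = src$categories))
    }
    out <- array(NA_real_, c(out_h, out_width, 3))
    for (b in 1:3) {
      v <- take(src$values[, , b])
      v[!mask] <- 0
      out[, , b] <- v
    }
    return(spherical_raster(out, "hammer", mask = mask))
  }

  # bilinear, RGB only; wrap columns across the antimeridian, clamp rows
  c0 <- floor(uc - 0.5) + 0.5
  r0 <- floor(vc - 0.5) + 0.5
  fc <- uc - c0
  fr <- vc - r0
  wrap <- function(cc) ((cc - 1L) %% W) + 1L
  cl <- wrap(round(c0)); cr <- wrap(round(c0) + 1L)
  rt <- pmin(pmax(round(r0), 1L), H)
  rb <- pmin(pmax(round(r0) + 1L, 1L), H)
  out <- array(0, c(out_h, out_width, 3))
  ok <- !is.na(uc)
  for (b in 1:3) {
    m <- src$values[, , b]
    v <- rep(0, length(uc))
    v[ok] <- (1 - fr[ok]) * ((1 - fc[ok]) * m[cbind(rt[ok], cl[ok])] +
                             fc[ok]       * m[cbind(rt[ok], cr[ok])]) +
             fr[ok]       * ((1 - fc[ok]) * m[cbind(rb[ok], cl[ok])] +
                             fc[ok]       * m[cbind(rb[ok], cr[ok])])
    out[, , b] <- matrix(v, out_h, out_width)
  }
  spherical_raster(out, "hammer", mask = mask)
}

#' Chi-square test of uniform areal density in the Hammer ellipse
#'
#' Diagnostic for the equal-area property: points drawn uniformly on the
#' sphere must land in the projection ellipse with uniform density.  The
#' bounding box is partitioned into a `cells` x `cells` grid; expected
#' counts are proportional to each cell's intersection area with the
#' ellipse (evaluated on a fine midpoint subgrid), and cells with expected
#' count below `min_expected` are pooled out.
#'
#' @param x,y projected point coordinates
#' @param cells grid cells per axis
#' @param min_expected minimum expected count for a cell to enter the
#'   statistic
#' @return list with `statistic`, `df`, `p.value`
#' @export
ellipse_uniformity_chisq <- function(x, y, cells = 10, min_expected = 5) {
  xb <- seq(-2 * sqrt(2), 2 * sqrt(2), length.out = cells + 1)
  yb <- seq(-sqrt(2), sqrt(2), length.out = cells + 1)
  ci <- findInterval(x, xb, rightmost.closed = TRUE)
  ri <- findInterval(y, yb, rightmost.closed = TRUE)
  counts <- table(factor(ri, 1:cells), factor(ci, 1:cells))

  # expected: ellipse-interior fraction of each cell on a fine subgrid
  sub <- 200
  frac <- matrix(0, cells, cells)
  for (i in seq_len(cells)) {
    ys <- seq(yb[i], yb[i + 1], length.out = sub + 1)
    ys <- (ys[-1] + ys[-length(ys)]) / 2
    for (j in seq_len(cells)) {
      xs <- seq(xb[j], xb[j + 1], length.out = sub + 1)
      xs <- (xs[-1] + xs[-length(xs)]) / 2
      frac[i, j] <- mean(outer(ys, xs, function(yy, xx)
        (xx / (2 * sqrt(2)))^2 + (yy / sqrt(2))^2 <= 1))
    }
  }
  n <- length(x)
  expected <- frac / sum(frac) * n
  keep <- expected >= min_expected
  O <- as.vector(counts)[as.vector(keep)]
  E <- expected[keep]
  E <- E / sum(E) * sum(O)
  stat <- sum((O - E)^2 / E)
  df <- length(O) - 1
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Solid-angle class proportions of an equirectangular label raster
#'
#' Weights each pixel by the cosine of its row latitude, the exact relative
#' solid angle of equirectangular pixels.  Serves as the independent oracle
#' for the equal-area property of the Hammer resampling path.
#'
#' @param src an equirectangular label `spherical_raster`
#' @return named numeric vector of class proportions summing to 1
#' @export
solid_angle_proportions <- function(src) {
  stopifnot(is_label_raster(src))
  if (src$geometry != "equirectangular")
    stop("source raster must be equirectangular")
  if (sum(src$mask) == 0L) stop("empty raster mask")
  w_lat <- cos(equirect_centers(src$width, src$height)$lat)
  wmat <- matrix(w_lat, src$height, src$width)
  wmat[!src$mask] <- 0
  vals <- src$values
  tot <- sum(wmat)
  agg <- tapply(as.vector(wmat), as.vector(vals), sum)
  agg <- agg[!is.na(names(agg))]
  p <- as.numeric(agg) / tot
  names(p) <- decode_labels(as.integer(names(agg)), src$categories)
  p
}

# integer codes -> category names when the raster carries them
decode_labels <- function(codes, categories) {
  if (is.null(categories)) as.character(codes) else categories[codes]
}

#' Class proportions of a masked categorical raster by pixel counting
#'
#' On a Hammer (equal-area) grid, masked pixel counts are proportional to
#' solid angle, so these proportions estimate true spherical class shares.
#'
#' @param src a label `spherical_raster`
#' @return named numeric vector of proportions summing to 1
#' @export
mask_proportions <- function(src) {
  stopifnot(is_label_raster(src))
  v <- src$values[src$mask]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("empty raster mask")
  tab <- table(v)
  p <- as.numeric(tab) / length(v)
  names(p) <- decode_labels(as.integer(names(tab)), src$categories)
  p
}
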