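#' Class scheme: grouping raw label ids into scene categories
#'
#' Semantic-segmentation rasters arrive with fine-grained integer ids (for
#' example the 150 ADE20K classes); the audit works on a handful of scene
#' categories (plant, sky, road, building, ...).  A `class_scheme` is an
#' ordered set of category names plus a total mapping from raw ids into
#' them; ids not listed can optionally fall through to an `"other"`
#' category, which still occupies visual field and therefore participates
#' in the landscape-level metrics.
#'
#' @param mapping named list `category -> integer vector of raw ids`
#' @param other name of the fall-through category, or `NULL` to require
#'   every id in a raster to be mapped explicitly
#' @return object of class `class_scheme`
#' @export
class_scheme <- function(mapping, other = "other") {
  stopifnot(is.list(mapping), !is.null(names(mapping)))
  ids <- unlist(mapping, use.names = FALSE)
  if (anyDuplicated(ids))
    stop("raw ids mapped to more than one category: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cats <- names(mapping)
  if (!is.null(other) && !(other %in% cats)) cats <- c(cats, other)
  if (anyDuplicated(cats)) stop("duplicate category names")
  structure(list(categories = cats, mapping = mapping, other = other),
            class = "class_scheme")
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("<class_scheme>", length(x$categories), "categories:",
      paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a class scheme as YAML (`category: [raw ids]`)
#'
#' @param path YAML file path
#' @param x a `class_scheme`
#' @param other passed to [class_scheme()]
#' @name class_scheme_io
#' @export
read_class_scheme <- function(path, other = "other") {
  class_scheme(yaml::read_yaml(path), other = other)
}

#' @rdname class_scheme_io
#' @export
write_class_scheme <- function(x, path) {
  stopifnot(inherits(x, "class_scheme"))
  yaml::write_yaml(x$mapping, path)
  invisible(path)
}

#' Group raw label ids into scene categories
#'
#' @param src a label `spherical_raster` of raw ids
#' @param scheme a `class_scheme`
#' @return a label `spherical_raster` whose integer codes index
#'   `scheme$categories`
#' @export
group_labels <- function(src, scheme) {
  stopifnot(is_label_raster(src), inherits(scheme, "class_scheme"))
  ids <- unlist(scheme$mapping, use.names = FALSE)
  cat_of_id <- rep(names(scheme$mapping),
                   vapply(scheme$mapping, length, 1L))
  present <- unique(src$values[src$mask])
  present <- present[!is.na(present)]
  unmapped <- setdiff(present, ids)
  if (length(unmapped) > 0L && is.null(scheme$other))
    stop("unmapped raw ids in raster: ",
         paste(sort(unmapped), collapse = ", "))
  codes <- match(cat_of_id, scheme$categories)
  lut_names <- as.character(ids)
  out <- src$values
  idx <- match(as.character(out), lut_names)
  out[] <- codes[idx]
  if (!is.null(scheme$other))
    out[is.na(idx) & !is.na(src$values)] <-
      match(scheme$other, scheme$categories)
  out[!src$mask] <- NA_integer_
  storage.mode(out) <- "integer"
  spherical_raster(out, geometry = src$geometry, mask = src$mask,
                   categories = scheme$categories)
}

#' Label the patches of a categorical raster
#'
#' A patch is a maximal connected set of same-category pixels, the unit of
#' the FRAGSTATS-style landscape metrics.  Connectivity 8 (queen) is the
#' default, matching the usual convention of spatial-pattern analysis
#' programs for categorical maps; 4 (rook) is available.
#'
#' @param src a label `spherical_raster`
#' @param connectivity 4 or 8
#' @return data.frame with one row per patch: `patch`, `category`
#'   (name if the raster carries categories, else the code as character),
#'   `area` (masked pixel count)
#' @export
label_patches <- function(src, connectivity = 8) {
  stopifnot(is_label_raster(src))
  vals <- src$values
  mask <- src$mask & !is.na(vals)
  vals_f <- vals
  vals_f[!mask] <- 0L
  ids <- .cc_label(vals_f, mask, as.integer(connectivity))
  keep <- !is.na(ids)
  if (!any(keep)) return(data.frame(patch = integer(), category = character(),
                                    area = integer()))
  tab <- table(ids[keep])
  patch_ids <- as.integer(names(tab))
  first_px <- match(patch_ids, ids)
  data.frame(
    patch = patch_ids,
    category = decode_labels(vals[first_px], src$categories),
    area = as.integer(tab),
    row.names = NULL
  )
}

#' Percentage of landscape (PLAND)
#'
#' Percent of the total masked scene area occupied by one category:
#' `100 * sum_j a_ij / A`.  Computed on an equal-area (Hammer) raster the
#' pixel counts are proportional to solid angle, so PLAND is the true
#' share of the visual field.
#'
#' @param src a label `spherical_raster`
#' @param category category name (or code as character)
#' @return percent in `[0, 100]` (0 when the category is absent)
#' @export
pland <- function(src, category) {
  stopifnot(is_label_raster(src))
  v <- src$values[src$mask]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("empty raster mask")
  cats <- decode_labels(v, src$categories)
  100 * sum(cats == category) / length(v)
}

#' Landscape division index (DIVISION)
#'
#' `1 - sum_i sum_j (a_ij / A)^2` over all patches: the probability that
#' two randomly chosen scene pixels fall in different patches.  0 for a
#' single patch covering the scene; approaches 1 as the scene fragments.
#'
#' @inheritParams label_patches
#' @return fraction in `[0, 1)`
#' @export
division <- function(src, connectivity = 8) {
  p <- label_patches(src, connectivity)
  if (nrow(p) == 0L) stop("empty raster mask")
  A <- sum(p$area)
  1 - sum((p$area / A)^2)
}

#' Shannon's diversity index (SHDI)
#'
#' `-sum_i P_i * ln(P_i)` over the categories present (`P_i` their area
#' proportions).  0 for a single category; at most `ln(m)` for `m`
#' categories, reached when areas are equal.
#'
#' @param src a label `spherical_raster`
#' @return nonnegative real
#' @export
shdi <- function(src) {
  p <- mask_proportions(src)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Audit one street scene on both layers
#'
#' Computes the visual-pattern indicator vector of a scene: PLAND per
#' category plus scene-level DIVISION and SHDI, for the constituent-element
#' layer and the color layer.  Input rasters may be equirectangular (they
#' are then reprojected to the Hammer equal-area grid at `out_width`) or
#' already in hammer geometry.
#'
#' @param element_raster label raster of scene categories (grouped ids)
#' @param color_raster label raster of the six color classes, or an RGB
#'   raster (then classified with `rules` first)
#' @param street_scale `"small"`, `"medium"` or `"large"` (lane-count
#'   annotation, not computed from imagery)
#' @param scene_id identifier recorded in the output rows
#' @param rules `color_rules` used when `color_raster` is RGB
#' @param out_width Hammer grid width for reprojection
#' @param connectivity patch connectivity for DIVISION
#' @return data.frame with one row per layer (`constituent_elements`,
#'   `colors`): `scene_id`, `layer`, `street_scale`, one `pland_<cat>`
#'   column per category of that layer, `division`, `shdi`
#' @export
audit_scene <- function(element_raster, color_raster, street_scale,
                        scene_id = "scene", rules = default_color_rules(),
                        out_width = 1024, connectivity = 8) {
  street_scale <- match.arg(street_scale, c("small", "medium", "large"))
  if (is_rgb_raster(color_raster))
    color_raster <- classify_raster(color_raster, rules)
  if (!is_label_raster(element_raster) || !is_label_raster(color_raster))
    stop("element_raster and color_raster must be label rasters")
  to_hammer <- function(r) {
    if (r$geometry == "hammer") r
    else equirect_to_hammer(r, out_width = out_width,
                            interpolation = "nearest")
  }
  eh <- to_hammer(element_raster)
  ch <- to_hammer(color_raster)
  if (!identical(dim(eh), dim(ch)))
    stop("element and color rasters must share geometry")
  rbind_fill(
    audit_layer(eh, "constituent_elements", scene_id, street_scale,
                connectivity),
    audit_layer(ch, "colors", scene_id, street_scale, connectivity)
  )
}

# rbind data.frames whose pland_* columns differ between layers,
# filling absent columns with NA
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[, cols, drop = FALSE]
  }))
}

audit_layer <- function(h, layer, scene_id, street_scale, connectivity) {
  cats <- h$categories
  if (is.null(cats)) {
    present <- sort(unique(h$values[h$mask]))
    cats <- as.character(present)
  }
  pl <- vapply(cats, function(cc) pland(h, cc), 0)
  row <- data.frame(scene_id = scene_id, layer = layer,
                    street_scale = street_scale, row.names = NULL,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cats)) row[[paste0("pland_", cats[i])]] <- pl[i]
  row$division <- division(h, connectivity)
  row$shdi <- shdi(h)
  row
}
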