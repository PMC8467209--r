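# Independent brute-force oracles for the landscape metrics, kept free of
# the package's own patch-labeling and counting code paths.

# queue-based flood fill over same-category neighbors
flood_fill_patches <- function(labels, mask = NULL, connectivity = 8) {
  h <- nrow(labels); w <- ncol(labels)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  mask <- mask & !is.na(labels)
  ids <- matrix(NA_integer_, h, w)
  nbr <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(c(-1, 0, 1), 3), rep(c(-1, 0, 1), each = 3))[-5, ]
  }
  next_id <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || !is.na(ids[r0, c0])) next
    next_id <- next_id + 1L
    cat0 <- labels[r0, c0]
    queue <- list(c(r0, c0))
    ids[r0, c0] <- next_id
    while (length(queue) > 0) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(nbr))) {
        rr <- cur[1] + nbr[k, 1]; cc <- cur[2] + nbr[k, 2]
        if (rr < 1 || rr > h || cc < 1 || cc > w) next
        if (!mask[rr, cc] || !is.na(ids[rr, cc])) next
        if (labels[rr, cc] != cat0) next
        ids[rr, cc] <- next_id
        queue[[length(queue) + 1L]] <- c(rr, cc)
      }
    }
  }
  ids
}

brute_patch_table <- function(labels, mask = NULL, connectivity = 8) {
  ids <- flood_fill_patches(labels, mask, connectivity)
  keep <- !is.na(ids)
  data.frame(patch = as.integer(names(table(ids[keep]))),
             area = as.integer(table(ids[keep])))
}

brute_pland <- function(labels, code, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(labels), ncol(labels))
  v <- labels[mask & !is.na(labels)]
  100 * sum(v == code) / length(v)
}

brute_division <- function(labels, mask = NULL, connectivity = 8) {
  p <- brute_patch_table(labels, mask, connectivity)
  1 - sum((p$area / sum(p$area))^2)
}

brute_shdi <- function(labels, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(labels), ncol(labels))
  v <- labels[mask & !is.na(labels)]
  p <- as.numeric(table(v)) / length(v)
  -sum(p * log(p))
}

# random square categorical raster (planar geometry)
random_label_raster <- function(n = 16, k = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spherical_raster(matrix(sample.int(k, n * n, replace = TRUE), n, n),
                   geometry = "planar")
}

# equirectangular label raster with a sky band above lat_deg
band_raster <- function(width = 1024, lat_deg = 30) {
  h <- width %/% 2L
  lat <- matrix(equirect_centers(width, h)$lat, h, width)
  lab <- matrix(1L, h, width)
  lab[lat >= lat_deg * pi / 180] <- 2L
  spherical_raster(lab, categories = c("ground", "sky"))
}

# small audit set shared by statistics tests (memoised per session)
.audit_cache <- new.env(parent = emptyenv())
get_test_audits <- function() {
  if (is.null(.audit_cache$a)) .audit_cache$a <- make_test_audits()
  .audit_cache$a
}

make_test_audits <- function(n_scenes = 39, width = 256, seed = 42) {
  specs <- synthetic_scene_specs(n = n_scenes, width = width, seed = seed)
  scenes <- lapply(seq_along(specs), function(i)
    generate_scene(specs[[i]], seed = seed + i))
  audits <- do.call(rbind, lapply(scenes, function(s)
    audit_scene(s$labels, s$rgb, s$spec$street_scale, s$spec$scene_id,
                out_width = width)))
  list(scenes = scenes, audits = audits)
}
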