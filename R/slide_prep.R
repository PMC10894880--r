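# Slide preparation: tessellation into 512 x 512 tiles at 0.5 um/px,
# HSV-saturation background removal, Macenko stain normalization, RGB
# z-scoring (training statistics only), and flip augmentation.

#' Tessellate a slide into non-overlapping tiles
#'
#' Accepts an in-memory RGB raster (H x W x 3 array, 0..255 or 0..1 scale),
#' a PNG path, or a pre-tiled directory (`<col>_<row>.png`). Raster input is
#' resampled to the target resolution when its microns-per-pixel differs by
#' more than 10% (area averaging for integer factors, bilinear otherwise);
#' sources coarser than the target cannot be upsampled and error. Partial
#' edge tiles are discarded; grid coordinates are 0-based with the origin at
#' the top-left; `level0_x/y` give each tile's offset in source pixels.
#'
#' @param slide Array, PNG path, or tile-directory path.
#' @param tile_size Tile side in pixels (default 512).
#' @param mpp Target resolution in microns per pixel (default 0.5).
#' @param source_mpp Resolution of the input raster; taken from
#'   `attr(slide, "mpp")` when absent, else assumed equal to `mpp` with a
#'   warning.
#' @param slide_id Identifier recorded in the grid.
#' @param sat_threshold,tissue_fraction_min Background-removal settings
#'   passed to [is_background()].
#' @return An object of class `tile_grid`: `slide_id`, `tile_size`, `mpp`,
#'   `tiles` (data frame `grid_col`, `grid_row`, `level0_x`, `level0_y`),
#'   `kept` (logical background mask, TRUE = tissue), `images` (list of
#'   tile arrays, in `tiles` order).
#' @export
tile_slide <- function(slide, tile_size = 512, mpp = 0.5, source_mpp = NULL,
                       slide_id = "slide", sat_threshold = 0.07,
                       tissue_fraction_min = 0.25) {
  if (is.character(slide) && length(slide) == 1 && dir.exists(slide)) {
    return(tile_directory(slide, tile_size, mpp, slide_id,
                          sat_threshold, tissue_fraction_min))
  }
  if (is.character(slide)) {
    if (!file.exists(slide)) stopf("cannot read slide '%s'", slide)
    img <- png::readPNG(slide) * 255
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img <- img[, , 1:3, drop = FALSE]
  } else {
    if (is.null(source_mpp)) source_mpp <- attr(slide, "mpp")
    img <- as_tile(slide)
    if (max(img) <= 1) img <- img * 255
  }
  if (is.null(source_mpp)) {
    warnf("no resolution metadata; assuming %.2f um/pixel", mpp)
    source_mpp <- mpp
  }
  scale <- mpp / source_mpp
  if (scale < 0.9) {
    stopf("source resolution (%.3f um/px) is coarser than the %.3f um/px target",
          source_mpp, mpp)
  }
  if (abs(scale - 1) > 0.1) {
    if (abs(scale - round(scale)) < 1e-9) {
      img <- downsample_block(img, as.integer(round(scale)))
    } else {
      img <- resize_bilinear(img, floor(dim(img)[1] / scale),
                             floor(dim(img)[2] / scale))
    }
  } else {
    scale <- 1
  }
  nr <- dim(img)[1] %/% tile_size
  nc <- dim(img)[2] %/% tile_size
  grid <- expand.grid(grid_col = seq_len(nc) - 1L, grid_row = seq_len(nr) - 1L,
                      KEEP.OUT.ATTRS = FALSE)
  grid$level0_x <- as.integer(grid$grid_col * tile_size * scale)
  grid$level0_y <- as.integer(grid$grid_row * tile_size * scale)
  images <- vector("list", nrow(grid))
  kept <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- grid$grid_row[i] * tile_size
    cl <- grid$grid_col[i] * tile_size
    images[[i]] <- img[r + seq_len(tile_size), cl + seq_len(tile_size), ,
                       drop = FALSE]
    kept[i] <- !is_background(images[[i]], sat_threshold, tissue_fraction_min)
  }
  structure(list(slide_id = slide_id, tile_size = tile_size, mpp = mpp,
                 tiles = grid, kept = kept, images = images),
            class = "tile_grid")
}

tile_directory <- function(path, tile_size, mpp, slide_id,
                           sat_threshold, tissue_fraction_min) {
  files <- list.files(path, pattern = "^[0-9]+_[0-9]+\\.png$")
  if (!length(files)) stopf("no '<col>_<row>.png' tiles in '%s'", path)
  coords <- do.call(rbind, strsplit(sub("\\.png$", "", files), "_"))
  grid <- data.frame(grid_col = as.integer(coords[, 1]),
                     grid_row = as.integer(coords[, 2]))
  ord <- order(grid$grid_row, grid$grid_col)
  grid <- grid[ord, , drop = FALSE]
  files <- files[ord]
  grid$level0_x <- grid$grid_col * tile_size
  grid$level0_y <- grid$grid_row * tile_size
  rownames(grid) <- NULL
  images <- lapply(file.path(path, files), function(f) png::readPNG(f) * 255)
  images <- lapply(images, function(im) im[, , 1:3, drop = FALSE])
  kept <- !vapply(images, is_background, TRUE,
                  sat_threshold = sat_threshold,
                  tissue_fraction_min = tissue_fraction_min)
  structure(list(slide_id = slide_id, tile_size = tile_size, mpp = mpp,
                 tiles = grid, kept = kept, images = images),
            class = "tile_grid")
}

#' Write the TileGrid JSON sidecar of a slide
#' @param grid A `tile_grid`.
#' @param path Output path.
#' @export
write_tile_grid <- function(grid, path) {
  jsonlite::write_json(
    list(slide_id = grid$slide_id, tile_size_px = grid$tile_size,
         mpp = grid$mpp, tiles = grid$tiles, kept_mask = grid$kept),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Is a tile background?
#'
#' Substitute for the proprietary deep-learning background-removal tool: a
#' tile is background when the fraction of its pixels with HSV saturation
#' above `sat_threshold` falls below `tissue_fraction_min`.
#'
#' @param tile 8-bit RGB tile (array or PNG path).
#' @param sat_threshold Saturation above which a pixel counts as tissue
#'   (default 0.07).
#' @param tissue_fraction_min Minimum tissue-pixel fraction (default 0.25).
#' @return `TRUE` iff the tile is background.
#' @export
is_background <- function(tile, sat_threshold = 0.07,
                          tissue_fraction_min = 0.25) {
  tile <- as_tile(tile)
  mx <- pmax(tile[, , 1], tile[, , 2], tile[, , 3])
  mn <- pmin(tile[, , 1], tile[, , 2], tile[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  mean(sat > sat_threshold) < tissue_fraction_min
}

# --- Macenko stain normalization -------------------------------------------

# Optical densities of a tile's pixels (rows) against a 255 white point.
tile_od <- function(tile) {
  flat <- cbind(as.vector(tile[, , 1]), as.vector(tile[, , 2]),
                as.vector(tile[, , 3]))
  -log10(pmax(flat, 1) / 255)
}

# Core Macenko estimate on an OD pixel matrix. Returns NULL when fewer than
# `min_pixels` pixels clear the OD floor.
macenko_estimate <- function(od, od_floor = 0.15, angle_percentiles = c(0.01, 0.99),
                             conc_quantile = 0.99, min_pixels = 100) {
  # drop optically faint pixels: OD magnitude below the floor. (A per-channel
  # rule would also drop pure-stain pixels, since each stain is dark in only
  # some channels, and would bias the extreme-angle estimates.)
  keep <- sqrt(rowSums(od^2)) >= od_floor
  odh <- od[keep, , drop = FALSE]
  if (nrow(odh) < min_pixels) return(NULL)
  e <- eigen(stats::cov(odh), symmetric = TRUE)
  basis <- e$vectors[, 1:2, drop = FALSE]
  # orient the basis so projections are predominantly positive
  for (k in 1:2) if (sum(odh %*% basis[, k]) < 0) basis[, k] <- -basis[, k]
  proj <- odh %*% basis
  phi <- atan2(proj[, 2], proj[, 1])
  ang <- stats::quantile(phi, angle_percentiles, names = FALSE)
  v1 <- basis %*% c(cos(ang[1]), sin(ang[1]))
  v2 <- basis %*% c(cos(ang[2]), sin(ang[2]))
  fix <- function(v) { v <- pmax(as.vector(v), 0); v / sqrt(sum(v^2)) }
  v1 <- fix(v1); v2 <- fix(v2)
  # hematoxylin has the larger red-channel OD component
  m <- if (v1[1] >= v2[1]) cbind(v1, v2) else cbind(v2, v1)
  colnames(m) <- c("hematoxylin", "eosin")
  conc <- t(solve(crossprod(m), crossprod(m, t(od))))   # least squares
  mc <- apply(conc, 2, stats::quantile, probs = conc_quantile, names = FALSE)
  list(stain_matrix = m, max_concentrations = mc)
}

#' Fit a Macenko stain reference from tissue tiles
#'
#' Pools optical densities of the reference tiles, estimates the two stain
#' directions from the extreme-angle percentiles in the top-2 eigenvector
#' plane (OD floor 0.15, 1%/99% angle percentiles), and records each
#' stain's 99th-percentile concentration.
#'
#' @param tiles List of RGB tiles (or a single tile).
#' @param od_floor Optical-density floor below which pixels are discarded.
#' @param angle_percentiles Robust angle percentiles.
#' @param conc_quantile Concentration quantile for the scaling reference.
#' @param max_pixels_per_tile Pixel subsample cap per tile (deterministic
#'   stride), keeping the fit desk-scale.
#' @return An object of class `stain_reference`: `stain_matrix` (3 x 2,
#'   column-unit-norm, non-negative) and `max_concentrations` (length 2).
#' @export
fit_stain_reference <- function(tiles, od_floor = 0.15,
                                angle_percentiles = c(0.01, 0.99),
                                conc_quantile = 0.99,
                                max_pixels_per_tile = 50000) {
  if (is.array(tiles)) tiles <- list(tiles)
  od <- do.call(rbind, lapply(tiles, function(t_) {
    o <- tile_od(as_tile(t_))
    if (nrow(o) > max_pixels_per_tile) {
      o <- o[seq(1, nrow(o), length.out = max_pixels_per_tile), , drop = FALSE]
    }
    o
  }))
  est <- macenko_estimate(od, od_floor, angle_percentiles, conc_quantile)
  if (is.null(est)) {
    stopf("reference tiles contain too little tissue for a stain estimate")
  }
  structure(est, class = "stain_reference")
}

#' Macenko-normalize a tile against a stain reference
#'
#' Estimates the tile's own stain directions and concentrations, rescales
#' concentrations to the reference's 99th percentiles, and reconstructs the
#' tile through the reference stain matrix. Tiles with fewer than
#' `min_pixels` pixels above the OD floor are returned unchanged with
#' attribute `degenerate = TRUE`.
#'
#' @param tile 8-bit RGB tile.
#' @param reference A [fit_stain_reference()] object.
#' @param od_floor,angle_percentiles,conc_quantile Macenko settings (must
#'   match the reference fit).
#' @param min_pixels Minimum tissue pixels for a stain estimate.
#' @return Normalized 8-bit RGB tile with attribute `degenerate`.
#' @export
macenko_normalize <- function(tile, reference, od_floor = 0.15,
                              angle_percentiles = c(0.01, 0.99),
                              conc_quantile = 0.99, min_pixels = 100) {
  stopifnot(inherits(reference, "stain_reference"))
  tile <- as_tile(tile)
  od <- tile_od(tile)
  est <- macenko_estimate(od, od_floor, angle_percentiles, conc_quantile,
                          min_pixels)
  if (is.null(est)) {
    attr(tile, "degenerate") <- TRUE
    return(tile)
  }
  m <- est$stain_matrix
  conc <- t(solve(crossprod(m), crossprod(m, t(od))))
  scale_f <- reference$max_concentrations / pmax(est$max_concentrations, 1e-8)
  conc <- sweep(conc, 2, scale_f, "*")
  od_new <- conc %*% t(reference$stain_matrix)
  out <- array(255 * 10^(-od_new), dim(tile))
  out <- round(pmin(pmax(out, 0), 255))
  attr(out, "degenerate") <- FALSE
  out
}

# --- channel statistics ----------------------------------------------------

#' Per-channel mean and standard deviation of a training tile corpus
#'
#' Statistics are global over all pixels of all training tiles and must be
#' fitted on training tiles only (test tiles are z-scored with these same
#' values; see the leakage tests).
#'
#' @param tiles List of RGB tiles (or a single tile).
#' @return Object of class `channel_stats`: `mean` and `sd` (named R/G/B),
#'   `n_pixels`.
#' @export
compute_channel_stats <- function(tiles) {
  if (is.array(tiles)) tiles <- list(tiles)
  ch_names <- c("R", "G", "B")
  pooled <- lapply(1:3, function(ch) {
    unlist(lapply(tiles, function(t_) as.vector(as_tile(t_)[, , ch])),
           use.names = FALSE)
  })
  mu <- vapply(pooled, mean, 0)
  sd_ <- vapply(pooled, stats::sd, 0)
  for (ch in 1:3) {
    if (sd_[ch] == 0) stopf("channel %s has zero variance", ch_names[ch])
  }
  structure(list(mean = stats::setNames(mu, ch_names),
                 sd = stats::setNames(sd_, ch_names),
                 n_pixels = length(pooled[[1]])),
            class = "channel_stats")
}

#' Z-score a tile with training channel statistics
#' @param tile RGB tile.
#' @param stats A [compute_channel_stats()] object.
#' @return Real-valued tile array.
#' @export
zscore_tile <- function(tile, stats) {
  stopifnot(inherits(stats, "channel_stats"))
  tile <- as_tile(tile)
  for (ch in 1:3) {
    tile[, , ch] <- (tile[, , ch] - stats$mean[ch]) / stats$sd[ch]
  }
  tile
}

#' @rdname zscore_tile
#' @export
zscore_invert <- function(tile, stats) {
  stopifnot(inherits(stats, "channel_stats"))
  for (ch in 1:3) {
    tile[, , ch] <- tile[, , ch] * stats$sd[ch] + stats$mean[ch]
  }
  tile
}

#' Random horizontal/vertical flip augmentation
#'
#' Training-time augmentation only; each flip is applied independently with
#' its own probability (testing uses normalization alone).
#'
#' @param tile RGB tile array.
#' @param p_horizontal,p_vertical Flip probabilities (default 0.5 each).
#' @return Possibly flipped tile.
#' @export
flip_augment <- function(tile, p_horizontal = 0.5, p_vertical = 0.5) {
  u <- stats::runif(2)
  if (u[1] < p_horizontal) tile <- tile[, rev(seq_len(dim(tile)[2])), ,
                                        drop = FALSE]
  if (u[2] < p_vertical) tile <- tile[rev(seq_len(dim(tile)[1])), , ,
                                      drop = FALSE]
  tile
}
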