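#' Partition a slide image into non-overlapping tiles
#'
#' Tiles are `tile_size_px` squares laid out row-major from pixel (0,0) at
#' the top-left; partial tiles at the right/bottom edges are dropped (not
#' padded), so every tile has equal area and nucleus count ranks tiles
#' identically to nuclear density.
#'
#' @param image RGB array, or `c(H, W)` integer dimensions.
#' @param tile_size_px Tile side in pixels (`>= 64`). Real whole-slide runs
#'   use [real_slide_tile_px()] (5120 px); the desk-scale default is 512 px.
#' @return A `tile_grid` list: `tile_size_px`, `n_rows`, `n_cols`,
#'   `image_dim`, and `origin` = "0-based, row-major, pixel (0,0) top-left".
#' @export
partition_tiles <- function(image, tile_size_px = 512) {
  dims <- if (is.array(image)) dim(image)[1:2] else as.integer(image[1:2])
  stopifnot(tile_size_px >= 64)
  if (any(dims < tile_size_px)) {
    stop(sprintf("image (%d x %d px) is smaller than one %d-px tile",
                 dims[1], dims[2], tile_size_px))
  }
  structure(list(tile_size_px = as.integer(tile_size_px),
                 n_rows = dims[1] %/% tile_size_px,
                 n_cols = dims[2] %/% tile_size_px,
                 image_dim = dims,
                 origin = "0-based, row-major, pixel (0,0) top-left"),
            class = "tile_grid")
}

#' Extract one tile from a slide image without copying the whole image
#' @param image RGB array.
#' @param grid A `tile_grid` from [partition_tiles()].
#' @param tile_row,tile_col 0-based tile coordinates.
#' @return RGB array of the tile.
#' @export
get_tile <- function(image, grid, tile_row, tile_col) {
  stopifnot(tile_row >= 0, tile_row < grid$n_rows,
            tile_col >= 0, tile_col < grid$n_cols)
  ts <- grid$tile_size_px
  image[tile_row * ts + seq_len(ts), tile_col * ts + seq_len(ts), , drop = FALSE]
}

#' Segment every tile of a slide
#'
#' Runs [segment_nuclei()] on each tile of the grid, returning the per-tile
#' results (row-major list) and the matrix of nucleus counts. Segmentation
#' failures are re-raised with the offending tile coordinates attached.
#'
#' @inheritParams get_tile
#' @param params A [seg_params()].
#' @param measure Compute per-nucleus records per tile (default TRUE).
#' @return List with `results` (list of `nuclei_seg`, row-major) and
#'   `counts` (`n_rows x n_cols` integer matrix).
#' @export
segment_tiles <- function(image, grid, params = seg_params(), measure = TRUE) {
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  results <- vector("list", grid$n_rows * grid$n_cols)
  k <- 0L
  for (tr in seq_len(grid$n_rows) - 1L) {
    for (tc in seq_len(grid$n_cols) - 1L) {
      k <- k + 1L
      seg <- tryCatch(
        segment_nuclei(get_tile(image, grid, tr, tc), params, measure = measure),
        error = function(e) stop(sprintf("segmentation failed in tile (%d, %d): %s",
                                         tr, tc, conditionMessage(e))))
      counts[tr + 1L, tc + 1L] <- seg$n_nuclei
      results[[k]] <- seg
    }
  }
  list(results = results, counts = counts)
}

#' Count detected nuclei per tile
#'
#' @inheritParams segment_tiles
#' @return Integer matrix of shape `n_rows x n_cols`.
#' @export
count_nuclei_per_tile <- function(grid, image, params = seg_params()) {
  segment_tiles(image, grid, params, measure = FALSE)$counts
}

#' Select the top-k most cellular tiles as regions of interest
#'
#' Ranks tiles by detected nucleus count (descending) with ties broken by
#' (row, col) ascending -- row-major order -- and keeps the top `k`
#' (default 5, the number of highest-density tiles used per slide). If `k`
#' exceeds the number of tiles, all tiles are returned and the shortfall is
#' logged.
#'
#' @param counts Matrix of per-tile nucleus counts (or a vector treated as
#'   one row).
#' @param k Number of ROIs (`>= 1`).
#' @param tile_size_px Tile size recorded in the entries (for pixel boxes).
#' @return An `roi_set`: data.frame `entries` with columns `tile_row`,
#'   `tile_col` (0-based), `nucleus_count`, `density_per_px2`, `x0`, `y0`,
#'   `x1`, `y1` (half-open pixel box), sorted by count descending; plus `k`.
#' @export
select_rois <- function(counts, k = 5L, tile_size_px = 512L) {
  stopifnot(k >= 1)
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1L)
  n_tiles <- length(counts)
  if (k > n_tiles) {
    gg_log("select_rois: k = %d exceeds %d tiles; returning all tiles", k, n_tiles)
  }
  kk <- min(k, n_tiles)
  ## row-major linear index (row, col 0-based)
  tr <- as.vector(row(counts)) - 1L
  tc <- as.vector(col(counts)) - 1L
  cnt <- as.vector(counts)
  ord <- order(-cnt, tr, tc)
  sel <- ord[seq_len(kk)]
  ts <- as.integer(tile_size_px)
  entries <- data.frame(tile_row = tr[sel], tile_col = tc[sel],
                        nucleus_count = cnt[sel],
                        density_per_px2 = cnt[sel] / (as.numeric(ts)^2),
                        x0 = tc[sel] * ts, y0 = tr[sel] * ts,
                        x1 = (tc[sel] + 1L) * ts, y1 = (tr[sel] + 1L) * ts)
  structure(list(entries = entries, k = as.integer(k),
                 tile_size_px = ts), class = "roi_set")
}

#' Write an ROI manifest as JSON
#' @param roi An `roi_set` from [select_rois()].
#' @param slide_id Slide identifier stored in the manifest.
#' @param path Output JSON path.
#' @export
write_roi_manifest <- function(roi, slide_id, path) {
  jsonlite::write_json(list(slide_id = slide_id,
                            tile_size_px = roi$tile_size_px,
                            k = roi$k, entries = roi$entries),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
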