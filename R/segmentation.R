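#' Nuclei segmentation parameters
#'
#' Parameters of the watershed nucleus detector. Defaults target the
#' 512-px desk-scale tile; `min_nucleus_area_px` and `seed_min_distance_px`
#' scale linearly with resolution for other tile sizes.
#'
#' @param stain_matrix 3x3 stain matrix (rows = unit OD vectors); default
#'   Ruifrok-Johnston H&E.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Haematoxylin-OD threshold when
#'   `threshold_method = "fixed"`.
#' @param od_floor Lower bound applied to the Otsu threshold; prevents
#'   spurious foreground on (near-)blank tiles where Otsu thresholds noise.
#' @param min_nucleus_area_px Minimum region area kept (px^2).
#' @param seed_min_distance_px Minimum separation of watershed seed maxima
#'   (px); the neighbourhood radius used for local-maximum detection on the
#'   distance transform.
#' @param opening_radius_px Radius (px) of the morphological opening applied
#'   to the thresholded mask.
#' @param watershed_tolerance Minimum distance-transform height separating
#'   two objects (EBImage watershed `tolerance`).
#' @return A `seg_params` list.
#' @export
seg_params <- function(stain_matrix = he_stain_matrix(),
                       threshold_method = c("otsu", "fixed"),
                       fixed_threshold = 0.3,
                       od_floor = 0.15,
                       min_nucleus_area_px = 40,
                       seed_min_distance_px = 7,
                       opening_radius_px = 1,
                       watershed_tolerance = 1) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(min_nucleus_area_px > 0, seed_min_distance_px >= 1,
            opening_radius_px >= 0)
  structure(list(stain_matrix = stain_matrix,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 od_floor = od_floor,
                 min_nucleus_area_px = min_nucleus_area_px,
                 seed_min_distance_px = seed_min_distance_px,
                 opening_radius_px = opening_radius_px,
                 watershed_tolerance = watershed_tolerance),
            class = "seg_params")
}

#' Segment nuclei in an H&E-like RGB tile
#'
#' Marker-controlled watershed segmentation on the deconvolved haematoxylin
#' channel: Otsu (or fixed) threshold, morphological opening, Euclidean
#' distance transform, local maxima separated by at least
#' `seed_min_distance_px` as seeds, watershed of the distance map, removal
#' of regions below `min_nucleus_area_px`, and contiguous relabelling
#' `1..N`. Blank tiles return zero nuclei without error.
#'
#' @param image RGB array (`H x W x 3`), 8-bit or `[0,1]`.
#' @param params A [seg_params()] object.
#' @param measure Also compute per-nucleus records (default TRUE).
#' @return List of class `nuclei_seg` with `labels` (integer `H x W`
#'   matrix, 0 = background), `n_nuclei`, `records` (data.frame of
#'   per-nucleus measurements, see [measure_regions()]; `NULL` when
#'   `measure = FALSE`), and `h_od`/`e_od` stain rasters.
#' @export
segment_nuclei <- function(image, params = seg_params(), measure = TRUE) {
  stopifnot(inherits(params, "seg_params"))
  stains <- separate_stains(image, params$stain_matrix)
  h <- stains$h_od
  if (params$threshold_method == "otsu") {
    hmax <- max(h, 2.5)
    thr <- EBImage::otsu(EBImage::Image(pmin(h / hmax, 1)), range = c(0, 1)) * hmax
    thr <- max(thr, params$od_floor)
  } else {
    thr <- params$fixed_threshold
  }
  mask <- h > thr
  if (params$opening_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * ceiling(params$opening_radius_px) + 1L, "disc")
    mask <- EBImage::opening(mask, brush)
  }
  if (!any(mask)) {
    labels <- matrix(0L, nrow(h), ncol(h))
  } else {
    d <- EBImage::distmap(mask)
    w <- EBImage::watershed(d, tolerance = params$watershed_tolerance,
                            ext = params$seed_min_distance_px)
    w <- matrix(as.integer(w), nrow(h), ncol(h))
    areas <- tabulate(w)
    keep <- which(areas >= params$min_nucleus_area_px)
    remap <- integer(length(areas))
    remap[keep] <- seq_along(keep)
    labels <- matrix(0L, nrow(h), ncol(h))
    nz <- w > 0L
    labels[nz] <- remap[w[nz]]
  }
  n <- max(labels, 0L)
  records <- NULL
  if (measure && n > 0L) {
    records <- measure_regions(labels, rgb_to_gray(image), h, stains$e_od)
  } else if (measure) {
    records <- empty_records()
  }
  structure(list(labels = labels, n_nuclei = n, records = records,
                 h_od = h, e_od = stains$e_od, threshold = thr),
            class = "nuclei_seg")
}

empty_records <- function() {
  data.frame(label = integer(0), area = numeric(0), perimeter = numeric(0),
             centroid_row = numeric(0), centroid_col = numeric(0),
             major_axis = numeric(0), minor_axis = numeric(0),
             eccentricity = numeric(0), solidity = numeric(0),
             circularity = numeric(0), mean_h_od = numeric(0),
             sd_intensity = numeric(0), ring_e_od = numeric(0))
}

#' Measure all labeled nuclei in a mask
#'
#' Computes per-region geometry and staining statistics: area, Crofton
#' perimeter (4 directions; agrees with the scikit-image estimator),
#' centroid, major/minor axis lengths and eccentricity from second central
#' moments, solidity (pixel area over convex-hull area of the pixel
#' squares), circularity `4*pi*A/P^2`, mean haematoxylin OD, within-nucleus
#' grayscale SD, and the mean eosin OD in a 2-px perinuclear ring.
#'
#' @param labels Integer label matrix (0 background, labels contiguous 1..N).
#' @param gray Grayscale raster (0..255 scale), same shape.
#' @param h_od,e_od Stain concentration rasters from [separate_stains()].
#' @return A data.frame with one row per label.
#' @export
measure_regions <- function(labels, gray, h_od, e_od) {
  n <- max(labels)
  if (n == 0L) return(empty_records())
  idx <- which(labels > 0L)
  lab <- labels[idx]
  nr <- nrow(labels)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  lf <- factor(lab, levels = seq_len(n))
  area <- as.numeric(table(lf))
  s <- function(v) as.numeric(rowsum(v, lf))
  rbar <- s(rr) / area
  cbar <- s(cc) / area
  mu20 <- s(rr^2) / area - rbar^2 + 1 / 12  # + pixel-square second moment
  mu02 <- s(cc^2) / area - cbar^2 + 1 / 12
  mu11 <- s(rr * cc) / area - rbar * cbar
  tr2 <- (mu20 + mu02) / 2
  det2 <- sqrt(pmax(((mu20 - mu02) / 2)^2 + mu11^2, 0))
  l1 <- pmax(tr2 + det2, 0)
  l2 <- pmax(tr2 - det2, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
  perim <- crofton_perimeters(labels, n)
  circ <- ifelse(perim > 0, 4 * pi * area / perim^2, NA_real_)

  mean_h <- s(h_od[idx]) / area
  gsum <- s(gray[idx]); g2sum <- s(gray[idx]^2)
  sd_int <- sqrt(pmax(g2sum / area - (gsum / area)^2, 0))

  rows_by_lab <- split(rr, lf)
  cols_by_lab <- split(cc, lf)
  solidity <- vapply(seq_len(n), function(k)
    region_solidity(rows_by_lab[[k]], cols_by_lab[[k]]), numeric(1))
  ring_e <- perinuclear_ring_means(labels, e_od, n, width = 2)
  data.frame(label = seq_len(n), area = area, perimeter = perim,
             centroid_row = rbar, centroid_col = cbar,
             major_axis = major, minor_axis = minor,
             eccentricity = ecc, solidity = solidity,
             circularity = circ, mean_h_od = mean_h,
             sd_intensity = sd_int, ring_e_od = ring_e)
}

#' Measure a single nucleus region
#'
#' Convenience wrapper around [measure_regions()] for one binary region.
#'
#' @param region Logical or 0/1 matrix marking the region.
#' @param gray,h_od,e_od Optional intensity rasters (default: the region
#'   itself scaled, so geometry is still measured).
#' @return One-row data.frame of measurements.
#' @export
measure_nucleus <- function(region, gray = NULL, h_od = NULL, e_od = NULL) {
  m <- matrix(as.integer(region != 0), nrow(region), ncol(region))
  if (!any(m > 0)) stop("empty region")
  if (is.null(gray)) gray <- m * 255
  if (is.null(h_od)) h_od <- m
  if (is.null(e_od)) e_od <- m * 0
  measure_regions(m, gray, h_od, e_od)
}

## Mean of `channel` over each nucleus's perinuclear ring: background pixels
## within `width` px of the foreground, assigned to the nearest nucleus by
## Voronoi propagation of the labels.
perinuclear_ring_means <- function(labels, channel, n = max(labels),
                                   width = 2) {
  fg <- labels > 0L
  d_bg <- EBImage::distmap(!fg)          # bg pixel -> distance to nearest fg
  ring <- !fg & as.array(d_bg) <= width
  if (!any(ring)) return(numeric(n))
  vor <- EBImage::propagate(matrix(0, nrow(labels), ncol(labels)),
                            seeds = labels, mask = fg | ring)
  vl <- as.integer(as.array(vor))[ring]
  ev <- channel[ring]
  keep <- vl > 0L
  out <- numeric(n)
  if (any(keep)) {
    sums <- rowsum(ev[keep], vl[keep])
    cnts <- rowsum(rep(1, sum(keep)), vl[keep])
    out[as.integer(rownames(sums))] <- sums[, 1] / cnts[, 1]
  }
  out
}

## Crofton perimeter (4 directions) of every label at once, by classifying
## all 2x2 pixel configurations of the padded label image. Blocks whose
## non-zero entries share one label are histogrammed vectorised; the rare
## blocks where two labels touch are resolved per label in a loop.
## Coefficients match scikit-image's perimeter_crofton(directions = 4).
crofton_perimeters <- function(labels, n = max(labels)) {
  if (n == 0L) return(numeric(0))
  nr <- nrow(labels); nc <- ncol(labels)
  lp <- matrix(0L, nr + 2L, nc + 2L)
  lp[2:(nr + 1L), 2:(nc + 1L)] <- labels
  a <- lp[-(nr + 2L), -(nc + 2L)]; b <- lp[-(nr + 2L), -1L]
  cc <- lp[-1L, -(nc + 2L)];       d <- lp[-1L, -1L]
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
             pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
             pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  mx <- pmax(a, b, cc, d)
  nzblock <- which(mx > 0L)
  av <- a[nzblock]; bv <- b[nzblock]; cv <- cc[nzblock]; dv <- d[nzblock]
  mv <- mx[nzblock]
  uniform <- (av == 0L | av == mv) & (bv == 0L | bv == mv) &
             (cv == 0L | cv == mv) & (dv == 0L | dv == mv)
  perim <- numeric(n)
  if (any(uniform)) {
    code <- (av[uniform] == mv[uniform]) + 2L * (bv[uniform] == mv[uniform]) +
            4L * (cv[uniform] == mv[uniform]) + 8L * (dv[uniform] == mv[uniform])
    contrib <- rowsum(coefs[code + 1L], mv[uniform])
    perim[as.integer(rownames(contrib))] <- contrib[, 1L]
  }
  ## blocks where two labels touch: evaluate each label against the others
  ## treated as background (vectorized via a block-x-label key)
  if (any(!uniform)) {
    mi <- which(!uniform)
    m <- length(mi)
    labv <- c(av[mi], bv[mi], cv[mi], dv[mi])
    bits <- rep(c(1L, 2L, 4L, 8L), each = m)
    key <- (rep(seq_len(m), 4) - 1) * (n + 1) + labv
    pos <- labv > 0L
    codes <- rowsum(bits[pos], key[pos])
    lab_of_key <- as.numeric(rownames(codes)) %% (n + 1)
    contrib2 <- rowsum(coefs[codes[, 1] + 1L], lab_of_key)
    perim[as.integer(rownames(contrib2))] <-
      perim[as.integer(rownames(contrib2))] + contrib2[, 1]
  }
  perim
}

## Solidity = pixel count / rasterized convex-hull area: the convex hull of
## the pixel centres is rasterized back onto the lattice (a pixel belongs to
## the hull if its centre satisfies every hull half-plane), so a convex
## region scores exactly 1.
region_solidity <- function(r, c) {
  n <- length(r)
  if (n <= 3L) return(1)
  h <- grDevices::chull(r, c)
  if (length(h) < 3L) return(1)
  hr <- r[h]; hc <- c[h]
  k <- length(h)
  nxt <- c(seq_len(k)[-1], 1L)
  ## orientation from the signed area so the half-plane test is sign-safe
  orient <- sign(sum(hr * hc[nxt] - hr[nxt] * hc))
  if (orient == 0) return(1)
  gr <- rep(min(r):max(r), times = max(c) - min(c) + 1L)
  gc <- rep(min(c):max(c), each = max(r) - min(r) + 1L)
  inside <- rep(TRUE, length(gr))
  for (e in seq_len(k)) {
    e2 <- nxt[e]
    cross <- (hr[e2] - hr[e]) * (gc - hc[e]) - (hc[e2] - hc[e]) * (gr - hr[e])
    inside <- inside & orient * cross >= -1e-9
    if (!any(inside)) break
  }
  hull_px <- sum(inside)
  if (hull_px == 0L) return(1)
  min(1, n / hull_px)
}
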