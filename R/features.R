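#' Ki-67 proliferative index
#'
#' `PI = positive cells / total cells * 100`, the percentage of tumour
#' cells immunoreactive for Ki-67.
#'
#' @param positive Number of Ki-67-positive cells (`0 <= positive <= total`).
#' @param total Total number of counted cells (`>= 1`).
#' @return The proliferative index in percent.
#' @export
compute_pi <- function(positive, total) {
  if (any(total < 1)) stop("domain error: total cells must be >= 1")
  if (any(positive < 0) || any(positive > total)) {
    stop("domain error: positive cells must be in [0, total]")
  }
  positive / total * 100
}

first_order_stat_names <- function() {
  c("mean", "median", "sd", "variance", "skewness", "kurtosis",
    "min", "max", "range", "p10", "p90", "iqr", "entropy")
}

glcm_prop_names <- function() {
  c("contrast", "dissimilarity", "homogeneity", "energy", "correlation",
    "entropy", "cluster_shade", "cluster_prominence", "max_probability",
    "sum_average", "difference_variance")
}

#' Canonical feature names
#'
#' The fixed, canonical ordering of the multiparametric battery: 24 visual
#' features (7 nuclear morphology measures x mean/SD, 5 nuclear staining
#' features, 5 spatial-pattern features), 171 sub-visual features (13
#' first-order statistics x 3 channels, 11 GLCM properties x 4 angles x 3
#' distances), and the Ki-67 proliferative index.
#'
#' @return Named list with `visual` (24), `subvisual` (171), `ki67` (1).
#' @export
feature_names <- function() {
  morph <- c("area", "perimeter", "major_axis", "minor_axis",
             "circularity", "eccentricity", "solidity")
  visual <- c(as.vector(outer(c("mean", "sd"), morph, paste, sep = "_")),
              c("mean_h_od", "mean_nuclear_sd_intensity", "mean_ring_e_od",
                "nucleus_background_contrast", "chromatin_entropy"),
              c("nuclei_count", "nuclear_density", "mean_nn_distance",
                "sd_nn_distance", "clark_evans_index"))
  fo <- as.vector(vapply(c("gray", "h", "e"), function(ch)
    paste("fo", ch, first_order_stat_names(), sep = "_"), character(13)))
  glcm <- character(0)
  for (p in glcm_prop_names())
    for (a in c(0, 45, 90, 135))
      for (d in c(1, 2, 4))
        glcm <- c(glcm, sprintf("glcm_%s_a%d_d%d", p, a, d))
  list(visual = visual, subvisual = c(fo, glcm), ki67 = "ki67_pi")
}

#' Feature ledger
#'
#' One row per feature column of the model table (196 = 24 visual + 171
#' sub-visual + Ki-67), with its category and a definition string.
#' @return data.frame with columns `name`, `category`, `definition`.
#' @export
feature_ledger <- function() {
  fn <- feature_names()
  defs_visual <- c(
    rep(c("per-nucleus morphology, mean over pooled ROI nuclei",
          "per-nucleus morphology, SD over pooled ROI nuclei"), 7),
    "mean haematoxylin OD inside nuclei",
    "mean within-nucleus grayscale SD",
    "mean eosin OD in a 2-px perinuclear ring",
    "background minus nucleus mean grayscale (per ROI, averaged)",
    "entropy of the within-nucleus haematoxylin histogram (64 bins)",
    "detected nuclei per ROI (averaged over ROIs)",
    "nuclei per px^2",
    "mean nearest-neighbour distance between nucleus centroids (px)",
    "SD of nearest-neighbour distances (px)",
    "Clark-Evans aggregation index (mean NN distance / CSR expectation)")
  rbind(
    data.frame(name = fn$visual, category = "visual", definition = defs_visual),
    data.frame(name = fn$subvisual,
               category = "subvisual",
               definition = c(
                 paste("first-order", rep(first_order_stat_names(), 3), "of",
                       rep(c("grayscale", "haematoxylin OD", "eosin OD"), each = 13)),
                 sprintf("GLCM %s", sub("^glcm_", "",
                                        fn$subvisual[-(1:39)])))),
    data.frame(name = fn$ki67, category = "ihc",
               definition = "Ki-67 proliferative index, percent"))
}

#' First-order intensity statistics of image channels
#'
#' Computes 13 first-order statistics (mean, median, SD, variance,
#' skewness, excess kurtosis, min, max, range, 10th/90th percentile, IQR,
#' 64-bin Shannon entropy) per channel. Skewness and kurtosis of a
#' zero-variance channel are defined as 0.
#'
#' @param channels Named list of numeric matrices/vectors, canonically
#'   `gray`, `h`, `e`.
#' @return Named numeric vector of `13 * length(channels)` values in
#'   canonical order.
#' @export
extract_first_order <- function(channels) {
  out <- lapply(names(channels), function(ch) {
    v <- first_order_stats(as.numeric(channels[[ch]]))
    names(v) <- paste("fo", ch, first_order_stat_names(), sep = "_")
    v
  })
  unlist(out)
}

first_order_stats <- function(x) {
  n <- length(x)
  stopifnot(n > 0)
  m <- mean(x)
  xc <- x - m
  v <- mean(xc^2)                      # population moments
  if (v > 0) {
    skw <- mean(xc^3) / v^1.5
    kur <- mean(xc^4) / v^2 - 3
  } else {
    skw <- 0; kur <- 0
  }
  xs <- sort(x)
  ## type-7 quantiles from the single sorted copy
  q7 <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    xs[lo + 1] + (h - lo) * (xs[pmin(lo + 2, n)] - xs[lo + 1])
  }
  q <- q7(c(0.1, 0.25, 0.5, 0.75, 0.9))
  c(mean = m, median = q[3], sd = sqrt(v * n / max(n - 1, 1)),
    variance = v * n / max(n - 1, 1), skewness = skw, kurtosis = kur,
    min = xs[1], max = xs[n], range = xs[n] - xs[1],
    p10 = q[1], p90 = q[5], iqr = q[4] - q[2],
    entropy = hist_entropy(x, 64L))
}

## Quantize a 0..255 grayscale raster into `levels` equal-width bins over
## the fixed 0..255 range (shift by a whole bin leaves co-occurrence
## displacements intact).
quantize_gray <- function(gray, levels = 32L) {
  q <- floor(gray / 256 * levels) + 1L
  matrix(pmin(pmax(q, 1L), levels), nrow(gray), ncol(gray))
}

## Symmetric, normalized co-occurrence matrix for one displacement.
## Angle convention (matching common GLCM practice): 0 deg = horizontal
## neighbour (0, d), 45 = (-d, d), 90 = (-d, 0), 135 = (-d, -d).
glcm_matrix <- function(q, levels, distance, angle) {
  off <- switch(as.character(angle),
                "0" = c(0L, 1L), "45" = c(-1L, 1L),
                "90" = c(-1L, 0L), "135" = c(-1L, -1L),
                stop("unsupported GLCM angle: ", angle))
  dr <- off[1] * distance; dc <- off[2] * distance
  nr <- nrow(q); nc <- ncol(q)
  if (abs(dr) >= nr || abs(dc) >= nc) {
    stop(sprintf("image (%d x %d) smaller than GLCM displacement %d", nr, nc, distance))
  }
  r1 <- seq_len(nr - abs(dr)) + max(0L, -dr)
  c1 <- seq_len(nc - abs(dc)) + max(0L, -dc)
  i <- q[r1, c1, drop = FALSE]
  j <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate((as.vector(i) - 1L) * levels + as.vector(j), levels * levels)
  m <- matrix(counts, levels, levels, byrow = TRUE)
  m <- m + t(m)
  m / sum(m)
}

glcm_properties <- function(P) {
  L <- nrow(P)
  i <- row(P); j <- col(P)
  mu <- sum(i * P)                     # symmetric: row mean == col mean
  sig2 <- sum((i - mu)^2 * P)
  d <- abs(i - j)
  pd <- as.numeric(rowsum(as.vector(P), as.vector(d)))  # p_{|i-j|}(0..L-1)
  kd <- sort(unique(as.vector(d)))
  mu_d <- sum(kd * pd)
  nz <- P > 0
  c(contrast = sum(P * (i - j)^2),
    dissimilarity = sum(P * d),
    homogeneity = sum(P / (1 + (i - j)^2)),
    energy = sum(P^2),
    correlation = if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else 1,
    entropy = -sum(P[nz] * log2(P[nz])),
    cluster_shade = sum(P * (i + j - 2 * mu)^3),
    cluster_prominence = sum(P * (i + j - 2 * mu)^4),
    max_probability = max(P),
    sum_average = sum(P * (i + j)),
    difference_variance = sum((kd - mu_d)^2 * pd))
}

#' Grey-level co-occurrence texture features
#'
#' Quantizes a grayscale raster to `levels` bins over the fixed 0..255
#' range and computes 11 Haralick-type properties of the symmetric,
#' normalized co-occurrence matrix for every combination of 4 angles and 3
#' displacement distances (132 values). Energy is the angular second
#' moment `sum(P^2)`; correlation of a constant image is defined as 1.
#'
#' @param gray Grayscale raster on the 0..255 scale (at least 8x8 px and
#'   larger than the maximum displacement).
#' @param levels Number of grey levels (default 32).
#' @param distances Displacement distances in px (default 1, 2, 4).
#' @param angles Displacement angles in degrees (default 0, 45, 90, 135).
#' @return Named numeric vector of `11 * length(angles) * length(distances)`
#'   values in canonical order.
#' @export
extract_glcm <- function(gray, levels = 32L, distances = c(1L, 2L, 4L),
                         angles = c(0, 45, 90, 135)) {
  stopifnot(nrow(gray) >= 8, ncol(gray) >= 8)
  q <- quantize_gray(gray, levels)
  props <- glcm_prop_names()
  out <- numeric(0)
  vals <- array(NA_real_, c(length(props), length(angles), length(distances)))
  for (ai in seq_along(angles)) {
    for (di in seq_along(distances)) {
      P <- glcm_matrix(q, levels, distances[di], angles[ai])
      vals[, ai, di] <- glcm_properties(P)
    }
  }
  nm <- character(0)
  res <- numeric(0)
  for (pi_ in seq_along(props)) {
    for (ai in seq_along(angles)) {
      for (di in seq_along(distances)) {
        nm <- c(nm, sprintf("glcm_%s_a%d_d%d", props[pi_], angles[ai], distances[di]))
        res <- c(res, vals[pi_, ai, di])
      }
    }
  }
  stats::setNames(res, nm)
}

## Spatial pattern summary of one ROI from nucleus centroids.
roi_pattern_stats <- function(records, tile_area_px2) {
  n <- nrow(records)
  density <- n / tile_area_px2
  if (n >= 2) {
    dm <- as.matrix(stats::dist(records[, c("centroid_row", "centroid_col")]))
    diag(dm) <- Inf
    nn <- apply(dm, 1, min)
    mean_nn <- mean(nn); sd_nn <- stats::sd(nn)
    ce <- mean_nn / (0.5 / sqrt(density))
  } else {
    mean_nn <- NA_real_; sd_nn <- NA_real_; ce <- NA_real_
  }
  c(nuclei_count = n, nuclear_density = density,
    mean_nn_distance = mean_nn, sd_nn_distance = sd_nn,
    clark_evans_index = ce)
}

#' Extract the 24 visual features of a case
#'
#' Aggregates per-nucleus records pooled across the selected ROIs
#' (morphology mean/SD), per-ROI staining summaries, and per-ROI spatial
#' pattern statistics (nuclei count, density, nearest-neighbour distances,
#' Clark-Evans index; averaged over ROIs).
#'
#' @param roi_results List of `nuclei_seg` objects (one per selected ROI),
#'   each carrying `records`, `labels`, `h_od` and the source tile's
#'   grayscale raster under `$gray` (as produced inside
#'   [build_feature_table()]; [segment_nuclei()] output plus `gray`).
#' @return Named numeric vector of length 24 in canonical order.
#' @export
extract_visual <- function(roi_results) {
  records <- do.call(rbind, lapply(roi_results, `[[`, "records"))
  if (is.null(records) || nrow(records) < 2) {
    stop("fewer than 2 nuclei across selected ROIs; lower the detection ",
         "threshold or select denser ROIs")
  }
  morph <- c("area", "perimeter", "major_axis", "minor_axis",
             "circularity", "eccentricity", "solidity")
  out <- numeric(0)
  for (m in morph) {
    out <- c(out, mean(records[[m]]), stats::sd(records[[m]]))
  }
  per_roi <- vapply(roi_results, function(rr) {
    labs <- rr$labels
    fg <- labs > 0L
    contrast <- if (any(fg) && any(!fg)) mean(rr$gray[!fg]) - mean(rr$gray[fg]) else 0
    chrom <- if (any(fg)) hist_entropy(rr$h_od[fg], 64L) else 0
    c(contrast, chrom, roi_pattern_stats(rr$records, length(labs)))
  }, numeric(7))
  stain <- c(mean(records$mean_h_od), mean(records$sd_intensity),
             mean(records$ring_e_od),
             mean(per_roi[1, ]), mean(per_roi[2, ]))
  patt <- rowMeans(per_roi[3:7, , drop = FALSE], na.rm = TRUE)
  patt[!is.finite(patt)] <- 0
  stats::setNames(c(out, stain, patt), feature_names()$visual)
}

#' Extract the 171 sub-visual features of a case
#'
#' First-order statistics of the grayscale, haematoxylin-OD and eosin-OD
#' channels plus GLCM texture of the grayscale channel, computed per ROI
#' tile and averaged across the selected ROIs (one vector per patient).
#'
#' @inheritParams extract_visual
#' @param levels,distances,angles GLCM settings, see [extract_glcm()].
#' @return Named numeric vector of length 171 in canonical order.
#' @export
extract_subvisual <- function(roi_results, levels = 32L,
                              distances = c(1L, 2L, 4L),
                              angles = c(0, 45, 90, 135)) {
  per_roi <- vapply(roi_results, function(rr) {
    fo <- extract_first_order(list(gray = rr$gray, h = rr$h_od, e = rr$e_od))
    gl <- extract_glcm(rr$gray, levels, distances, angles)
    c(fo, gl)
  }, numeric(171))
  stats::setNames(rowMeans(per_roi), feature_names()$subvisual)
}

#' Build the per-case feature table of a cohort
#'
#' Runs the per-case image pipeline (tiling, watershed segmentation of each
#' tile, top-k ROI selection, visual + sub-visual extraction) and joins the
#' Ki-67 proliferative index, producing one row per case with 196 feature
#' columns plus `case_id` and `grade`. Failed cases are collected in a skip
#' report (attribute `"skipped"`), not silently dropped.
#'
#' @param cohort A `cohort_manifest` ([generate_cohort()]/[read_cohort()]).
#' @param tile_size_px Tile size for ROI partitioning (default 512).
#' @param roi_k Number of ROIs per slide (default 5).
#' @param params [seg_params()] used for all tiles.
#' @param glcm_levels,glcm_distances,glcm_angles GLCM settings.
#' @param out_csv Optional path; when given the table is written as CSV.
#' @param verbose Log per-case progress.
#' @return data.frame (`feature_table`) with columns `case_id`, `grade`
#'   (factor II/III/IV), 24 visual, 171 sub-visual and `ki67_pi`.
#' @export
build_feature_table <- function(cohort, tile_size_px = 512, roi_k = 5L,
                                params = seg_params(),
                                glcm_levels = 32L,
                                glcm_distances = c(1L, 2L, 4L),
                                glcm_angles = c(0, 45, 90, 135),
                                out_csv = NULL, verbose = FALSE) {
  old_verb <- options(gliograde.verbose = verbose)
  on.exit(options(old_verb))
  cases <- cohort$cases
  fn <- feature_names()
  rows <- vector("list", nrow(cases))
  skipped <- list()
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    res <- tryCatch({
      img <- read_rgb_image(file.path(cohort$dir, cs$image_path))
      grid <- partition_tiles(img, tile_size_px)
      segs <- segment_tiles(img, grid, params, measure = FALSE)
      roi <- select_rois(segs$counts, roi_k, tile_size_px)
      ## tiles are stored row-major; measure only the selected ROIs
      sel_idx <- roi$entries$tile_row * grid$n_cols + roi$entries$tile_col + 1L
      roi_results <- lapply(sel_idx, function(k) {
        rr <- segs$results[[k]]
        tile <- get_tile(img, grid, (k - 1L) %/% grid$n_cols, (k - 1L) %% grid$n_cols)
        rr$gray <- rgb_to_gray(tile)
        if (is.null(rr$records)) {
          rr$records <- if (rr$n_nuclei > 0)
            measure_regions(rr$labels, rr$gray, rr$h_od, rr$e_od)
          else empty_records()
        }
        rr
      })
      vis <- extract_visual(roi_results)
      sub <- extract_subvisual(roi_results, glcm_levels, glcm_distances, glcm_angles)
      ki <- compute_pi(cs$ki67_positive, cs$ki67_total)
      data.frame(case_id = cs$case_id, grade = cs$grade,
                 as.list(c(vis, sub, ki67_pi = ki)),
                 check.names = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[cs$case_id]] <- conditionMessage(res)
    } else {
      rows[[i]] <- res
    }
    if (verbose && i %% 10 == 0) gg_log("features: %d/%d cases", i, nrow(cases))
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  tab$grade <- factor(tab$grade, levels = grade_levels())
  stopifnot(identical(setdiff(colnames(tab), c("case_id", "grade")),
                      c(fn$visual, fn$subvisual, fn$ki67)))
  attr(tab, "skipped") <- skipped
  if (length(skipped)) {
    gg_log("build_feature_table: %d case(s) skipped: %s", length(skipped),
           paste(names(skipped), collapse = ", "))
  }
  if (!is.null(out_csv)) write_feature_table(tab, out_csv)
  tab
}

#' @rdname build_feature_table
#' @param table A feature table.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  tab <- table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) signif(x, 12))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname build_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  tab$grade <- factor(tab$grade, levels = grade_levels())
  tab
}
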