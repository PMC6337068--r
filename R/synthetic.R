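#' Grade profile for the synthetic cohort generator
#'
#' A grade profile holds the generative parameters of one WHO glioma grade:
#' how many nuclei a tile carries, how large and pleomorphic they are, how
#' darkly they stain, how strongly they cluster, and the Ki-67 proliferative
#' index distribution of the grade.
#'
#' @param grade One of `"II"`, `"III"`, `"IV"`.
#' @param nuclei_per_tile_mean Poisson mean of the nucleus count per tile at
#'   the profile's reference tile size.
#' @param nucleus_radius_mean_px,nucleus_radius_sd_px Mean/SD (px) of the
#'   equivalent nuclear radius (radii are truncated below at 2.5 px).
#' @param eccentricity_max Upper bound of the uniform eccentricity draw in
#'   `[0, 1)`; larger values give more pleomorphic, elongated nuclei.
#' @param stain_darkness_mean Mean haematoxylin concentration of a nucleus
#'   (optical-density units, `[0, 1]`); higher = more hyperchromatic.
#' @param cluster_fraction Fraction of nuclei placed around cluster centres
#'   instead of uniformly, in `[0, 1]`.
#' @param ki67_pi_mean_pct,ki67_pi_sd_pct Mean/SD (percent) of the grade's
#'   Ki-67 proliferative index.
#' @param stain_darkness_sd SD of the per-nucleus stain darkness jitter.
#' @param cluster_sd_px Spatial SD (px) of nuclei around a cluster centre.
#' @param noise_sd Pixel Gaussian noise SD on the 0-1 intensity scale.
#' @return An object of class `grade_profile`.
#' @seealso [default_grade_profiles()]
#' @export
grade_profile <- function(grade,
                          nuclei_per_tile_mean,
                          nucleus_radius_mean_px,
                          nucleus_radius_sd_px,
                          eccentricity_max,
                          stain_darkness_mean,
                          cluster_fraction,
                          ki67_pi_mean_pct,
                          ki67_pi_sd_pct,
                          stain_darkness_sd = 0.08,
                          cluster_sd_px = 25,
                          noise_sd = 2 / 255) {
  grade <- match.arg(grade, grade_levels())
  p <- list(grade = grade,
            nuclei_per_tile_mean = nuclei_per_tile_mean,
            nucleus_radius_mean_px = nucleus_radius_mean_px,
            nucleus_radius_sd_px = nucleus_radius_sd_px,
            eccentricity_max = eccentricity_max,
            stain_darkness_mean = stain_darkness_mean,
            cluster_fraction = cluster_fraction,
            ki67_pi_mean_pct = ki67_pi_mean_pct,
            ki67_pi_sd_pct = ki67_pi_sd_pct,
            stain_darkness_sd = stain_darkness_sd,
            cluster_sd_px = cluster_sd_px,
            noise_sd = noise_sd)
  validate_grade_profile(p)
  class(p) <- "grade_profile"
  p
}

#' @rdname grade_profile
#' @export
grade_levels <- function() c("II", "III", "IV")

validate_grade_profile <- function(p) {
  stopifnot(p$nuclei_per_tile_mean >= 0)
  if (p$nucleus_radius_sd_px < 0 || p$ki67_pi_sd_pct < 0) {
    stop("configuration error: negative SD in grade profile for grade ", p$grade)
  }
  frac_ok <- function(x, lo = 0, hi = 1) x >= lo && x <= hi
  if (!frac_ok(p$cluster_fraction) ||
      !frac_ok(p$stain_darkness_mean) ||
      p$eccentricity_max < 0 || p$eccentricity_max >= 1) {
    stop("configuration error: fraction/eccentricity out of range in grade profile for grade ",
         p$grade)
  }
  if (p$ki67_pi_mean_pct < 0 || p$ki67_pi_mean_pct > 100) {
    stop("configuration error: ki67_pi_mean_pct out of [0, 100]")
  }
  invisible(TRUE)
}

#' Default grade profiles of the synthetic cohort
#'
#' Generative parameters per grade at the 512-px desk-scale tile. Densities,
#' sizes, pleomorphism, chromasia and clustering increase with grade so that
#' grades are learnable but overlapping; Ki-67 proliferative index
#' distributions are 3.0 +/- 2.1 % (II), 11.8 +/- 3.4 % (III) and
#' 15.8 +/- 7.4 % (IV), the accepted per-grade norms for gliomas.
#'
#' | grade | nuclei/tile | radius (px) | ecc max | darkness | cluster frac | Ki-67 PI (%) |
#' |-------|-------------|-------------|---------|----------|--------------|--------------|
#' | II    | 150         | 6 +/- 1     | 0.3     | 0.50     | 0.1          | 3.0 +/- 2.1  |
#' | III   | 300         | 7 +/- 2     | 0.6     | 0.60     | 0.3          | 11.8 +/- 3.4 |
#' | IV    | 450         | 8 +/- 3     | 0.8     | 0.75     | 0.5          | 15.8 +/- 7.4 |
#'
#' @return Named list of three [grade_profile()] objects (`II`, `III`, `IV`).
#' @export
default_grade_profiles <- function() {
  list(
    II = grade_profile("II", 150, 6, 1, 0.3, 0.50, 0.1, 3.0, 2.1),
    III = grade_profile("III", 300, 7, 2, 0.6, 0.60, 0.3, 11.8, 3.4),
    IV = grade_profile("IV", 450, 8, 3, 0.8, 0.75, 0.5, 15.8, 7.4)
  )
}

#' Sample a tile's ground-truth nucleus layout (no rasterization)
#'
#' Draws the nucleus population of one tile: `N ~ Poisson(mean)` nuclei with
#' truncated-normal radii, uniform eccentricities and orientations, stain
#' darkness jitter, and positions that are a mixture of clustered (around
#' Poisson-thinned cluster centres) and uniform placement. Overlap control:
#' with `overlap = "capped"` a candidate centre is re-drawn unless its
#' distance to every accepted nucleus is at least half the sum of semi-major
#' axes (caps pairwise area overlap at roughly 30%); with `overlap = "none"`
#' boundaries must be separated by at least `gap_px` and nuclei lie fully
#' inside the tile. Candidates that cannot be placed within 60 attempts are
#' dropped (so the returned layout is exactly what will be rendered).
#'
#' @param profile A [grade_profile()].
#' @param size_px Tile side length in pixels (`>= 64`).
#' @param seed Integer seed.
#' @param overlap `"capped"` (default) or `"none"`.
#' @param gap_px Minimum boundary gap (px) in `"none"` mode.
#' @return A data.frame with one row per nucleus: `row`, `col` (centre, px),
#'   `radius` (equivalent radius), `semi_major`, `semi_minor`, `ecc`,
#'   `theta` (orientation, radians), `darkness`.
#' @export
sample_tile_layout <- function(profile, size_px, seed,
                               overlap = c("capped", "none"), gap_px = 4) {
  overlap <- match.arg(overlap)
  stopifnot(size_px >= 64)
  with_seed(seed, {
    n <- stats::rpois(1, profile$nuclei_per_tile_mean)
    if (n == 0L) {
      return(data.frame(row = numeric(0), col = numeric(0), radius = numeric(0),
                        semi_major = numeric(0), semi_minor = numeric(0),
                        ecc = numeric(0), theta = numeric(0), darkness = numeric(0)))
    }
    r <- pmax(stats::rnorm(n, profile$nucleus_radius_mean_px,
                           profile$nucleus_radius_sd_px), 2.5)
    ecc <- stats::runif(n, 0, profile$eccentricity_max)
    theta <- stats::runif(n, 0, pi)
    ## Area-preserving ellipse: semi_major * semi_minor = r^2.
    b <- r * (1 - ecc^2)^(1 / 4)
    a <- r^2 / b
    darkness <- pmin(pmax(stats::rnorm(n, profile$stain_darkness_mean,
                                       profile$stain_darkness_sd), 0.1), 1.2)
    n_clustered <- round(n * profile$cluster_fraction)
    n_centres <- max(1L, round(n_clustered / 15))
    ccol <- stats::runif(n_centres, 1, size_px)
    crow <- stats::runif(n_centres, 1, size_px)
    is_clustered <- seq_len(n) <= n_clustered

    row <- col <- amax <- numeric(n)
    n_acc <- 0L
    kept <- integer(0)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in 1:60) {
        if (is_clustered[i]) {
          k <- sample.int(n_centres, 1)
          ri <- crow[k] + stats::rnorm(1, 0, profile$cluster_sd_px)
          ci <- ccol[k] + stats::rnorm(1, 0, profile$cluster_sd_px)
          if (overlap == "none") {
            ri <- min(max(ri, a[i] + 2), size_px - a[i] - 2)
            ci <- min(max(ci, a[i] + 2), size_px - a[i] - 2)
          } else {
            ri <- min(max(ri, 1), size_px)
            ci <- min(max(ci, 1), size_px)
          }
        } else if (overlap == "none") {
          ri <- stats::runif(1, a[i] + 2, size_px - a[i] - 2)
          ci <- stats::runif(1, a[i] + 2, size_px - a[i] - 2)
        } else {
          ri <- stats::runif(1, 1, size_px)
          ci <- stats::runif(1, 1, size_px)
        }
        if (n_acc == 0L) { placed <- TRUE; break }
        acc <- seq_len(n_acc)
        min_sep <- if (overlap == "none") amax[acc] + a[i] + gap_px
                   else 0.5 * (amax[acc] + a[i])
        if (all((row[acc] - ri)^2 + (col[acc] - ci)^2 >= min_sep^2)) {
          placed <- TRUE
          break
        }
      }
      if (placed) {
        n_acc <- n_acc + 1L
        row[n_acc] <- ri; col[n_acc] <- ci; amax[n_acc] <- a[i]
        kept <- c(kept, i)
      }
    }
    row <- row[seq_len(n_acc)]; col <- col[seq_len(n_acc)]
    data.frame(row = row, col = col, radius = r[kept],
               semi_major = a[kept], semi_minor = b[kept],
               ecc = ecc[kept], theta = theta[kept], darkness = darkness[kept])
  })
}

#' Render a synthetic H&E-like tile
#'
#' Rasterizes a sampled nucleus layout into an 8-bit RGB tile. Nuclei are
#' filled ellipses carrying haematoxylin concentration equal to their stain
#' darkness; the background carries a smooth eosin-like pink texture
#' (baseline 0.15 OD plus Gaussian-blurred noise). Concentrations are
#' converted to RGB through the Beer-Lambert law with the H&E stain vectors,
#' Gaussian pixel noise is added, and the result is quantized to 8 bits (so
#' an in-memory tile round-trips a PNG byte-identically).
#'
#' @inheritParams sample_tile_layout
#' @return List with `image` (8-bit RGB array `size x size x 3`, integer
#'   0..255), `truth` (the layout data.frame from [sample_tile_layout()]),
#'   and `n_nuclei` (`nrow(truth)`).
#' @export
render_tile <- function(profile, size_px, seed,
                        overlap = c("capped", "none"), gap_px = 4) {
  overlap <- match.arg(overlap)
  truth <- sample_tile_layout(profile, size_px, seed, overlap, gap_px)
  sm <- he_stain_matrix()
  img <- with_seed(derive_seed(seed, 777001), {
    hconc <- matrix(0, size_px, size_px)
    for (i in seq_len(nrow(truth))) {
      a <- truth$semi_major[i]; b <- truth$semi_minor[i]
      th <- truth$theta[i]
      r0 <- max(1L, floor(truth$row[i] - a)); r1 <- min(size_px, ceiling(truth$row[i] + a))
      c0 <- max(1L, floor(truth$col[i] - a)); c1 <- min(size_px, ceiling(truth$col[i] + a))
      rs <- r0:r1; cs <- c0:c1
      dr <- outer(rs - truth$row[i], rep(1, length(cs)))
      dc <- outer(rep(1, length(rs)), cs - truth$col[i])
      u <- (dr * cos(th) + dc * sin(th)) / a
      v <- (-dr * sin(th) + dc * cos(th)) / b
      inside <- u^2 + v^2 <= 1
      blk <- hconc[rs, cs, drop = FALSE]
      blk[inside] <- pmax(blk[inside], truth$darkness[i])
      hconc[rs, cs] <- blk
    }
    ## smooth eosin texture: coarse Gaussian field, bilinearly upsampled
    econc <- pmax(0.15 + smooth_noise_field(size_px, cell = 16, sd = 0.05), 0)
    pix_noise <- matrix(stats::rnorm(size_px^2, 0, profile$noise_sd), size_px)
    rgb <- array(0, c(size_px, size_px, 3L))
    for (k in 1:3) {
      ch <- 10^-(hconc * sm["h", k] + econc * sm["e", k]) + pix_noise
      rgb[, , k] <- as.integer(round(pmin(pmax(ch, 0), 1) * 255))
    }
    storage.mode(rgb) <- "integer"
    rgb
  })
  list(image = img, truth = truth, n_nuclei = nrow(truth))
}

#' Sample Ki-67 immunohistochemistry counts for one case
#'
#' Emulates the Ki-67 counting protocol: the number of examined tumour cells
#' is uniform on `[1000, 3000]` (at least 1000 cells are always counted),
#' the case's proliferative index (percent) is drawn from the grade's normal
#' distribution truncated to `[0, 100]`, and the positive count is binomial.
#'
#' @inheritParams sample_tile_layout
#' @return List with `positive` and `total` integer counts
#'   (`positive <= total`).
#' @export
sample_ki67_counts <- function(profile, seed) {
  with_seed(seed, {
    total <- sample(1000:3000, 1)
    pi_pct <- min(max(stats::rnorm(1, profile$ki67_pi_mean_pct,
                                   profile$ki67_pi_sd_pct), 0), 100)
    positive <- stats::rbinom(1, total, pi_pct / 100)
    list(positive = positive, total = total)
  })
}

#' Cohort configuration for the synthetic generator
#'
#' @param n_per_grade Named integer vector of case counts per grade;
#'   defaults to the study composition 49/45/52 (146 cases).
#' @param tile_size_px Tile side (px); desk-scale default 512. Real-slide
#'   tiles are 5120 px (see [real_slide_tile_px()]).
#' @param slide_tiles Integer `c(rows, cols)` of tiles per synthetic slide.
#' @param profiles Named list of [grade_profile()] objects.
#' @param image_format `"png"` (default) or `"tiff"`.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_grade = c(II = 49, III = 45, IV = 52),
                          tile_size_px = 512,
                          slide_tiles = c(2, 2),
                          profiles = default_grade_profiles(),
                          image_format = c("png", "tiff")) {
  image_format <- match.arg(image_format)
  stopifnot(all(grade_levels() %in% names(n_per_grade)),
            all(n_per_grade >= 0),
            tile_size_px >= 64,
            length(slide_tiles) == 2L, all(slide_tiles >= 1))
  for (g in grade_levels()) validate_grade_profile(profiles[[g]])
  structure(list(n_per_grade = n_per_grade[grade_levels()],
                 tile_size_px = tile_size_px,
                 slide_tiles = as.integer(slide_tiles),
                 profiles = profiles,
                 image_format = image_format),
            class = "cohort_config")
}

#' Tile size used for real whole-slide images
#'
#' Fixed-size high-resolution tiles of 5120 x 5120 px; the desk-scale
#' synthetic default is 512 px with all geometry scale-free.
#' @return 5120L
#' @export
real_slide_tile_px <- function() 5120L

#' Generate a synthetic glioma cohort
#'
#' Generates `sum(n_per_grade)` cases (default 146 = 49 grade II + 45 grade
#' III + 52 grade IV). Each case gets a slide image assembled from
#' `slide_tiles` rendered tiles (so slide dimensions are an integer multiple
#' of the tile size), a Ki-67 count pair, and a per-case seed derived
#' deterministically as `master_seed + case_index`. Images, a per-case JSON
#' ground-truth sidecar (nucleus centres, radii, orientations), and a CSV
#' manifest (`case_id, grade, image_path, ki67_positive, ki67_total, seed`)
#' are written under `out_dir`. Re-running with the same configuration and
#' seed reproduces byte-identical files.
#'
#' @param config A [cohort_config()].
#' @param master_seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @param write_truth Write ground-truth JSON sidecars (default TRUE).
#' @return Invisibly, a `cohort_manifest`: list with `cases` (the manifest
#'   data.frame), `counts_by_grade`, `master_seed`, `config`, `dir`.
#' @export
generate_cohort <- function(config = cohort_config(), master_seed = 1L,
                            out_dir, write_truth = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n_total <- sum(config$n_per_grade)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grades <- rep(grade_levels(), times = config$n_per_grade)
  rows <- vector("list", n_total)
  ts <- config$tile_size_px
  st <- config$slide_tiles
  for (i in seq_len(n_total)) {
    g <- grades[i]
    prof <- config$profiles[[g]]
    case_seed <- derive_seed(master_seed, i)
    case_id <- sprintf("case_%03d_%s", i, g)
    img <- array(0L, c(st[1] * ts, st[2] * ts, 3L))
    truth_list <- list()
    t_idx <- 0L
    for (tr in seq_len(st[1])) {
      for (tc in seq_len(st[2])) {
        t_idx <- t_idx + 1L
        tile <- render_tile(prof, ts, derive_seed(case_seed, 1000L * t_idx))
        img[(tr - 1L) * ts + seq_len(ts), (tc - 1L) * ts + seq_len(ts), ] <- tile$image
        if (nrow(tile$truth)) {
          tt <- tile$truth
          tt$row <- tt$row + (tr - 1L) * ts
          tt$col <- tt$col + (tc - 1L) * ts
          truth_list[[t_idx]] <- tt
        }
      }
    }
    ki <- sample_ki67_counts(prof, derive_seed(case_seed, 500009L))
    img_file <- file.path(out_dir, paste0(case_id, ".", config$image_format))
    write_rgb_image(img, img_file)
    if (write_truth) {
      truth <- if (length(truth_list)) do.call(rbind, truth_list) else
        data.frame(row = numeric(0), col = numeric(0))
      jsonlite::write_json(truth, file.path(out_dir, paste0(case_id, "_truth.json")),
                           digits = NA, dataframe = "columns")
    }
    rows[[i]] <- data.frame(case_id = case_id, grade = g,
                            image_path = basename(img_file),
                            ki67_positive = ki$positive, ki67_total = ki$total,
                            seed = case_seed, stringsAsFactors = FALSE)
  }
  cases <- if (n_total) do.call(rbind, rows) else
    data.frame(case_id = character(0), grade = character(0),
               image_path = character(0), ki67_positive = integer(0),
               ki67_total = integer(0), seed = integer(0))
  manifest <- structure(list(cases = cases,
                             counts_by_grade = stats::setNames(
                               as.integer(config$n_per_grade), grade_levels()),
                             master_seed = master_seed,
                             config = config, dir = out_dir),
                        class = "cohort_manifest")
  utils::write.csv(cases, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort manifest written by [generate_cohort()]
#' @param dir Cohort directory containing `manifest.csv`.
#' @return A `cohort_manifest` list (without the generating config).
#' @export
read_cohort <- function(dir) {
  cases <- utils::read.csv(file.path(dir, "manifest.csv"),
                           stringsAsFactors = FALSE)
  cnt <- table(factor(cases$grade, grade_levels()))
  structure(list(cases = cases,
                 counts_by_grade = stats::setNames(as.integer(cnt), grade_levels()),
                 master_seed = NA_integer_, config = NULL, dir = dir),
            class = "cohort_manifest")
}

## Smooth random field: iid normal values on a coarse grid of spacing
## `cell` px, bilinearly interpolated to a size x size matrix.
smooth_noise_field <- function(size, cell = 16, sd = 0.05) {
  ng <- ceiling(size / cell) + 1L
  g <- matrix(stats::rnorm(ng * ng, 0, sd), ng, ng)
  pos <- (seq_len(size) - 1) / cell
  i0 <- pmin(floor(pos) + 1L, ng - 1L)
  fr <- pos - (i0 - 1L)
  ## interpolate rows then columns
  rows <- g[i0, , drop = FALSE] * (1 - fr) + g[i0 + 1L, , drop = FALSE] * fr
  rows[, i0, drop = FALSE] * rep(1 - fr, each = size) +
    rows[, i0 + 1L, drop = FALSE] * rep(fr, each = size)
}

write_rgb_image <- function(img, path) {
  x <- img / 255
  if (grepl("\\.tiff?$", path)) {
    ## tiff::writeTIFF expects [0,1] array
    requireNamespace("tiff", quietly = TRUE) ||
      stop("tiff package required for TIFF output")
    tiff::writeTIFF(x, path, bits.per.sample = 8L)
  } else {
    png::writePNG(x, path)
  }
}

#' Read an 8-bit RGB image (PNG or TIFF)
#' @param path Image file path.
#' @return Integer array `H x W x 3` with values 0..255.
#' @export
read_rgb_image <- function(path) {
  x <- if (grepl("\\.tiff?$", path)) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  array(as.integer(round(x * 255)), dim(x))
}
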