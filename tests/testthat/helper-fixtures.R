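# Shared fixtures built in code. Small profiles keep unit tests fast; the
# full-scale defaults are exercised in test-acceptance.R.

# moderate-density, near-round test profile (tile 256 px)
test_profile <- function(grade = "II", n_mean = 40, radius = 6, radius_sd = 1,
                         ecc = 0.3, dark = 0.5, cluster = 0.1,
                         pi_mean = 3.0, pi_sd = 2.1, dark_sd = 0.05) {
  grade_profile(grade, n_mean, radius, radius_sd, ecc, dark, cluster,
                pi_mean, pi_sd, stain_darkness_sd = dark_sd)
}

# calibration profile for count-oracle tests: well-separated, round, crisp
calib_profile <- function(n_mean = 50) {
  grade_profile("II", n_mean, 7, 0.7, 0.3, 0.5, 0, 3.0, 2.1,
                stain_darkness_sd = 0.05)
}

# render an RGB image directly from stain concentration fields
stain_image <- function(hconc, econc = 0.15) {
  sm <- he_stain_matrix()
  d <- dim(hconc)
  if (length(econc) == 1) econc <- matrix(econc, d[1], d[2])
  rgb <- array(0, c(d[1], d[2], 3L))
  for (k in 1:3) {
    rgb[, , k] <- 10^-(hconc * sm["h", k] + econc * sm["e", k])
  }
  array(as.integer(round(pmin(pmax(rgb, 0), 1) * 255)), dim(rgb))
}

# binary disk / ellipse rasters
disk_mask <- function(r, size = 2 * r + 11, cr = (size + 1) / 2, cc = cr) {
  outer(seq_len(size), seq_len(size),
        function(i, j) (i - cr)^2 + (j - cc)^2 <= r^2)
}

ellipse_mask <- function(a, b, theta = 0, size = 2 * a + 11) {
  ctr <- (size + 1) / 2
  outer(seq_len(size), seq_len(size), function(i, j) {
    u <- ((i - ctr) * cos(theta) + (j - ctr) * sin(theta)) / a
    v <- (-(i - ctr) * sin(theta) + (j - ctr) * cos(theta)) / b
    u^2 + v^2 <= 1
  })
}

# synthetic 196-column feature table with planted grade effects; used where a
# real image cohort would be too slow. Effects are planted on named columns.
fake_feature_table <- function(n_per_grade = 20, seed = 1,
                               informative = c("nuclei_count", "mean_area",
                                               "fo_gray_mean",
                                               "glcm_contrast_a0_d1",
                                               "sd_perimeter"),
                               effect = 2) {
  fn <- feature_names()
  all_feats <- c(fn$visual, fn$subvisual, fn$ki67)
  grades <- rep(grade_levels(), each = n_per_grade)
  n <- length(grades)
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * length(all_feats)), n,
                dimnames = list(NULL, all_feats))
    g <- as.integer(factor(grades, grade_levels()))
    for (f in informative) x[, f] <- x[, f] + effect * g
    x[, "ki67_pi"] <- pmax(rnorm(n, 3 * g, 2), 0)
    tab <- data.frame(case_id = sprintf("case_%03d", seq_len(n)),
                      grade = factor(grades, grade_levels()),
                      x, check.names = FALSE)
    tab
  })
}

# tiny real image cohort, generated once per test run and cached on disk
tiny_cohort <- local({
  manifest <- NULL
  function(n = c(II = 3, III = 3, IV = 3), seed = 11) {
    if (is.null(manifest)) {
      profs <- list(II = test_profile("II", 25, pi_mean = 3.0, pi_sd = 2.1),
                    III = test_profile("III", 50, radius = 6.5, ecc = 0.5,
                                       dark = 0.6, cluster = 0.3,
                                       pi_mean = 11.8, pi_sd = 3.4),
                    IV = test_profile("IV", 75, radius = 7, ecc = 0.7,
                                      dark = 0.7, cluster = 0.5,
                                      pi_mean = 15.8, pi_sd = 7.4))
      cc <- cohort_config(n_per_grade = n, tile_size_px = 128,
                          slide_tiles = c(2, 2), profiles = profs)
      manifest <<- generate_cohort(cc, seed,
                                   file.path(tempdir(), "gliograde-tiny-cohort"))
    }
    manifest
  }
})

# brute-force GLCM oracle: enumerate all pixel pairs at one displacement,
# build the symmetric normalized matrix, evaluate properties from the
# textbook formulas. Independent of the package implementation.
glcm_brute <- function(gray, levels, distance, angle) {
  q <- floor(gray / 256 * levels) + 1
  q[q > levels] <- levels
  off <- switch(as.character(angle),
                "0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
                "135" = c(-1, -1))
  dr <- off[1] * distance; dc <- off[2] * distance
  cm <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(ncol(q))) {
      i2 <- i + dr; j2 <- j + dc
      if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q)) {
        cm[q[i, j], q[i2, j2]] <- cm[q[i, j], q[i2, j2]] + 1
      }
    }
  }
  cm <- cm + t(cm)
  P <- cm / sum(cm)
  i <- row(P); j <- col(P)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  pd <- sapply(0:(levels - 1), function(k) sum(P[abs(i - j) == k]))
  mu_d <- sum((0:(levels - 1)) * pd)
  nz <- P > 0
  c(contrast = sum(P * (i - j)^2),
    dissimilarity = sum(P * abs(i - j)),
    homogeneity = sum(P / (1 + (i - j)^2)),
    energy = sum(P^2),
    correlation = if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else 1,
    entropy = -sum(P[nz] * log2(P[nz])),
    cluster_shade = sum(P * (i + j - 2 * mu)^3),
    cluster_prominence = sum(P * (i + j - 2 * mu)^4),
    max_probability = max(P),
    sum_average = sum(P * (i + j)),
    difference_variance = sum(((0:(levels - 1)) - mu_d)^2 * pd))
}
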