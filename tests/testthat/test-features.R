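test_that("the proliferative index is the exact positive fraction in percent", {
  expect_equal(compute_pi(200, 1000), 20.0)
  expect_equal(compute_pi(0, 1500), 0.0)
  expect_equal(compute_pi(1000, 1000), 100.0)
  expect_error(compute_pi(5, 0), "total")
  expect_error(compute_pi(11, 10), "positive")
})

test_that("the feature battery has the canonical dimensions and names", {
  fn <- feature_names()
  expect_length(fn$visual, 24)
  expect_length(fn$subvisual, 171)
  expect_length(fn$ki67, 1)
  # the features named in per-case explanations are present
  expect_true(all(c("sd_perimeter", "sd_major_axis", "nuclei_count")
                  %in% fn$visual))
  ledger <- feature_ledger()
  expect_equal(nrow(ledger), 196)
  expect_false(any(duplicated(ledger$name)))
  expect_equal(as.vector(table(ledger$category)[c("visual", "subvisual", "ihc")]),
               c(24L, 171L, 1L))
})

test_that("first-order statistics handle constant and symmetric inputs", {
  v <- gliograde:::first_order_stats(rep(7, 100))
  expect_equal(unname(v[c("mean", "sd", "range", "entropy", "skewness",
                          "kurtosis")]),
               c(7, 0, 0, 0, 0, 0))
  # two-value channel, 50% each: entropy is exactly 1 bit
  two <- gliograde:::first_order_stats(rep(c(10, 200), 50))
  expect_equal(unname(two["entropy"]), 1)
  # symmetric sample: skewness ~ 0
  sym <- gliograde:::first_order_stats(rep(c(-3, -1, 0, 1, 3), 200))
  expect_equal(unname(sym["skewness"]), 0, tolerance = 0.05)
  # quantile statistics match stats::quantile type 7
  withr::with_seed(1, x <- rnorm(501))
  fo <- gliograde:::first_order_stats(x)
  expect_equal(unname(fo[c("median", "p10", "p90")]),
               unname(quantile(x, c(0.5, 0.1, 0.9))))
  expect_equal(unname(fo["iqr"]), unname(diff(quantile(x, c(0.25, 0.75)))))
  # canonical layout: 13 stats x 3 channels
  out <- extract_first_order(list(gray = matrix(1:16, 4), h = matrix(0, 4, 4),
                                  e = matrix(1, 4, 4)))
  expect_length(out, 39)
  expect_equal(names(out)[1], "fo_gray_mean")
})

test_that("GLCM identities hold on a constant image", {
  g <- extract_glcm(matrix(100, 16, 16))
  expect_length(g, 132)
  for (a in c(0, 45, 90, 135)) {
    for (d in c(1, 2, 4)) {
      expect_equal(unname(g[sprintf("glcm_contrast_a%d_d%d", a, d)]), 0)
      expect_equal(unname(g[sprintf("glcm_homogeneity_a%d_d%d", a, d)]), 1)
      expect_equal(unname(g[sprintf("glcm_energy_a%d_d%d", a, d)]), 1)
      expect_equal(unname(g[sprintf("glcm_entropy_a%d_d%d", a, d)]), 0)
    }
  }
})

test_that("GLCM matches a brute-force pair-enumeration oracle", {
  # alternating-column binary image at two grey levels (via the matrix
  # builder directly; the exported extractor requires ROIs of at least 8x8)
  alt <- matrix(rep(c(0, 128), 8), 4, 4, byrow = TRUE)
  q <- gliograde:::quantize_gray(alt, 2)
  for (a in c(0, 45, 90, 135)) {
    P <- gliograde:::glcm_matrix(q, 2, 1, a)
    got <- gliograde:::glcm_properties(P)
    oracle <- glcm_brute(alt, 2, 1, a)
    for (p in gliograde:::glcm_prop_names()) {
      expect_equal(unname(got[p]), unname(oracle[p]), tolerance = 1e-12,
                   label = sprintf("%s at %d deg", p, a))
    }
  }
  # horizontal pairs of the alternating image always differ by one level
  P0 <- gliograde:::glcm_matrix(q, 2, 1, 0)
  expect_equal(unname(gliograde:::glcm_properties(P0)["contrast"]), 1)
  expect_error(extract_glcm(alt), ">= 8")

  # random patch, all displacements
  withr::with_seed(7, patch <- matrix(sample(0:255, 144, TRUE), 12, 12))
  got2 <- extract_glcm(patch, levels = 8)
  for (a in c(0, 135)) {
    for (d in c(1, 4)) {
      oracle <- glcm_brute(patch, 8, d, a)
      for (p in gliograde:::glcm_prop_names()) {
        expect_equal(unname(got2[sprintf("glcm_%s_a%d_d%d", p, a, d)]),
                     unname(oracle[p]), tolerance = 1e-10)
      }
    }
  }
})

test_that("co-occurrence matrices are symmetric and normalized", {
  withr::with_seed(3, patch <- matrix(sample(0:255, 400, TRUE), 20, 20))
  q <- gliograde:::quantize_gray(patch, 16)
  for (a in c(0, 45, 90, 135)) {
    P <- gliograde:::glcm_matrix(q, 16, 2, a)
    expect_equal(P, t(P))
    expect_equal(sum(P), 1)
  }
  expect_error(gliograde:::glcm_matrix(q[1:3, 1:3], 16, 4, 0), "smaller")
})

test_that("intensity shift moves first-order mean but not GLCM contrast", {
  withr::with_seed(5, patch <- matrix(sample(0:127, 256, TRUE), 16, 16))
  shift <- 8 * (256 / 32)  # a whole number of quantization bins
  g1 <- extract_glcm(patch)
  g2 <- extract_glcm(patch + shift)
  expect_equal(g2[grep("contrast", names(g2))], g1[grep("contrast", names(g1))])
  f1 <- gliograde:::first_order_stats(patch)
  f2 <- gliograde:::first_order_stats(patch + shift)
  expect_equal(unname(f2["mean"] - f1["mean"]), shift)
})

test_that("visual features aggregate nuclei and spatial pattern correctly", {
  tile <- render_tile(test_profile(n_mean = 30), 256, seed = 8)
  seg <- segment_nuclei(tile$image)
  seg$gray <- gliograde:::rgb_to_gray(tile$image)
  v <- extract_visual(list(seg))
  expect_length(v, 24)
  expect_named(v, feature_names()$visual)
  expect_equal(unname(v["nuclei_count"]), seg$n_nuclei)
  expect_equal(unname(v["mean_area"]), mean(seg$records$area))
  expect_true(v["nucleus_background_contrast"] > 0)  # nuclei darker than stroma
  sv <- extract_subvisual(list(seg))
  expect_length(sv, 171)
  expect_false(anyNA(c(v, sv)))
  # fewer than two nuclei is a hard error with guidance
  blank <- segment_nuclei(stain_image(matrix(0, 128, 128)))
  blank$gray <- matrix(255, 128, 128)
  expect_error(extract_visual(list(blank)), "fewer than 2 nuclei")
})

test_that("Clark-Evans index separates regular grids from random placement", {
  # regular grid of disks vs the same count placed uniformly at random
  mk_labels <- function(centres, r = 4, size = 200) {
    m <- matrix(0L, size, size)
    for (i in seq_len(nrow(centres))) {
      m[disk_mask(r, size, centres[i, 1], centres[i, 2])] <- i
    }
    m
  }
  grid_centres <- as.matrix(expand.grid(seq(20, 180, by = 40),
                                        seq(20, 180, by = 40)))
  withr::with_seed(2, rand_centres <- matrix(runif(50, 10, 190), ncol = 2))
  rec_grid <- measure_regions(mk_labels(grid_centres),
                              matrix(0, 200, 200), matrix(0, 200, 200),
                              matrix(0, 200, 200))
  rec_rand <- measure_regions(mk_labels(rand_centres),
                              matrix(0, 200, 200), matrix(0, 200, 200),
                              matrix(0, 200, 200))
  ce_grid <- gliograde:::roi_pattern_stats(rec_grid, 200^2)["clark_evans_index"]
  ce_rand <- gliograde:::roi_pattern_stats(rec_rand, 200^2)["clark_evans_index"]
  expect_true(ce_grid > ce_rand)
  expect_gt(ce_grid, 1)  # regular pattern exceeds complete spatial randomness
})

test_that("doubling the image scale doubles perimeters and quadruples areas", {
  small <- measure_nucleus(disk_mask(8))
  big <- measure_nucleus(disk_mask(16))
  expect_equal(big$perimeter / small$perimeter, 2, tolerance = 0.1)
  expect_equal(big$area / small$area, 4, tolerance = 0.1)
})

test_that("the per-case feature table is complete and round-trips CSV", {
  m <- tiny_cohort()
  tab <- build_feature_table(m, tile_size_px = 128, roi_k = 3,
                             params = seg_params(min_nucleus_area_px = 20,
                                                 seed_min_distance_px = 5))
  expect_equal(nrow(tab), 9)
  expect_equal(ncol(tab), 198)  # case_id + grade + 196 features
  expect_false(anyNA(tab))
  expect_length(attr(tab, "skipped"), 0)
  expect_equal(tab$ki67_pi,
               compute_pi(m$cases$ki67_positive, m$cases$ki67_total))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  num <- vapply(tab, is.numeric, logical(1))
  for (cn in names(tab)[num]) {
    expect_equal(back[[cn]], signif(tab[[cn]], 12), tolerance = 1e-11)
  }
  expect_equal(back$grade, tab$grade)
})
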