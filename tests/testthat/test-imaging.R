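test_that("illumination correction preserves a flat field and reduces gradient CV", {
  img <- uniform_egg(0.5)
  out <- correct_illumination(img, 64)
  expect_equal(out$channels$LUM, img$channels$LUM, tolerance = 1e-10)

  n <- 256
  g <- matrix(rep(seq(0.3, 0.7, length.out = n), each = n), n, n)
  mask <- matrix(TRUE, n, n)
  gi <- egg_image(list(R = g, G = g, B = g, UV = g, LUM = g), mask, 30)
  cv <- function(x) sd(x[mask]) / mean(x[mask])
  # default blur sigma far larger than the frame: kernel truncated, no error
  corr <- correct_illumination(gi, 2048)
  expect_lt(cv(corr$channels$LUM), cv(g))
  corr2 <- correct_illumination(gi, 128)
  expect_lt(cv(corr2$channels$LUM), cv(corr$channels$LUM))
  # within-mask mean preserved
  expect_equal(mean(corr$channels$LUM[mask]), mean(g), tolerance = 1e-6)
})

test_that("mask shrinking erodes by the expected margin", {
  n <- 251
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), n), n, n)
  disk <- (xs - 126)^2 + (ys - 126)^2 <= 100^2
  shr <- shrink_mask(disk, egg_width_px = 200, fraction = 0.03)
  r_eff <- sqrt(sum(shr) / pi)
  expect_equal(r_eff, 94, tolerance = 0.02)
  expect_identical(shrink_mask(disk, 200, fraction = 0), disk)
  ell <- fix_spotted()$image$mask
  expect_lt(sum(shrink_mask(ell, 13.4 * 15, 0.03)), sum(ell))
  tiny <- matrix(FALSE, 9, 9); tiny[5, 5] <- TRUE
  expect_error(shrink_mask(tiny, 200, 0.03), "too small")
})

test_that("Phansalkar segmentation finds rendered spots and nothing on spotless eggs", {
  expect_length(segment_spots(uniform_egg(0.8))$component_areas, 0)

  r <- fix_spotted()
  seg <- segment_spots(r$image, fix_analysis_mask(), radius_px = 25)
  expect_length(seg$component_areas, 12)
  expect_equal(sum(seg$component_areas), sum(seg$spot_mask))
  jac <- sum(seg$spot_mask & r$spot_truth) / sum(seg$spot_mask | r$spot_truth)
  expect_gt(jac, 0.8)
  # spot mask stays inside the analysis mask
  expect_true(all(!seg$spot_mask[!seg$analysis_mask]))
})

test_that("segmentation is stable under brightness scaling and illumination gradients", {
  r <- fix_spotted()
  amask <- fix_analysis_mask()
  n_ref <- length(segment_spots(r$image, amask, radius_px = 25)$component_areas)
  for (c0 in c(0.6, 1.4)) {
    img2 <- r$image
    img2$channels <- lapply(img2$channels, function(x) pmin(x * c0, 1))
    expect_length(segment_spots(img2, amask, radius_px = 25)$component_areas, n_ref)
  }
  rg <- render_egg_image(n_spots = 12, spot_radius_mm = 0.27, min_sep_mm = 2,
                         scale = 15, seed = 3, gradient_amp = 0.3)
  corr <- correct_illumination(rg$image, 165)
  expect_length(segment_spots(corr, amask, radius_px = 25)$component_areas, n_ref)
})

test_that("colour stats recover render reflectances and fall back on spotless eggs", {
  r <- fix_spotted()
  seg <- segment_spots(r$image, fix_analysis_mask(), radius_px = 25)
  cs <- colour_stats(r$image, seg)
  bg <- c(R = 0.55, G = 0.5, B = 0.45, UV = 0.3, LUM = 0.75)
  sp <- c(R = 0.2, G = 0.15, B = 0.12, UV = 0.08, LUM = 0.2)
  for (ch in names(bg)) {
    nm <- if (ch == "LUM") "lum" else ch
    expect_lt(abs(cs[[paste0("colour_bkg_", nm)]] - bg[[ch]]), 0.01)
    # spot means sit between pure-spot and background values; segmentation
    # includes anti-aliased rims, so allow a wider band around the render value
    expect_lt(abs(cs[[paste0("colour_spot_", nm)]] - sp[[ch]]), 0.08)
  }
  blank <- uniform_egg(0.8)
  seg0 <- segment_spots(blank)
  expect_warning(cs0 <- colour_stats(blank, seg0), "no spots")
  expect_equal(unname(cs0[1:5]), unname(cs0[6:10]))
})

test_that("luminance histogram matches direct binning and sums to one", {
  u <- uniform_egg(0.55)
  h <- luminance_histogram(u)
  expect_equal(unname(h[6]), 1)
  expect_equal(sum(h), 1)

  img <- uniform_egg(0.25)
  img$channels$LUM[img$mask][seq(1, sum(img$mask), by = 2)] <- 0.75
  h2 <- luminance_histogram(img)
  expect_equal(unname(h2[3] + h2[8]), 1)
  expect_equal(unname(h2[3]), 0.5, tolerance = 0.01)

  r <- fix_spotted()$image
  h3 <- luminance_histogram(r)
  lum <- r$channels$LUM[r$mask]
  oracle <- vapply(1:10, function(b)
    mean(lum >= (b - 1) / 10 & (lum < b / 10 | (b == 10 & lum <= 1))), 0)
  expect_equal(unname(h3), oracle, tolerance = 1e-12)
  expect_equal(sum(h3), 1)
})

test_that("granularity spectrum is zero on uniform images and symmetric under negation", {
  u <- uniform_egg(0.5)
  reg <- region_partition(u$mask)
  g <- granularity_spectrum(u, reg, n_scales = 6)
  expect_true(all(g$energy == 0))
  expect_true(all(g$skewness == 0))

  r <- fix_spotted()$image
  regs <- region_partition(r$mask, r$blunt_end)
  g1 <- granularity_spectrum(r, regs, n_scales = 8)
  neg <- r
  neg$channels$LUM <- 1 - neg$channels$LUM
  g2 <- granularity_spectrum(neg, regs, n_scales = 8)
  expect_equal(g1$energy, g2$energy, tolerance = 1e-9)
  expect_equal(g1$skewness, -g2$skewness, tolerance = 1e-9)

  # adding a constant (DC) leaves the band-pass energies unchanged
  shift <- r
  shift$channels$LUM <- pmin(shift$channels$LUM + 0.1, 1)
  g3 <- granularity_spectrum(shift, regs, n_scales = 8)
  expect_equal(g1$energy, g3$energy, tolerance = 1e-9)
})

test_that("granularity energy peaks at the scale matching a sinusoidal texture", {
  n <- 120; m <- 240; scale <- 10
  mask <- matrix(FALSE, n, m)
  xs <- matrix(rep(seq_len(m), each = n), n, m)
  ys <- matrix(rep(seq_len(n), m), n, m)
  mask[((xs - m / 2) / (m / 2 - 6))^2 + ((ys - n / 2) / (n / 2 - 6))^2 <= 1] <- TRUE
  fr <- cbpdetect:::.principal_frame(mask)
  len_px <- diff(range(fr$u)) + 1
  target <- 4  # scale index (1/sqrt(2))^3 of egg length
  lambda <- (1 / sqrt(2))^(target - 1) * len_px
  ch <- 0.5 + 0.3 * sin(2 * pi * xs / lambda)
  img <- egg_image(list(R = ch, G = ch, B = ch, UV = ch, LUM = ch), mask, scale)
  g <- granularity_spectrum(img, region_partition(mask), n_scales = 8)
  expect_equal(which.max(g$energy[, "whole"]), target)
})

test_that("spot metrics agree with brute-force zone bookkeeping", {
  blank <- uniform_egg(0.8)
  sm0 <- spot_metrics(segment_spots(blank), region_partition(blank$mask), 10)
  expect_equal(unname(sm0), rep(0, 5))

  r <- fix_spotted()
  seg <- segment_spots(r$image, fix_analysis_mask(), radius_px = 25)
  regs <- region_partition(r$image$mask, "left")
  sm <- spot_metrics(seg, regs, 15)
  cov_zone <- vapply(c("blunt", "middle", "sharp"), function(z) {
    zm <- regs[[z]] & seg$analysis_mask
    100 * sum(seg$spot_mask & zm) / sum(zm)
  }, 0)
  expect_equal(sm[["spot_disp_mean"]], mean(cov_zone))
  expect_equal(sm[["spot_disp_sd"]], sqrt(mean((cov_zone - mean(cov_zone))^2)))
  expect_equal(sm[["spot_disp_cv"]], 100 * sm[["spot_disp_sd"]] / sm[["spot_disp_mean"]])
  expect_equal(sm[["spot_coverage_pct"]], 100 * sum(seg$spot_mask) / sum(seg$analysis_mask))
  expect_equal(sm[["spot_mean_area_mm2"]], mean(seg$component_areas) / 15^2)
})

test_that("shape metrics match closed forms for spheroids and are mirror-invariant", {
  r <- render_egg_image(n_spots = 0, scale = 15, length_mm = 22, width_mm = 14, seed = 1)
  sm <- shape_metrics(r$image$mask, 15)
  a <- 11; b <- 7; e <- sqrt(1 - b^2 / a^2)
  V <- 4 / 3 * pi * a * b^2
  S <- 2 * pi * b^2 * (1 + (a / (b * e)) * asin(e))
  expect_equal(sm[["shape_length_mm"]], 22, tolerance = 0.01)
  expect_equal(sm[["shape_width_mm"]], 14, tolerance = 0.01)
  expect_equal(sm[["shape_volume_mm3"]], V, tolerance = 0.01)
  expect_equal(sm[["shape_surface_mm2"]], S, tolerance = 0.01)
  expect_lt(sm[["shape_ellipse_dev"]], 0.005)
  expect_equal(sm[["shape_aspect"]], 22 / 14, tolerance = 0.01)

  sph <- render_egg_image(n_spots = 0, scale = 15, length_mm = 20, width_mm = 20, seed = 1)
  sms <- shape_metrics(sph$image$mask, 15)
  expect_equal(sms[["shape_aspect"]], 1, tolerance = 0.01)
  expect_equal(sms[["shape_volume_mm3"]], 4 / 3 * pi * 1000, tolerance = 0.01)

  mirrored <- r$image$mask[, rev(seq_len(ncol(r$image$mask)))]
  expect_equal(shape_metrics(mirrored, 15), sm, tolerance = 1e-6)

  clipped <- matrix(TRUE, 10, 10)
  expect_error(shape_metrics(clipped, 10), "clipped")
})

test_that("shape volume matches a voxel-counting oracle on an asymmetric pyriform solid", {
  # profile r(u) = w * sqrt(1-t^2) * (1 - 0.25 t), t in [-1, 1]: blunter at
  # one end; rasterize the solid of revolution and count voxels
  scale <- 15
  L <- 20 * scale; w <- 6 * scale
  n <- 2 * ceiling(w * 1.35) + 9; m <- L + 14
  xs <- matrix(rep(seq_len(m), each = n), n, m)
  ys <- matrix(rep(seq_len(n), m), n, m)
  t <- (xs - (m + 1) / 2) / (L / 2)
  rr <- ifelse(abs(t) <= 1, w * sqrt(pmax(1 - t^2, 0)) * (1 - 0.25 * t), -1)
  mask <- abs(ys - (n + 1) / 2) <= rr & rr > 0
  sm <- shape_metrics(mask, scale)
  tt <- seq(-1, 1, length.out = 4001)
  r_mm <- 6 * sqrt(1 - tt^2) * (1 - 0.25 * tt)
  V_oracle <- pi * sum((r_mm[-1]^2 + r_mm[-4001]^2) / 2) * (10 * diff(tt)[1])
  expect_equal(sm[["shape_volume_mm3"]], V_oracle, tolerance = 0.02)
})

test_that("full feature extraction recovers render parameters and satisfies invariants", {
  r <- fix_spotted()
  row <- fix_feature_row()
  lum_cols <- grep("^lum_bin_", names(row))
  expect_equal(sum(as.numeric(row[lum_cols])), 1, tolerance = 1e-9)
  expect_gte(row$spot_coverage_pct, 0); expect_lte(row$spot_coverage_pct, 100)
  expect_gte(row$shape_length_mm, row$shape_width_mm)
  expect_gt(row$shape_volume_mm3, 0); expect_gt(row$shape_surface_mm2, 0)
  truth_cov <- 100 * sum(r$spot_truth & fix_analysis_mask()) / sum(fix_analysis_mask())
  expect_lt(abs(row$spot_coverage_pct - truth_cov), 2)
  expect_lt(abs(row$shape_length_mm - 19), 1 / 15)
  expect_lt(abs(row$shape_width_mm - 13.4), 1 / 15)
  expect_equal(ncol(row), 2 + 10 + 10 + 48 + 48 + 5 + 6)
})
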