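#' Calibrated multichannel egg image
#'
#' Container for one egg: five reflectance rasters (R, G, B, UV and a
#' luminance channel, all in `[0, 1]`), a boolean egg mask, the pixel scale
#' and the orientation of the blunt pole along the image x axis. All rasters
#' must share dimensions; images are assumed to be at a common working scale
#' (the study standard is 30 px/mm).
#'
#' @param channels named list of numeric matrices `R`, `G`, `B`, `UV`, `LUM`,
#'   values in `[0, 1]`.
#' @param mask logical matrix of egg pixels, same dimensions as the channels.
#' @param scale pixels per millimetre (positive).
#' @param egg_id,clutch_id identifiers.
#' @param blunt_end `"left"` or `"right"`: which end of the long axis is the
#'   blunt pole.
#' @return an object of class `egg_image`.
#' @export
egg_image <- function(channels, mask, scale, egg_id = "egg", clutch_id = "clutch",
                      blunt_end = c("left", "right")) {
  blunt_end <- match.arg(blunt_end)
  need <- c("R", "G", "B", "UV", "LUM")
  if (!all(need %in% names(channels)))
    stop("channels must contain R, G, B, UV, LUM")
  channels <- channels[need]
  dims <- dim(channels$R)
  for (ch in need) {
    if (!identical(dim(channels[[ch]]), dims))
      stop("all channel rasters must share dimensions")
    rng <- range(channels[[ch]])
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("reflectance values must lie in [0, 1] (channel ", ch, ")")
    channels[[ch]] <- pmin(pmax(channels[[ch]], 0), 1)
  }
  if (!identical(dim(mask), dims)) stop("mask must share channel dimensions")
  if (!is.logical(mask)) stop("mask must be logical")
  if (!any(mask)) stop("no egg pixels")
  if (!(is.numeric(scale) && length(scale) == 1 && scale > 0))
    stop("scale must be a positive number")
  structure(list(channels = channels, mask = mask, scale = scale,
                 egg_id = egg_id, clutch_id = clutch_id, blunt_end = blunt_end),
            class = "egg_image")
}

#' @export
print.egg_image <- function(x, ...) {
  d <- dim(x$mask)
  cat("<egg_image> ", x$egg_id, " (clutch ", x$clutch_id, ")\n", sep = "")
  cat("  ", d[1], "x", d[2], " px at ", x$scale, " px/mm; ",
      sum(x$mask), " egg pixels; blunt end: ", x$blunt_end, "\n", sep = "")
  invisible(x)
}

#' Correct uneven illumination by division with a Gaussian-blurred field
#'
#' Each channel is divided by its heavily blurred version (a smooth estimate
#' of the illumination field) and rescaled so the within-mask mean of the
#' channel is preserved; output is clipped to `[0, 1]`. Division rather than
#' subtraction preserves reflectance ratios. For blur radii larger than the
#' image the kernel is truncated to the image extent.
#'
#' @param img an [egg_image].
#' @param blur_radius_px Gaussian sigma in pixels (default 2048, the study
#'   setting, which on typical egg crops amounts to a near-global mean).
#' @return an [egg_image] with corrected channels.
#' @export
correct_illumination <- function(img, blur_radius_px = 2048) {
  stopifnot(inherits(img, "egg_image"), blur_radius_px >= 1)
  if (!any(img$mask)) stop("no egg pixels")
  out <- img
  for (ch in names(img$channels)) {
    x <- img$channels[[ch]]
    b <- gauss_blur(x, blur_radius_px)
    ratio <- x / pmax(b, 1e-8)
    m_in <- mean(x[img$mask])
    m_ratio <- mean(ratio[img$mask])
    y <- if (m_ratio > 0) ratio * (m_in / m_ratio) else ratio
    out$channels[[ch]] <- pmin(pmax(y, 0), 1)
  }
  out
}

#' Shrink the egg mask by a fraction of the egg width
#'
#' Morphological erosion by a disc of radius `round(fraction * egg_width_px)`,
#' used to keep darker egg edges out of spot thresholding (study default: 3%
#' of the egg width).
#'
#' @param mask logical matrix.
#' @param egg_width_px egg width in pixels.
#' @param fraction erosion radius as a fraction of the width (default 0.03).
#' @return eroded logical matrix.
#' @export
shrink_mask <- function(mask, egg_width_px, fraction = 0.03) {
  stopifnot(is.logical(mask), any(mask), egg_width_px > 0, fraction >= 0)
  r <- round(fraction * egg_width_px)
  if (r < 1) return(mask)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  out <- EBImage::erode(mask * 1, brush) > 0.5
  if (!any(out)) stop("egg too small for margin")
  out
}

# Fill pixels outside the mask with the within-mask mean so that local
# filters near the egg edge are not contaminated by the background.
.mean_fill <- function(x, mask) {
  x[!mask] <- mean(x[mask])
  x
}

# 8-connected labelling of a boolean raster via graph components.
label_components <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0)
    return(list(labels = matrix(0L, nrow(mask), ncol(mask)), sizes = integer(0)))
  n <- nrow(mask)
  id <- seq_along(idx)               # vertex ids of spot pixels
  pos <- integer(length(mask)); pos[idx] <- id
  rows <- ((idx - 1L) %% n) + 1L
  cols <- ((idx - 1L) %/% n) + 1L
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nr <- rows + d[1]; nc <- cols + d[2]
    ok <- nr >= 1L & nr <= n & nc >= 1L & nc <= ncol(mask)
    nidx <- (nc[ok] - 1L) * n + nr[ok]
    hit <- pos[nidx] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(id[ok][hit], pos[nidx][hit]))
  }
  g <- igraph::graph_from_edgelist(if (is.null(edges)) matrix(0L, 0, 2) else edges,
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(id) - igraph::vcount(g)))
  comp <- igraph::components(g)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[idx] <- comp$membership
  list(labels = labels, sizes = as.integer(tabulate(comp$membership)))
}

#' Segment egg spots by Phansalkar local thresholding
#'
#' Applies the Phansalkar threshold
#' \eqn{T = m (1 + p e^{-q m} + k (s/R - 1))}
#' where `m` and `s` are the local mean and standard deviation of the
#' luminance channel over a disc neighbourhood; pixels darker than `T`
#' inside the (shrunken) analysis mask are spots. Designed for low-contrast
#' spots on normalised `[0, 1]` images.
#'
#' @param img an [egg_image], illumination-corrected.
#' @param analysis_mask logical matrix, the shrunken egg mask (see
#'   [shrink_mask]); defaults to the egg mask itself.
#' @param radius_px neighbourhood radius (default 50, the study setting).
#' @param k,p,q,r_norm Phansalkar constants (defaults 0.25, 2, 10, 0.5, the
#'   original formulation).
#' @return list of class `spot_segmentation`: `spot_mask` (logical),
#'   `labels` (integer raster), `component_areas` (pixel counts),
#'   `analysis_mask`.
#' @export
segment_spots <- function(img, analysis_mask = img$mask, radius_px = 50,
                          k = 0.25, p = 2.0, q = 10.0, r_norm = 0.5) {
  stopifnot(inherits(img, "egg_image"), is.logical(analysis_mask))
  if (!all(analysis_mask[!img$mask] == FALSE))
    stop("analysis_mask must lie within the egg mask")
  lum <- .mean_fill(img$channels$LUM, img$mask)
  # neighbourhood cannot exceed the image
  radius_px <- min(as.integer(radius_px), (min(dim(lum)) - 1L) %/% 2L)
  w <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  w <- w / sum(w)
  m <- EBImage::filter2(lum, w, boundary = "replicate")
  s <- sqrt(pmax(EBImage::filter2(lum^2, w, boundary = "replicate") - m^2, 0))
  thr <- m * (1 + p * exp(-q * m) + k * ((s / r_norm) - 1))
  spot_mask <- (img$channels$LUM < thr) & analysis_mask
  lab <- label_components(spot_mask)
  structure(list(spot_mask = spot_mask, labels = lab$labels,
                 component_areas = lab$sizes, analysis_mask = analysis_mask),
            class = "spot_segmentation")
}

# Principal-axis frame of a mask: centroid, unit long-axis vector (x-positive)
# and projected coordinates u (long axis) / v (short axis) of mask pixels.
.principal_frame <- function(mask) {
  idx <- which(mask)
  n <- nrow(mask)
  xy <- cbind(((idx - 1L) %/% n) + 1L,   # x = column
              ((idx - 1L) %% n) + 1L)    # y = row
  ctr <- colMeans(xy)
  cc <- sweep(xy, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  e1 <- ev$vectors[, 1]
  if (e1[1] < 0 || (e1[1] == 0 && e1[2] < 0)) e1 <- -e1
  e2 <- c(-e1[2], e1[1])
  list(centroid = ctr, e1 = e1, e2 = e2,
       u = cc %*% e1, v = cc %*% e2, idx = idx)
}

#' Partition the egg into blunt, middle and sharp thirds
#'
#' Splits the egg mask into three equal-length zones along its long
#' (principal) axis. The blunt zone is the third on the side named by
#' `blunt_end` ("left" = lower x).
#'
#' @param mask logical egg mask.
#' @param blunt_end `"left"` or `"right"`.
#' @return list of class `region_partition` with logical rasters `whole`,
#'   `blunt`, `middle`, `sharp`.
#' @export
region_partition <- function(mask, blunt_end = c("left", "right")) {
  blunt_end <- match.arg(blunt_end)
  stopifnot(is.logical(mask), any(mask))
  fr <- .principal_frame(mask)
  u <- fr$u
  lo <- min(u); hi <- max(u)
  q1 <- lo + (hi - lo) / 3; q2 <- lo + 2 * (hi - lo) / 3
  zone <- ifelse(u <= q1, 1L, ifelse(u <= q2, 2L, 3L))
  mk <- function(z) {
    m <- matrix(FALSE, nrow(mask), ncol(mask))
    m[fr$idx[zone == z]] <- TRUE
    m
  }
  left <- mk(1L); middle <- mk(2L); right <- mk(3L)
  if (blunt_end == "left") {
    blunt <- left; sharp <- right
  } else {
    blunt <- right; sharp <- left
  }
  structure(list(whole = mask, blunt = blunt, middle = middle, sharp = sharp),
            class = "region_partition")
}

#' Guess the blunt end from the wider half of the mask
#'
#' Convenience heuristic only: compares the maximum width of the two halves
#' of the egg along the long axis. Supply the orientation in metadata
#' whenever it is known.
#'
#' @param mask logical egg mask.
#' @return `"left"` or `"right"`.
#' @export
detect_blunt_end <- function(mask) {
  fr <- .principal_frame(mask)
  mid <- (min(fr$u) + max(fr$u)) / 2
  wl <- diff(range(fr$v[fr$u <= mid]))
  wr <- diff(range(fr$v[fr$u > mid]))
  if (wl >= wr) "left" else "right"
}

#' Mean colour and brightness of spots and background
#'
#' Means of the R, G, B, UV and luminance channels over spot pixels and over
#' background (analysis mask minus spots) pixels. A spotless egg falls back
#' to background values for the spot means (with a warning) so downstream
#' PCA never sees missing data.
#'
#' @param img an [egg_image].
#' @param seg a `spot_segmentation` from [segment_spots].
#' @return named numeric vector of length 10
#'   (`colour_spot_R`, ..., `colour_bkg_lum`).
#' @export
colour_stats <- function(img, seg) {
  stopifnot(inherits(img, "egg_image"), inherits(seg, "spot_segmentation"))
  bkg <- seg$analysis_mask & !seg$spot_mask
  if (!any(bkg)) stop("background empty")
  chs <- c("R", "G", "B", "UV", "LUM")
  bkg_means <- vapply(chs, function(ch) mean(img$channels[[ch]][bkg]), 0)
  if (any(seg$spot_mask)) {
    spot_means <- vapply(chs, function(ch) mean(img$channels[[ch]][seg$spot_mask]), 0)
  } else {
    warning("egg has no spots; spot colour stats set to background values")
    spot_means <- bkg_means
  }
  out <- c(spot_means, bkg_means)
  names(out) <- c(paste0("colour_spot_", c("R", "G", "B", "UV", "lum")),
                  paste0("colour_bkg_", c("R", "G", "B", "UV", "lum")))
  out
}

#' Whole-egg luminance histogram over ten levels
#'
#' Proportion of egg-mask pixels with luminance in each of ten bins
#' `[0, 0.1), ..., [0.9, 1]` (last bin closed). Proportions sum to 1.
#'
#' @param img an [egg_image].
#' @return named numeric vector `lum_bin_01` ... `lum_bin_10`.
#' @export
luminance_histogram <- function(img) {
  stopifnot(inherits(img, "egg_image"), any(img$mask))
  lum <- img$channels$LUM[img$mask]
  bin <- pmin(pmax(floor(lum * 10) + 1L, 1L), 10L)  # 1.0 folds into bin 10
  counts <- tabulate(bin, nbins = 10L)
  out <- counts / sum(counts)
  names(out) <- sprintf("lum_bin_%02d", 1:10)
  out
}

#' Granularity spectrum: pattern energy and skewness per scale and region
#'
#' Band-pass decomposes the luminance channel with a difference-of-Gaussians
#' filter bank at `n_scales` geometric scales `(1/sqrt(2))^i` of the egg
#' length (1 down to ~0.0221 for 12 scales) and, for each scale and each of
#' the four regions (whole, blunt, middle, sharp), reports pattern energy
#' (the s.d. of the filtered pixels) and pattern skewness (their third
#' standardised moment; 0 for constant signal). Pixels outside the egg are
#' mean-filled before filtering so the egg outline itself does not register
#' as pattern.
#'
#' @param img an [egg_image].
#' @param regions a [region_partition].
#' @param n_scales number of scales (default 12).
#' @return list with matrices `energy` and `skewness` (`n_scales` x 4,
#'   columns `whole`, `blunt`, `middle`, `sharp`) and the `scales` vector.
#' @export
granularity_spectrum <- function(img, regions, n_scales = 12) {
  stopifnot(inherits(img, "egg_image"), inherits(regions, "region_partition"))
  region_names <- c("whole", "blunt", "middle", "sharp")
  for (rn in region_names)
    if (sum(regions[[rn]]) < 3) stop("region with < 3 pixels: ", rn)
  fr <- .principal_frame(img$mask)
  len_px <- diff(range(fr$u)) + 1
  scales <- (1 / sqrt(2))^(0:(n_scales - 1))
  # DoG pair (sigma, sigma*sqrt(2)) peaks at wavelength ~5.336*sigma;
  # sigma chosen so each band is centred on its scale fraction of egg length
  sigma0 <- scales[1] * len_px / (sqrt(2) * pi / sqrt(log(2)))
  sigmas <- sigma0 * sqrt(2) * (1 / sqrt(2))^(0:n_scales)
  lum <- .mean_fill(img$channels$LUM, img$mask)
  blurred <- lapply(sigmas, function(s) gauss_blur(lum, s))
  energy <- matrix(0, n_scales, 4, dimnames = list(NULL, region_names))
  skew <- energy
  for (i in seq_len(n_scales)) {
    band <- blurred[[i + 1]] - blurred[[i]]   # fine minus coarse
    for (j in seq_along(region_names)) {
      px <- band[regions[[region_names[j]]]]
      energy[i, j] <- sd_pop(px)
      skew[i, j] <- skewness(px)
    }
  }
  list(energy = energy, skewness = skew, scales = scales)
}

#' Spot size, coverage and dispersion metrics
#'
#' Mean spot component area (mm^2), percent of the analysis mask covered by
#' spots, and three dispersion measures derived from per-zone coverages
#' (blunt/middle/sharp): their mean, population s.d. (n = 3) and coefficient
#' of variation (s.d./mean x 100; 0 when the mean is 0).
#'
#' @param seg a `spot_segmentation`.
#' @param regions a [region_partition].
#' @param scale pixels per mm.
#' @return named numeric vector
#'   (`spot_mean_area_mm2`, `spot_coverage_pct`, `spot_disp_mean`,
#'   `spot_disp_sd`, `spot_disp_cv`).
#' @export
spot_metrics <- function(seg, regions, scale) {
  stopifnot(inherits(seg, "spot_segmentation"), inherits(regions, "region_partition"),
            scale > 0)
  mean_area <- if (length(seg$component_areas) > 0)
    mean(seg$component_areas) / scale^2 else 0
  n_analysis <- sum(seg$analysis_mask)
  coverage <- 100 * sum(seg$spot_mask) / n_analysis
  zone_cov <- vapply(c("blunt", "middle", "sharp"), function(rn) {
    zm <- regions[[rn]] & seg$analysis_mask
    if (!any(zm)) return(0)
    100 * sum(seg$spot_mask & zm) / sum(zm)
  }, 0)
  dm <- mean(zone_cov)
  ds <- sd_pop(zone_cov)
  cv <- if (dm > 0) 100 * ds / dm else 0
  c(spot_mean_area_mm2 = mean_area, spot_coverage_pct = coverage,
    spot_disp_mean = dm, spot_disp_sd = unname(ds), spot_disp_cv = cv)
}

#' Egg shape metrics from the mask outline
#'
#' Computes length, maximum width, volume and surface area (treating the egg
#' as a solid of revolution around its long axis), mean absolute radial
#' deviation of the outline from the moment-equivalent ellipse (normalised
#' by length), and the aspect ratio length/width. Volume and surface use a
#' trapezoidal half-width profile with at least 200 stations.
#'
#' @param mask logical egg mask (single connected component, not touching
#'   the image border).
#' @param scale pixels per mm.
#' @return named numeric vector (`shape_length_mm`, `shape_width_mm`,
#'   `shape_volume_mm3`, `shape_surface_mm2`, `shape_ellipse_dev`,
#'   `shape_aspect`).
#' @export
shape_metrics <- function(mask, scale) {
  stopifnot(is.logical(mask), any(mask), scale > 0)
  n <- nrow(mask); m <- ncol(mask)
  idx <- which(mask)
  rows <- ((idx - 1L) %% n) + 1L
  cols <- ((idx - 1L) %/% n) + 1L
  if (min(rows) == 1L || max(rows) == n || min(cols) == 1L || max(cols) == m)
    stop("egg clipped")
  fr <- .principal_frame(mask)
  u <- fr$u; v <- fr$v
  len_px <- diff(range(u)) + 1
  wid_px <- diff(range(v)) + 1
  # half-width profile r(u) on >= 200 stations
  ns <- max(200L, ceiling(len_px / 3))
  br <- seq(min(u) - 0.5, max(u) + 0.5, length.out = ns + 1L)
  st <- findInterval(u, br, rightmost.closed = TRUE)
  r_px <- vapply(seq_len(ns), function(j) {
    vj <- v[st == j]
    if (length(vj) == 0) 0 else (diff(range(vj)) + 1) / 2
  }, 0)
  # smooth the squared profile (exactly quadratic for an ellipse, so the
  # spline is well behaved at the tips) to suppress pixel jitter, then
  # integrate volume = pi * int r^2 du and lateral surface
  # = 2 pi * int sqrt(r^2 + (d(r^2)/du)^2 / 4) du on a fine grid
  centers <- (br[-1] + br[-(ns + 1L)]) / 2
  ss <- stats::smooth.spline(centers, r_px^2, df = min(20, ns - 1L))
  grid <- seq(min(br), max(br), length.out = 1001L)
  qv <- pmax(stats::predict(ss, grid)$y, 0)
  qd <- stats::predict(ss, grid, deriv = 1)$y
  dg <- diff(grid)[1]
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2) * dg
  vol <- pi * trapz(qv) / scale^3
  integrand <- ifelse(qv > 0, 2 * pi * sqrt(qv + qd^2 / 4), 0)
  surf <- trapz(integrand) / scale^2
  # moment-equivalent ellipse deviation
  a_e <- len_px / 2; b_e <- wid_px / 2
  boundary <- mask & !(EBImage::erode(mask * 1, EBImage::makeBrush(3, "box")) > 0.5)
  bfr_idx <- which(boundary)
  bxy <- cbind(((bfr_idx - 1L) %/% n) + 1L, ((bfr_idx - 1L) %% n) + 1L)
  bc <- sweep(bxy, 2, fr$centroid)
  bu <- bc %*% fr$e1; bv <- bc %*% fr$e2
  th <- atan2(bv, bu)
  r_obs <- sqrt(bu^2 + bv^2)
  r_ell <- a_e * b_e / sqrt((b_e * cos(th))^2 + (a_e * sin(th))^2)
  ell_dev <- mean(abs(r_obs - r_ell)) / len_px
  c(shape_length_mm = len_px / scale, shape_width_mm = wid_px / scale,
    shape_volume_mm3 = vol, shape_surface_mm2 = surf,
    shape_ellipse_dev = ell_dev, shape_aspect = len_px / wid_px)
}

#' Extract the full raw feature vector from one egg image
#'
#' Runs the whole image-analysis chain: illumination correction, mask
#' shrinking, Phansalkar spot segmentation, colour statistics, luminance
#' histogram, granularity spectrum, spot metrics and shape metrics. Returns
#' one named row with stable column names: 10 colour values, 10 luminance
#' bins, `n_scales` x 4 pattern energies and skewnesses, 5 spot metrics and
#' 6 shape metrics.
#'
#' @param img an [egg_image].
#' @param blur_radius_px illumination-correction sigma (default 2048).
#' @param radius_px Phansalkar neighbourhood radius (default 50).
#' @param shrink_fraction mask-shrink fraction of egg width (default 0.03).
#' @param n_scales granularity scales (default 12).
#' @param correct whether to run illumination correction first (default TRUE).
#' @return a one-row `data.frame` with `egg_id`, `clutch_id` and all
#'   feature columns.
#' @export
extract_features <- function(img, blur_radius_px = 2048, radius_px = 50,
                             shrink_fraction = 0.03, n_scales = 12,
                             correct = TRUE) {
  stopifnot(inherits(img, "egg_image"))
  if (correct) img <- correct_illumination(img, blur_radius_px)
  fr <- .principal_frame(img$mask)
  wid_px <- diff(range(fr$v)) + 1
  amask <- shrink_mask(img$mask, wid_px, shrink_fraction)
  seg <- segment_spots(img, amask, radius_px = radius_px)
  regions <- region_partition(img$mask, img$blunt_end)
  colour <- colour_stats(img, seg)
  lum <- luminance_histogram(img)
  gran <- granularity_spectrum(img, regions, n_scales = n_scales)
  region_names <- colnames(gran$energy)
  en <- as.vector(gran$energy)
  sk <- as.vector(gran$skewness)
  names(en) <- paste0("energy_s", rep(sprintf("%02d", seq_len(n_scales)), 4),
                      "_", rep(region_names, each = n_scales))
  names(sk) <- paste0("skew_s", rep(sprintf("%02d", seq_len(n_scales)), 4),
                      "_", rep(region_names, each = n_scales))
  spots <- spot_metrics(seg, regions, img$scale)
  shape <- shape_metrics(img$mask, img$scale)
  out <- data.frame(egg_id = img$egg_id, clutch_id = img$clutch_id,
                    t(c(colour, lum, en, sk, spots, shape)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}
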