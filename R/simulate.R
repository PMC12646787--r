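# Synthetic generators: trait-level clutch tables, rendered egg images, and
# simulated-parasitism bookkeeping (combination enumeration and per-observer
# assessment sets).

#' Names and order of the nine phenotypic traits
#' @return character vector of length 9.
#' @export
trait_names <- function() {
  c("PC1_colour", "PC2_colour", "PC3_colour", "PC1_luminance",
    "PC1_pattern", "PC2_pattern", "PC1_pattern2", "PC2_pattern2", "PC1_shape")
}

#' Configuration for the synthetic clutch generator
#'
#' Defaults reproduce the structure of the study population: 54 females with
#' five-egg clutches, between-clutch spread larger than within-clutch spread
#' (scaled-s.d. metrics 0.82 vs 0.58). Traits are drawn i.i.d. per dimension:
#' female means ~ N(0, sigma_between^2 I9), eggs ~ N(mean, sigma_within^2 I9);
#' identity covariance is the default because real traits are PCA scores and
#' hence near-uncorrelated.
#'
#' @param n_females number of females/clutches (default 54).
#' @param eggs_per_clutch eggs per clutch (default 5).
#' @param sigma_between s.d. of female mean vectors (default 0.82).
#' @param sigma_within s.d. of eggs around their female mean (default 0.58).
#' @param first_egg_shift,last_egg_shift additive shift applied to the
#'   first-/last-laid egg of every clutch; scalar (added to every trait) or
#'   length-9 vector. Default 0.
#' @param seed integer seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_females = 54, eggs_per_clutch = 5,
                         sigma_between = 0.82, sigma_within = 0.58,
                         first_egg_shift = 0, last_egg_shift = 0, seed = 1) {
  stopifnot(n_females >= 2, eggs_per_clutch >= 1,
            sigma_between >= 0, sigma_within >= 0)
  expand <- function(x) if (length(x) == 1) rep(x, 9) else {
    stopifnot(length(x) == 9); x
  }
  structure(list(n_females = as.integer(n_females),
                 eggs_per_clutch = as.integer(eggs_per_clutch),
                 sigma_between = sigma_between, sigma_within = sigma_within,
                 first_egg_shift = expand(first_egg_shift),
                 last_egg_shift = expand(last_egg_shift),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic trait table of clutches
#'
#' @param cfg a [synth_config].
#' @return `data.frame` with `egg_id`, `clutch_id`, `laying_order` and the
#'   nine trait columns ([trait_names]); deterministic under `cfg$seed`.
#' @export
synth_clutches <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    nf <- cfg$n_females; ne <- cfg$eggs_per_clutch
    means <- matrix(stats::rnorm(nf * 9, 0, cfg$sigma_between), nf, 9)
    rows <- vector("list", nf)
    for (f in seq_len(nf)) {
      eggs <- matrix(stats::rnorm(ne * 9, 0, cfg$sigma_within), ne, 9)
      eggs <- sweep(eggs, 2, means[f, ], `+`)
      eggs[1, ] <- eggs[1, ] + cfg$first_egg_shift
      eggs[ne, ] <- eggs[ne, ] + cfg$last_egg_shift
      colnames(eggs) <- trait_names()
      rows[[f]] <- data.frame(
        egg_id = sprintf("F%02d_E%d", f, seq_len(ne)),
        clutch_id = sprintf("F%02d", f),
        laying_order = seq_len(ne), eggs,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Enumerate all simulated-parasitism combinations
#'
#' Every pairing of a host clutch with every egg of every other female.
#' For 54 clutches of 5 eggs this yields 54 x 265 = 14,310 combinations.
#'
#' @param clutches `data.frame` with `egg_id` and `clutch_id`.
#' @return list with `count` and `combinations` (`data.frame` of
#'   `host_clutch`, `parasite_egg`).
#' @export
enumerate_combinations <- function(clutches) {
  stopifnot(all(c("egg_id", "clutch_id") %in% names(clutches)))
  ids <- unique(clutches$clutch_id)
  if (length(ids) < 2) stop("need at least 2 clutches")
  combos <- do.call(rbind, lapply(ids, function(cid) {
    foreign <- clutches$egg_id[clutches$clutch_id != cid]
    data.frame(host_clutch = cid, parasite_egg = foreign,
               stringsAsFactors = FALSE)
  }))
  rownames(combos) <- NULL
  list(count = nrow(combos), combinations = combos)
}

#' Sample per-participant assessment sets of parasitized clutches
#'
#' Each participant assesses every host clutch once, with a parasitic egg
#' drawn at random from the other females; 35 participants x 54 clutches
#' gives the study's 1,890 simulated parasitism trials. Duplicates across
#' participants are possible.
#'
#' @param clutches `data.frame` with `egg_id`, `clutch_id`.
#' @param n_participants number of participants (default 35).
#' @param seed integer seed.
#' @return `data.frame` with `participant`, `host_clutch`, `parasite_egg`.
#' @export
sample_assessment_sets <- function(clutches, n_participants = 35, seed = 1) {
  ids <- unique(clutches$clutch_id)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
      par_egg <- vapply(ids, function(cid) {
        pool <- clutches$egg_id[clutches$clutch_id != cid]
        pool[sample.int(length(pool), 1)]
      }, "")
      data.frame(participant = p, host_clutch = ids, parasite_egg = par_egg,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Construct a parasitized-clutch layout
#'
#' Game 1 presents all six eggs (five host + one parasite) in random order.
#' Game 2 presents four randomly chosen host eggs as known, and the
#' remaining host egg plus the parasite as the two candidates.
#'
#' @param clutches trait table (`egg_id`, `clutch_id`, traits).
#' @param host_clutch host clutch id.
#' @param parasite_egg parasite egg id (from another clutch).
#' @param game 1 or 2.
#' @param seed seed for the display permutation / known-host draw.
#' @return list of class `parasitized_clutch`: `host_clutch`, `egg_ids`
#'   (display order), `parasite_id`, `game`, and for game 2 `known_hosts`
#'   and `candidates`.
#' @export
make_parasitized_clutch <- function(clutches, host_clutch, parasite_egg,
                                    game = 1, seed = 1) {
  host_eggs <- clutches$egg_id[clutches$clutch_id == host_clutch]
  if (length(host_eggs) < 2) stop("malformed layout: host clutch too small")
  if (parasite_egg %in% host_eggs || !(parasite_egg %in% clutches$egg_id))
    stop("malformed layout: parasite egg must come from another female")
  if (!game %in% c(1, 2)) stop("game must be 1 or 2")
  with_seed(seed, {
    if (game == 1) {
      ids <- sample(c(host_eggs, parasite_egg))
      structure(list(host_clutch = host_clutch, egg_ids = ids,
                     parasite_id = parasite_egg, game = 1L,
                     known_hosts = NULL, candidates = NULL),
                class = "parasitized_clutch")
    } else {
      known <- sample(host_eggs, length(host_eggs) - 1L)
      withheld <- setdiff(host_eggs, known)
      cand <- sample(c(withheld, parasite_egg))
      structure(list(host_clutch = host_clutch,
                     egg_ids = c(sample(known), cand),
                     parasite_id = parasite_egg, game = 2L,
                     known_hosts = sort(known), candidates = cand),
                class = "parasitized_clutch")
    }
  })
}

#' Build layout objects from an assessment-set table
#'
#' @param sets output of [sample_assessment_sets] (or any `data.frame` with
#'   `host_clutch`, `parasite_egg`).
#' @param clutches trait table.
#' @param game 1 or 2.
#' @param seed master seed; one sub-seed is derived per layout.
#' @return list of `parasitized_clutch` objects.
#' @export
build_layouts <- function(sets, clutches, game = 1, seed = 1) {
  seeds <- derive_seeds(seed, nrow(sets))
  lapply(seq_len(nrow(sets)), function(i)
    make_parasitized_clutch(clutches, sets$host_clutch[i], sets$parasite_egg[i],
                            game = game, seed = seeds[i]))
}

#' Render a synthetic spotted egg image with ground truth
#'
#' Draws a prolate (elliptical) egg mask with per-channel background and
#' spot reflectances, spots placed as anti-aliased discs by a seeded point
#' process with optional per-zone density weighting and minimum separation,
#' and an optional multiplicative left-right illumination ramp. The exact
#' spot-disc mask is returned for segmentation oracles.
#'
#' @param length_mm,width_mm egg axes (defaults 19 x 13.4, a typical barn
#'   swallow egg).
#' @param scale pixels per mm (default 30, the study working scale).
#' @param n_spots number of spots (default 40).
#' @param spot_radius_mm mean spot radius (default 0.35).
#' @param spot_radius_sd_mm s.d. of spot radii (default 0).
#' @param bg,spot named reflectance vectors (R, G, B, UV, LUM) in `[0, 1]`.
#' @param zone_weights relative spot density in blunt/middle/sharp thirds.
#' @param min_sep_mm minimum centre separation (default 0 = none).
#' @param gradient_amp amplitude of the multiplicative illumination ramp
#'   (0 = flat field; 0.3 means +-15% across the frame).
#' @param margin_mm background margin around the egg (default 1.5).
#' @param egg_id,clutch_id,blunt_end passed to [egg_image].
#' @param seed integer seed.
#' @return list: `image` (an [egg_image]) and `spot_truth` (logical raster).
#' @export
render_egg_image <- function(length_mm = 19, width_mm = 13.4, scale = 30,
                             n_spots = 40, spot_radius_mm = 0.35,
                             spot_radius_sd_mm = 0,
                             bg = c(R = 0.55, G = 0.5, B = 0.45, UV = 0.3, LUM = 0.75),
                             spot = c(R = 0.2, G = 0.15, B = 0.12, UV = 0.08, LUM = 0.2),
                             zone_weights = c(1, 1, 1), min_sep_mm = 0,
                             gradient_amp = 0, margin_mm = 1.5,
                             egg_id = "egg", clutch_id = "clutch",
                             blunt_end = "left", seed = 1) {
  stopifnot(length_mm > 0, width_mm > 0, length_mm >= width_mm, scale > 0)
  if (spot_radius_mm >= width_mm) stop("spot radius must be smaller than egg width")
  a <- length_mm / 2 * scale
  b <- width_mm / 2 * scale
  mar <- ceiling(margin_mm * scale)
  ncol_px <- ceiling(2 * a) + 2 * mar
  nrow_px <- ceiling(2 * b) + 2 * mar
  cx <- ncol_px / 2 + 0.5; cy <- nrow_px / 2 + 0.5
  xs <- matrix(rep(seq_len(ncol_px), each = nrow_px), nrow_px, ncol_px)
  ys <- matrix(rep(seq_len(nrow_px), ncol_px), nrow_px, ncol_px)
  ell <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2
  mask <- ell <= 1
  with_seed(seed, {
    # spot centres: rejection-sample inside an inset ellipse, zone-weighted
    alpha <- matrix(0, nrow_px, ncol_px)
    truth <- matrix(FALSE, nrow_px, ncol_px)
    centres <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    inset <- 0.8
    tries <- 0
    while (nrow(centres) < n_spots && tries < 20000 && n_spots > 0) {
      tries <- tries + 1
      px <- stats::runif(1, cx - a, cx + a)
      py <- stats::runif(1, cy - b, cy + b)
      if (((px - cx) / (a * inset))^2 + ((py - cy) / (b * inset))^2 > 1) next
      zone <- findInterval(px, cx + c(-a / 3, a / 3)) + 1L
      w <- zone_weights[zone] / max(zone_weights)
      if (stats::runif(1) > w) next
      if (min_sep_mm > 0 && nrow(centres) > 0 &&
          min(sqrt((centres[, 1] - px)^2 + (centres[, 2] - py)^2)) < min_sep_mm * scale)
        next
      r <- max(spot_radius_mm + stats::rnorm(1, 0, spot_radius_sd_mm), 0.05) * scale
      centres <- rbind(centres, c(px, py))
      radii <- c(radii, r)
    }
    for (i in seq_len(nrow(centres))) {
      d <- sqrt((xs - centres[i, 1])^2 + (ys - centres[i, 2])^2)
      alpha <- pmax(alpha, pmin(pmax(radii[i] - d + 0.5, 0), 1))
      truth <- truth | (d <= radii[i])
    }
  })
  truth <- truth & mask
  ramp <- 1 + gradient_amp * ((xs - 1) / (ncol_px - 1) - 0.5)
  channels <- lapply(stats::setNames(names(bg), names(bg)), function(ch) {
    val <- bg[[ch]] * (1 - alpha) + spot[[ch]] * alpha
    pmin(pmax(val * ramp, 0), 1)
  })
  img <- egg_image(channels, mask, scale, egg_id = egg_id,
                   clutch_id = clutch_id, blunt_end = blunt_end)
  list(image = img, spot_truth = truth)
}
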