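# Shared fixtures, computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Small rendered egg (15 px/mm) with 12 well-separated spots.
fix_spotted <- function() cached("spotted", render_egg_image(
  n_spots = 12, spot_radius_mm = 0.27, min_sep_mm = 2, scale = 15, seed = 3))

# Analysis mask of the spotted fixture.
fix_analysis_mask <- function() cached("amask", {
  r <- fix_spotted()
  shrink_mask(r$image$mask, 13.4 * 15, 0.03)
})

# One full feature row extracted from the spotted fixture.
fix_feature_row <- function() cached("featrow", {
  extract_features(fix_spotted()$image, radius_px = 25, correct = FALSE)
})

# Feature table: the extracted row plus Gaussian jitter, for trait-model
# structure tests (column layout is the real one; values are synthetic).
fix_feature_table <- function(n = 30, seed = 42) cached(paste0("ft", n, seed), {
  base <- fix_feature_row()
  num <- vapply(base, is.numeric, TRUE)
  set.seed(seed)
  out <- base[rep(1, n), ]
  for (j in which(num))
    out[[j]] <- base[[j]] + stats::rnorm(n, 0, pmax(abs(base[[j]]) * 0.2, 0.05))
  out$egg_id <- sprintf("E%02d", seq_len(n))
  out$clutch_id <- sprintf("C%02d", rep(seq_len(n / 5), each = 5))
  rownames(out) <- NULL
  out
})

# Strong-identity synthetic trait table (default study geometry).
fix_traits <- function() cached("traits", synth_clutches(synth_config(seed = 7)))

# Uniform egg image helper.
uniform_egg <- function(value = 0.5, n = 60, m = 90, scale = 10) {
  mask <- matrix(FALSE, n, m)
  xs <- matrix(rep(seq_len(m), each = n), n, m)
  ys <- matrix(rep(seq_len(n), m), n, m)
  mask[((xs - m / 2) / (m / 2 - 4))^2 + ((ys - n / 2) / (n / 2 - 4))^2 <= 1] <- TRUE
  ch <- matrix(value, n, m)
  egg_image(list(R = ch, G = ch, B = ch, UV = ch, LUM = ch), mask, scale)
}

# Brute-force unsupervised oracle: mean pairwise distance enumeration.
brute_force_identify <- function(pc, traits) {
  x <- as.matrix(traits[, trait_names()])
  rownames(x) <- traits$egg_id
  md <- function(a, b) sqrt(sum((x[a, ] - x[b, ])^2))
  if (pc$game == 1) {
    ids <- pc$egg_ids
    sc <- vapply(ids, function(e)
      mean(vapply(setdiff(ids, e), md, 0, a = e)), 0)
  } else {
    sc <- vapply(pc$candidates, function(e)
      mean(vapply(pc$known_hosts, md, 0, a = e)), 0)
  }
  top <- names(sc)[sc == max(sc)]
  if (length(top) == 1) top else NA_character_
}
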