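# Nine phenotypic traits: five separate PCAs over feature groups, random
# forest importance ranking of the resulting traits, and importance
# weighting for the distance-based identification methods.

.feature_groups <- function(cols, pattern_scope = c("scales_by_region", "whole_only")) {
  pattern_scope <- match.arg(pattern_scope)
  pat <- grep("^(energy|skew)_", cols, value = TRUE)
  if (pattern_scope == "whole_only")
    pat <- grep("_whole$", pat, value = TRUE)
  list(colour = grep("^colour_", cols, value = TRUE),
       luminance = grep("^lum_bin_", cols, value = TRUE),
       pattern = pat,
       pattern2 = grep("^spot_", cols, value = TRUE),
       shape = grep("^shape_", cols, value = TRUE))
}

.default_ncomp <- c(colour = 3L, luminance = 1L, pattern = 2L,
                    pattern2 = 2L, shape = 1L)

#' Fit the phenotypic trait model (five grouped PCAs)
#'
#' Standardizes each feature column (z-score on the fitted table) and runs a
#' separate PCA per feature group: colour (10 variables), luminance (10
#' histogram bins), pattern (granularity energies and skewnesses), pattern2
#' (spot size, coverage and dispersion) and shape (6 variables). The
#' retained component counts default to (3, 1, 2, 2, 1), giving the nine
#' phenotypic traits. Component signs are fixed by forcing the variable with
#' the largest absolute loading of each component to load positively.
#' Constant columns are dropped with a warning.
#'
#' @param features feature table as produced by [extract_features] (rows =
#'   eggs; must include all feature columns, at least 10 eggs, no missing
#'   values).
#' @param ncomp named integer vector of components per group.
#' @param pattern_scope `"scales_by_region"` (all scales x 4 regions feed the
#'   pattern PCA; default) or `"whole_only"` (whole-egg spectra only).
#' @return object of class `egg_trait_model` with per-group centers, scales,
#'   loadings and explained-variance fractions.
#' @export
fit_trait_model <- function(features, ncomp = .default_ncomp,
                            pattern_scope = "scales_by_region") {
  stopifnot(nrow(features) >= 10)
  groups <- .feature_groups(names(features), pattern_scope)
  if (any(vapply(groups, length, 0L) == 0)) stop("missing feature columns")
  if (anyNA(features[, unlist(groups)])) stop("missing values in features")
  fits <- list()
  for (g in names(groups)) {
    x <- as.matrix(features[, groups[[g]], drop = FALSE])
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping constant column(s) in group ", g, ": ",
              paste(colnames(x)[sds == 0], collapse = ", "))
      x <- x[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    k <- min(ncomp[[g]], ncol(x), nrow(x) - 1L)
    pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
    rot <- pc$rotation[, seq_len(k), drop = FALSE]
    # sign convention: largest-|loading| variable loads positively
    for (j in seq_len(k)) {
      i_max <- which.max(abs(rot[, j]))
      if (rot[i_max, j] < 0) rot[, j] <- -rot[, j]
    }
    fits[[g]] <- list(vars = colnames(x), center = pc$center, scale = pc$scale,
                      rotation = rot, n_comp = k,
                      explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
  }
  structure(list(groups = fits, ncomp = ncomp, pattern_scope = pattern_scope,
                 n_fit = nrow(features)),
            class = "egg_trait_model")
}

#' @export
print.egg_trait_model <- function(x, ...) {
  cat("<egg_trait_model> fitted on", x$n_fit, "eggs\n")
  for (g in names(x$groups)) {
    f <- x$groups[[g]]
    cat(sprintf("  %-9s %2d vars -> %d component(s), %.1f%% variance\n",
                g, length(f$vars), f$n_comp, 100 * sum(f$explained)))
  }
  invisible(x)
}

#' Project a feature table onto the nine phenotypic traits
#'
#' @param object an `egg_trait_model`.
#' @param newdata feature table with the columns the model was fitted on.
#' @param ... unused.
#' @return `data.frame` with `egg_id`, `clutch_id`, optionally
#'   `laying_order`, and the nine trait columns in [trait_names] order.
#' @export
predict.egg_trait_model <- function(object, newdata, ...) {
  scores <- list()
  for (g in names(object$groups)) {
    f <- object$groups[[g]]
    if (!all(f$vars %in% names(newdata)))
      stop("newdata lacks fitted columns of group ", g)
    x <- as.matrix(newdata[, f$vars, drop = FALSE])
    z <- sweep(sweep(x, 2, f$center), 2, f$scale, `/`)
    sc <- z %*% f$rotation
    colnames(sc) <- paste0("PC", seq_len(ncol(sc)), "_",
                           if (g == "pattern2") "pattern2" else g)
    scores[[g]] <- sc
  }
  out <- do.call(cbind, scores)
  keep <- intersect(c("egg_id", "clutch_id", "laying_order"), names(newdata))
  res <- cbind(newdata[, keep, drop = FALSE], as.data.frame(out))
  # fixed trait order: colour 1-3, luminance 1, pattern 1-2, pattern2 1-2, shape 1
  ord <- intersect(trait_names(), names(res))
  res <- res[, c(keep, ord)]
  rownames(res) <- NULL
  res
}

#' Z-score the nine trait columns over the full egg set
#'
#' Distance-based methods and the variance metrics operate on traits scaled
#' across all eggs.
#'
#' @param traits trait table with the [trait_names] columns.
#' @return same table with scaled trait columns.
#' @export
scale_traits <- function(traits) {
  tn <- intersect(trait_names(), names(traits))
  traits[tn] <- lapply(traits[tn], function(x) as.numeric(scale(x)))
  traits
}

#' Rank traits by random-forest permutation importance
#'
#' Fits a random-forest classifier of female identity on the nine traits and
#' returns each trait's mean decrease in accuracy, the importance measure
#' used as a multiplicative trait weight. Negative importances are clamped
#' to zero with a warning.
#'
#' @param traits trait table.
#' @param female_ids factor/character of female (clutch) identities.
#' @param ntree number of trees (default 500).
#' @param seed integer seed.
#' @return list of class `importance_weights`: `w` (named, nonnegative, in
#'   [trait_names] order) and `provenance = "fitted"`.
#' @export
rank_traits <- function(traits, female_ids, ntree = 500, seed = 1) {
  tn <- trait_names()
  stopifnot(all(tn %in% names(traits)))
  f <- factor(female_ids)
  if (nlevels(f) < 2) stop("need at least 2 females")
  if (any(table(f) < 2)) stop("each female needs at least 2 eggs")
  x <- as.matrix(traits[, tn])
  rf <- with_seed(seed, randomForest::randomForest(
    x, f, ntree = ntree, importance = TRUE))
  w <- randomForest::importance(rf, type = 1)[, 1]
  if (any(w < 0)) {
    warning("negative permutation importances clamped to 0")
    w <- pmax(w, 0)
  }
  structure(list(w = w[tn], provenance = "fitted"), class = "importance_weights")
}

#' Reference importance weights
#'
#' The mean-decrease-in-accuracy weights reported for the study population
#' (shape PC1 down to pattern2 PC1), usable when no labelled dataset is at
#' hand. Order follows [trait_names].
#'
#' @return an `importance_weights` object with `provenance = "reference"`.
#' @export
reference_weights <- function() {
  w <- c(PC1_colour = 21.30, PC2_colour = 22.48, PC3_colour = 32.06,
         PC1_luminance = 19.73, PC1_pattern = 20.44, PC2_pattern = 28.44,
         PC1_pattern2 = 17.95, PC2_pattern2 = 18.61, PC1_shape = 37.13)
  structure(list(w = w[trait_names()], provenance = "reference"),
            class = "importance_weights")
}

#' Weight traits by importance
#'
#' Elementwise product of each trait column with its importance weight;
#' weighted traits feed the Euclidean-distance methods (MED and unsupervised
#' identification).
#'
#' @param traits trait table (scaled).
#' @param weights an `importance_weights` object or a length-9 nonnegative
#'   numeric vector in [trait_names] order.
#' @return trait table with weighted trait columns.
#' @export
weight_traits <- function(traits, weights) {
  w <- if (inherits(weights, "importance_weights")) weights$w else weights
  tn <- trait_names()
  stopifnot(all(tn %in% names(traits)))
  if (length(w) != length(tn)) stop("weights length must match trait count")
  if (any(!is.finite(w))) stop("weights must be finite")
  if (is.null(names(w))) names(w) <- tn
  for (nm in tn) traits[[nm]] <- traits[[nm]] * w[[nm]]
  traits
}
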