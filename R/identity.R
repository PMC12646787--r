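# Identity signal in egg phenotypes: within- vs between-clutch variance
# metrics, Beecher's information statistic with a label-shuffled control,
# and laying-order deviation profiles.

#' Within- and between-clutch variance metrics
#'
#' For each clutch, the s.d. of every trait over its eggs is averaged across
#' the nine traits (the within metric, one value per female). The between
#' metric averages, across traits, the s.d. of the clutch-mean ("average
#' egg") vectors. A one-sample t-test compares the within metrics against
#' the between value. Traits are expected to be z-scored over the full egg
#' set ([scale_traits]). Clutches with a single egg are excluded with a
#' warning. Sample (n-1) standard deviations are used throughout.
#'
#' @param traits scaled trait table.
#' @param clutch_ids clutch/female identifiers (defaults to
#'   `traits$clutch_id`).
#' @return list of class `identity_stats`: `within_per_clutch`,
#'   `within_mean`, `within_sd`, `between`, `t_stat`, `df`, `p`.
#' @export
clutch_variance_stats <- function(traits, clutch_ids = traits$clutch_id) {
  tn <- trait_names()
  stopifnot(all(tn %in% names(traits)))
  x <- as.matrix(traits[, tn])
  f <- factor(clutch_ids)
  sizes <- table(f)
  if (any(sizes < 2)) {
    warning("excluding ", sum(sizes < 2), " clutch(es) with a single egg")
    keep <- f %in% names(sizes)[sizes >= 2]
    x <- x[keep, , drop = FALSE]
    f <- droplevels(f[keep])
  }
  if (nlevels(f) < 2) stop("need at least 2 clutches")
  within_per_clutch <- vapply(levels(f), function(cl) {
    mean(apply(x[f == cl, , drop = FALSE], 2, stats::sd))
  }, 0)
  clutch_means <- t(vapply(levels(f), function(cl)
    colMeans(x[f == cl, , drop = FALSE]), numeric(ncol(x))))
  between <- mean(apply(clutch_means, 2, stats::sd))
  tt <- stats::t.test(within_per_clutch, mu = between)
  structure(list(within_per_clutch = within_per_clutch,
                 within_mean = mean(within_per_clutch),
                 within_sd = stats::sd(within_per_clutch),
                 between = between,
                 t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "identity_stats")
}

#' @export
print.identity_stats <- function(x, ...) {
  cat("<identity_stats>\n")
  cat(sprintf("  within-clutch:  mean %.3f (s.d. %.3f, n = %d)\n",
              x$within_mean, x$within_sd, length(x$within_per_clutch)))
  cat(sprintf("  between-clutch: %.3f\n", x$between))
  cat(sprintf("  one-sample t = %.2f, df = %d, p = %.3g\n", x$t_stat, x$df, x$p))
  invisible(x)
}

#' Beecher's information statistic (Hs) with shuffled control
#'
#' Decorrelates the traits by a full PCA, runs a one-way ANOVA of each
#' component score on female identity, and sums `0.5 * log2(F)` over the
#' components significant at p < 0.05. A control value repeats the
#' computation with female labels shuffled (seeded). F is capped at 1e6 so
#' degenerate (zero within-clutch variance) data stay finite.
#'
#' @param traits trait table.
#' @param clutch_ids female identifiers (defaults to `traits$clutch_id`).
#' @param seed seed for the label shuffle.
#' @return list of class `beecher_hs`: `hs`, `hs_control`,
#'   `n_significant_vars`, `per_component` (F and p per component), `seed`.
#' @export
beecher_hs <- function(traits, clutch_ids = traits$clutch_id, seed = 1) {
  tn <- intersect(trait_names(), names(traits))
  x <- as.matrix(traits[, tn])
  f <- factor(clutch_ids)
  if (nlevels(f) < 2 || any(table(f) < 2))
    stop("need at least 2 clutches with at least 2 eggs")
  k_max <- nrow(x) - 1L
  if (ncol(x) > k_max) {
    warning("fewer eggs than components; truncating to ", k_max, " components")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(min(ncol(pc$x), k_max)), drop = FALSE]
  hs_of <- function(labels) {
    Fp <- apply(scores, 2, function(s) {
      a <- stats::anova(stats::lm(s ~ labels))
      c(F = min(a$`F value`[1], 1e6, na.rm = TRUE), p = a$`Pr(>F)`[1])
    })
    sig <- which(Fp["p", ] < 0.05 & Fp["F", ] > 1)
    list(hs = sum(0.5 * log2(Fp["F", sig])), n_sig = length(sig), Fp = Fp)
  }
  real <- hs_of(f)
  if (any(apply(x, 2, function(col) all(tapply(col, f, stats::sd) < 1e-12))))
    warning("zero within-clutch variance; F capped at 1e6")
  ctrl <- with_seed(seed, hs_of(sample(f)))
  structure(list(hs = real$hs, hs_control = ctrl$hs,
                 n_significant_vars = real$n_sig,
                 per_component = t(real$Fp), seed = seed),
            class = "beecher_hs")
}

#' @export
print.beecher_hs <- function(x, ...) {
  cat(sprintf("<beecher_hs> Hs = %.3f over %d significant component(s); shuffled control Hs = %.3f\n",
              x$hs, x$n_significant_vars, x$hs_control))
  invisible(x)
}

#' Mean within-clutch deviation by laying position
#'
#' For each egg with known laying order, computes the mean Euclidean
#' distance (scaled traits) to its clutch-mates and averages by laying
#' position — first- and last-laid eggs that deviate from the clutch show
#' up as elevated positions. Clutches with incomplete order are skipped.
#'
#' @param traits scaled trait table.
#' @param clutch_ids clutch identifiers (defaults to `traits$clutch_id`).
#' @param laying_orders integer laying positions (defaults to
#'   `traits$laying_order`).
#' @return `data.frame` with `position`, `mean_deviation`, `n`.
#' @export
laying_order_deviation <- function(traits, clutch_ids = traits$clutch_id,
                                   laying_orders = traits$laying_order) {
  tn <- trait_names()
  x <- as.matrix(traits[, tn])
  f <- factor(clutch_ids)
  dev <- numeric(0); pos <- integer(0)
  for (cl in levels(f)) {
    sel <- which(f == cl)
    ord <- laying_orders[sel]
    if (anyNA(ord) || length(sel) < 2) next
    D <- as.matrix(stats::dist(x[sel, , drop = FALSE]))
    dev <- c(dev, rowSums(D) / (length(sel) - 1))
    pos <- c(pos, ord)
  }
  if (length(dev) == 0) stop("no clutch with complete laying order")
  agg <- stats::aggregate(dev, list(position = pos), mean)
  cnt <- stats::aggregate(dev, list(position = pos), length)
  data.frame(position = agg$position, mean_deviation = agg$x, n = cnt$x)
}
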