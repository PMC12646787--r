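# Detection of parasitized clutches (MED) and parasitic eggs (unsupervised
# weighted-distance ranking; supervised same/different random-forest voting
# under leave-one-clutch-out and leave-one-egg-out validation).

.trait_matrix <- function(traits) {
  tn <- trait_names()
  stopifnot(all(tn %in% names(traits)), "egg_id" %in% names(traits))
  x <- as.matrix(traits[, tn])
  rownames(x) <- traits$egg_id
  x
}

#' Maximum Euclidean distance (MED) statistic of a clutch
#'
#' Computes all pairwise Euclidean distances among the clutch's eggs
#' (importance-weighted traits), each egg's mean distance over its pairs,
#' and the MED — the mean distance of the most different egg. Clutches with
#' MED above the threshold are classified as parasitized (default threshold
#' 350, calibrated for reference-scale weights).
#'
#' @param traits weighted trait table (or matrix with egg-id rownames) for
#'   one clutch of at least 3 eggs.
#' @param threshold classification threshold (default 350).
#' @param weights_provenance `"reference"` or `"fitted"`; a non-reference
#'   provenance triggers a warning because the default threshold is only
#'   meaningful on the reference weight scale.
#' @return list of class `med_result`: `per_egg_mean_distance`, `med`,
#'   `most_different_egg`, `classified_parasitized`, `threshold`.
#' @export
med_statistic <- function(traits, threshold = 350,
                          weights_provenance = "reference") {
  x <- if (is.matrix(traits)) traits else .trait_matrix(traits)
  if (nrow(x) < 3) stop("MED needs at least 3 eggs")
  if (!identical(weights_provenance, "reference"))
    warning("MED threshold 350 is calibrated for reference-scale weights")
  D <- as.matrix(stats::dist(x))
  per_egg <- rowSums(D) / (nrow(x) - 1)
  med <- max(per_egg)
  structure(list(per_egg_mean_distance = per_egg, med = med,
                 most_different_egg = rownames(x)[which.max(per_egg)],
                 classified_parasitized = med > threshold,
                 threshold = threshold),
            class = "med_result")
}

#' @export
print.med_result <- function(x, ...) {
  cat(sprintf("<med_result> MED = %.2f (egg %s); %sparasitized at threshold %g\n",
              x$med, x$most_different_egg,
              if (x$classified_parasitized) "" else "not ", x$threshold))
  invisible(x)
}

#' Unsupervised identification of the parasitic egg by weighted distance
#'
#' Game 1: among the six eggs, each egg's mean Euclidean distance over its
#' five pairs is computed and the egg with the largest mean is called
#' parasitic. Game 2: each of the two candidates is scored by its mean
#' distance to the four known host eggs (the candidate-candidate pair is
#' excluded) and the larger mean is called. Exact ties are ambiguous.
#'
#' @param pc a `parasitized_clutch` layout.
#' @param traits weighted trait table covering the layout's eggs.
#' @return list: `called_egg` (or `NA` if ambiguous), `ambiguous`, `scores`.
#' @export
unsupervised_identify <- function(pc, traits) {
  stopifnot(inherits(pc, "parasitized_clutch"))
  x <- .trait_matrix(traits)
  if (!all(pc$egg_ids %in% rownames(x))) stop("layout eggs missing from traits")
  if (pc$game == 1) {
    xx <- x[pc$egg_ids, , drop = FALSE]
    D <- as.matrix(stats::dist(xx))
    scores <- rowSums(D) / (nrow(xx) - 1)
  } else {
    hosts <- x[pc$known_hosts, , drop = FALSE]
    scores <- vapply(pc$candidates, function(e) {
      mean(sqrt(colSums((t(hosts) - x[e, ])^2)))
    }, 0)
  }
  mx <- max(scores)
  top <- names(scores)[scores == mx]
  list(called_egg = if (length(top) == 1) top else NA_character_,
       ambiguous = length(top) > 1, scores = scores)
}

# |trait difference| features for the rows (ia, ib) of trait matrix X
.pair_features <- function(X, ia, ib) {
  f <- abs(X[ia, , drop = FALSE] - X[ib, , drop = FALSE])
  colnames(f) <- paste0("d_", colnames(X))
  f
}

#' Build a balanced same/different pair-training set
#'
#' Samples `n_same` within-female and `n_diff` between-female egg pairs
#' uniformly without replacement from the pool (with replacement plus a
#' warning when fewer are available). Pair features are the absolute
#' per-trait differences of the scaled traits, making the classifier
#' symmetric under egg swap. If `forced_host_eggs` is given, every pair
#' among them is included as 'same' before the remainder is sampled
#' (leave-one-egg-out training).
#'
#' @param pool scaled trait table (`egg_id`, `clutch_id`, traits).
#' @param n_same,n_diff pair counts (defaults 265 each, the study sizes).
#' @param seed integer seed.
#' @param forced_host_eggs optional egg ids whose mutual pairs are forced in
#'   as 'same'.
#' @return `data.frame` with `egg_a`, `egg_b`, `label`
#'   (factor same/different) and the nine `d_` feature columns.
#' @export
build_pair_training <- function(pool, n_same = 265, n_diff = 265, seed = 1,
                                forced_host_eggs = NULL) {
  X <- .trait_matrix(pool)
  cl <- pool$clutch_id
  n <- nrow(X)
  if (n < 4) stop("pool too small")
  pr <- utils::combn(n, 2)
  same <- cl[pr[1, ]] == cl[pr[2, ]]
  same_idx <- which(same)
  diff_idx <- which(!same)
  forced_pos <- integer(0)
  if (!is.null(forced_host_eggs)) {
    stopifnot(all(forced_host_eggs %in% pool$egg_id))
    fi <- match(forced_host_eggs, pool$egg_id)
    forced_pos <- same_idx[pr[1, same_idx] %in% fi & pr[2, same_idx] %in% fi]
    same_idx <- setdiff(same_idx, forced_pos)
  }
  take <- function(idx, k, what) {
    if (k <= 0) return(integer(0))
    if (length(idx) == 0) stop("no ", what, " pairs available in the pool")
    if (length(idx) >= k) idx[sample.int(length(idx), k)]
    else {
      warning("only ", length(idx), " ", what, " pairs available; sampling with replacement")
      idx[sample.int(length(idx), k, replace = TRUE)]
    }
  }
  with_seed(seed, {
    sel_same <- c(forced_pos, take(same_idx, n_same - length(forced_pos), "'same'"))
    sel_diff <- take(diff_idx, n_diff, "'different'")
    sel <- c(sel_same, sel_diff)
    feats <- .pair_features(X, pr[1, sel], pr[2, sel])
    out <- data.frame(egg_a = pool$egg_id[pr[1, sel]],
                      egg_b = pool$egg_id[pr[2, sel]],
                      label = factor(rep(c("same", "different"),
                                         c(length(sel_same), length(sel_diff))),
                                     levels = c("same", "different")),
                      feats, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

# Train one same/different forest on a pair-training set.
.train_pair_rf <- function(training, ntree) {
  if (nlevels(droplevels(training$label)) < 2)
    stop("degenerate training set: single class")
  fx <- as.matrix(training[, grep("^d_", names(training)), drop = FALSE])
  randomForest::randomForest(fx, training$label, ntree = ntree)
}

# Within-clutch comparison pairs of a layout: all 15 pairs in game 1,
# candidate x known-host pairs (8) in game 2.
.layout_pairs <- function(pc) {
  if (pc$game == 1) {
    pr <- utils::combn(pc$egg_ids, 2)
    data.frame(egg_a = pr[1, ], egg_b = pr[2, ], stringsAsFactors = FALSE)
  } else {
    expand.grid(egg_a = pc$candidates, egg_b = pc$known_hosts,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
}

# Tally 'different' verdicts into votes; each verdict credits both pair
# members once per direction (x2), so a game-1 egg accrues up to 10
# comparisons per repeat (2 x 5 pairs).
.tally_votes <- function(pc, pair_df, verdicts_by_repeat) {
  eggs <- if (pc$game == 1) pc$egg_ids else c(pc$candidates, pc$known_hosts)
  votes <- stats::setNames(integer(length(eggs)), eggs)
  for (v in verdicts_by_repeat) {
    diff_rows <- which(v == "different")
    for (i in diff_rows) {
      votes[pair_df$egg_a[i]] <- votes[pair_df$egg_a[i]] + 2L
      votes[pair_df$egg_b[i]] <- votes[pair_df$egg_b[i]] + 2L
    }
  }
  cand <- if (pc$game == 1) pc$egg_ids else pc$candidates
  cv <- votes[cand]
  top <- names(cv)[cv == max(cv)]
  structure(list(per_egg_votes = votes, n_repeats = length(verdicts_by_repeat),
                 called_egg = if (length(top) == 1) top else NA_character_,
                 ambiguous = length(top) > 1,
                 margin = if (length(cv) > 1) diff(sort(cv, decreasing = TRUE)[2:1]) else NA_integer_,
                 truth = pc$parasite_id),
            class = "vote_tally")
}

#' @export
print.vote_tally <- function(x, ...) {
  cat("<vote_tally> over", x$n_repeats, "repeat(s):",
      if (x$ambiguous) "ambiguous" else paste("called", x$called_egg), "\n")
  print(x$per_egg_votes)
  invisible(x)
}

#' Supervised same/different identification of the parasitic egg
#'
#' Per repeat, a balanced pair-training set is drawn from the pool (fresh
#' sub-seed), a same/different random forest is trained, and all
#' within-clutch comparison pairs of the layout are classified; every
#' 'different' verdict credits both eggs of the pair, counted once per
#' direction. Votes are summed over repeats and the egg with the most
#' 'different' votes is called parasitic; ties are reported as ambiguous,
#' never broken. Under `mode = "loco"` (leave-one-clutch-out) the training
#' pool excludes every egg of the tested host female; under `mode = "leo"`
#' (leave-one-egg-out, game 2 only) the four known host eggs join the pool
#' and all their mutual pairs are forced into the 'same' class.
#'
#' @param pc a `parasitized_clutch` layout.
#' @param pool scaled trait table of all eggs (including the layout's).
#' @param mode `"loco"` or `"leo"`.
#' @param n_repeats training repeats (default 10).
#' @param n_same,n_diff training pair counts (defaults 265).
#' @param ntree trees per forest (default 500).
#' @param seed master seed.
#' @return a `vote_tally`.
#' @export
supervised_identify <- function(pc, pool, mode = c("loco", "leo"),
                                n_repeats = 10, n_same = 265, n_diff = 265,
                                ntree = 500, seed = 1) {
  mode <- match.arg(mode)
  evaluate_layouts(list(pc), pool, mode = mode, n_repeats = n_repeats,
                   n_same = n_same, n_diff = n_diff, ntree = ntree,
                   seed = seed)[[1]]
}

#' Evaluate many parasitized-clutch layouts efficiently
#'
#' Same procedure as [supervised_identify], vectorised over layouts:
#' layouts sharing a training pool (same host clutch under
#' leave-one-clutch-out; same host clutch and known-host set under
#' leave-one-egg-out) share the per-repeat forests.
#'
#' @param layouts list of `parasitized_clutch` objects (all the same game).
#' @param pool scaled trait table of all eggs.
#' @inheritParams supervised_identify
#' @return list of `vote_tally`, one per layout, in input order.
#' @export
evaluate_layouts <- function(layouts, pool, mode = c("loco", "leo"),
                             n_repeats = 10, n_same = 265, n_diff = 265,
                             ntree = 500, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(length(layouts) >= 1)
  games <- vapply(layouts, function(l) l$game, 0L)
  if (length(unique(games)) != 1) stop("layouts must share a game")
  if (mode == "leo" && games[1] != 2) stop("leave-one-egg-out is defined for game 2 only")
  X <- .trait_matrix(pool)
  keys <- vapply(layouts, function(l) {
    if (mode == "loco") l$host_clutch
    else paste(l$host_clutch, paste(sort(l$known_hosts), collapse = "+"))
  }, "")
  groups <- split(seq_along(layouts), keys)
  # independent sub-seed streams for pair sampling and for forest training,
  # so results are bit-reproducible regardless of ambient RNG state
  all_seeds <- derive_seeds(seed, 2L * length(groups) * n_repeats)
  seeds <- matrix(all_seeds[seq_len(length(groups) * n_repeats)],
                  nrow = length(groups))
  rf_seeds <- matrix(all_seeds[-seq_len(length(groups) * n_repeats)],
                     nrow = length(groups))
  tallies <- vector("list", length(layouts))
  for (gi in seq_along(groups)) {
    li <- groups[[gi]]
    l0 <- layouts[[li[1]]]
    if (mode == "loco") {
      train_pool <- pool[pool$clutch_id != l0$host_clutch, , drop = FALSE]
      forced <- NULL
    } else {
      train_pool <- pool[pool$clutch_id != l0$host_clutch |
                           pool$egg_id %in% l0$known_hosts, , drop = FALSE]
      forced <- l0$known_hosts
    }
    pair_dfs <- lapply(layouts[li], .layout_pairs)
    all_pairs <- do.call(rbind, pair_dfs)
    feats <- .pair_features(X, match(all_pairs$egg_a, rownames(X)),
                            match(all_pairs$egg_b, rownames(X)))
    nper <- vapply(pair_dfs, nrow, 0L)
    verdicts <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      training <- build_pair_training(train_pool, n_same, n_diff,
                                      seed = seeds[gi, r],
                                      forced_host_eggs = forced)
      rf <- with_seed(rf_seeds[gi, r], .train_pair_rf(training, ntree))
      verdicts[[r]] <- as.character(predict(rf, feats))
    }
    off <- c(0L, cumsum(nper))
    for (j in seq_along(li)) {
      rows <- (off[j] + 1L):off[j + 1L]
      tallies[[li[j]]] <- .tally_votes(layouts[[li[j]]], pair_dfs[[j]],
                                       lapply(verdicts, `[`, rows))
    }
  }
  tallies
}

#' Accuracy summary from counts
#'
#' Ambiguity-excluding accuracy:
#' `accuracy_pct = 100 * n_correct / (n_total - n_ambiguous)`.
#'
#' @param n_total total trials.
#' @param n_ambiguous trials excluded as ambiguous (vote ties).
#' @param n_correct correct calls among the non-ambiguous trials.
#' @return list of class `accuracy_summary`.
#' @export
accuracy_summary <- function(n_total, n_ambiguous, n_correct) {
  stopifnot(n_total >= 0, n_ambiguous >= 0, n_correct >= 0,
            n_ambiguous <= n_total, n_correct <= n_total - n_ambiguous)
  denom <- n_total - n_ambiguous
  structure(list(n_total = n_total, n_ambiguous = n_ambiguous,
                 n_correct = n_correct,
                 accuracy_pct = if (denom > 0) 100 * n_correct / denom else NA_real_),
            class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf("<accuracy_summary> %d/%d correct (%d ambiguous excluded): %.1f%%\n",
              x$n_correct, x$n_total - x$n_ambiguous, x$n_ambiguous,
              x$accuracy_pct))
  invisible(x)
}

#' Summarise identification accuracy over a set of tallies
#'
#' @param tallies list of `vote_tally` (or any list whose elements have
#'   `called_egg` and `ambiguous`).
#' @param truth character vector of true parasite egg ids, aligned with
#'   `tallies`; defaults to the truth stored in the tallies.
#' @return an [accuracy_summary].
#' @export
summarize_accuracy <- function(tallies, truth = NULL) {
  if (is.null(truth))
    truth <- vapply(tallies, function(t) t$truth %||% NA_character_, "")
  stopifnot(length(truth) == length(tallies))
  amb <- vapply(tallies, function(t) isTRUE(t$ambiguous), TRUE)
  called <- vapply(tallies, function(t) t$called_egg %||% NA_character_, "")
  accuracy_summary(length(tallies), sum(amb),
                   sum(!amb & called == truth, na.rm = TRUE))
}
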