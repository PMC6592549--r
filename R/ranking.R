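#' Charged-interaction score of one pose set
#'
#' The per-run model score: the fraction of docked poses forming the ionic
#' contact with the anchor carboxylate.  Reported with its exact rational
#' form alongside the float.
#'
#' @param records data.frame of interaction records (from
#'   [ionic_contacts()]), needing a logical `ionic_to_anchor` column.
#' @return list with `score` (k/n as double), `n_interacting`, `n_poses`,
#'   `fraction` (exact "k/n" string).
#' @export
score_pose_set <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("cannot score an empty record set")
  k <- sum(records$ionic_to_anchor)
  n <- nrow(records)
  list(score = k / n, n_interacting = k, n_poses = n,
       fraction = sprintf("%d/%d", k, n))
}

#' Aggregate replicate-run scores for one model
#'
#' Replicate docking runs control for the stochastic search; the model score
#' is the arithmetic mean of the per-run fractions (not the pooled fraction,
#' which is also reported for transparency when pose counts are given).
#'
#' @param per_run named numeric vector of per-run scores in \[0, 1\].
#' @param n_poses optional per-run pose counts (for the pooled score).
#' @return list with `aggregate`, `per_run`, `discrepancy` (max - min) and
#'   `pooled` (NA unless `n_poses` given).
#' @export
aggregate_runs <- function(per_run, n_poses = NULL) {
  if (!length(per_run)) stop("need at least one run")
  if (any(per_run < 0 | per_run > 1)) stop("scores must lie in [0, 1]")
  pooled <- NA_real_
  if (!is.null(n_poses)) {
    stopifnot(length(n_poses) == length(per_run))
    pooled <- sum(per_run * n_poses) / sum(n_poses)
  }
  list(aggregate = mean(per_run), per_run = per_run,
       discrepancy = max(per_run) - min(per_run), pooled = pooled)
}

#' Rank models by aggregated charged-interaction score
#'
#' Orders models by aggregate score (descending); ties are broken by smaller
#' run discrepancy, then lexically by model id, so the ranking is fully
#' reproducible.  Ranks are the dense permutation 1..n.
#'
#' @param score_table long data.frame with columns `model_id`, `run_id`,
#'   `score` and optionally `n_poses`.
#' @return data.frame of class `model_score_table`, one row per model:
#'   `model_id`, one `score_<run>` column per run, `aggregate`,
#'   `discrepancy`, `pooled`, `rank`, sorted by rank.
#' @export
rank_models <- function(score_table) {
  need <- c("model_id", "run_id", "score")
  missing <- setdiff(need, names(score_table))
  if (length(missing))
    stop("score table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(score_table[c("model_id", "run_id")]))
    stop("duplicate (model_id, run_id) rows in score table")
  sp <- split(score_table, score_table$model_id)
  runs <- sort(unique(score_table$run_id))
  rows <- lapply(sp, function(d) {
    per_run <- stats::setNames(d$score[match(runs, d$run_id)], runs)
    if (anyNA(per_run))
      stop("model ", d$model_id[1], " lacks run(s): ",
           paste(runs[is.na(per_run)], collapse = ", "))
    agg <- aggregate_runs(per_run,
                          n_poses = if ("n_poses" %in% names(d))
                            d$n_poses[match(runs, d$run_id)] else NULL)
    out <- data.frame(model_id = d$model_id[1], stringsAsFactors = FALSE)
    for (r in runs) out[[paste0("score_", r)]] <- per_run[[r]]
    out$aggregate <- agg$aggregate
    out$discrepancy <- agg$discrepancy
    out$pooled <- agg$pooled
    out
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$aggregate, tab$discrepancy, tab$model_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("model_score_table", "data.frame")
  tab
}

#' @export
print.model_score_table <- function(x, n = 10L, ...) {
  cat("Model score table:", nrow(x), "models,",
      sum(startsWith(names(x), "score_")), "run(s)\n")
  cat(sprintf("  top score %.4f (%s), median %.4f, %d model(s) at 0\n",
              x$aggregate[1], x$model_id[1], stats::median(x$aggregate),
              sum(x$aggregate == 0)))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Select the k best and k worst ranked models
#'
#' @param ranked a `model_score_table` from [rank_models()].
#' @param k group size (default 10); requires at least `2k` models so the
#'   groups are disjoint.
#' @return list of class `extreme_selection` with `k`, `best`, `worst`
#'   (model-id vectors in rank order).
#' @export
select_extremes <- function(ranked, k = 10L) {
  n <- nrow(ranked)
  if (n < 2L * k)
    stop("need at least 2k = ", 2L * k, " models for disjoint groups, have ",
         n)
  structure(list(k = as.integer(k),
                 best = ranked$model_id[seq_len(k)],
                 worst = ranked$model_id[seq.int(n - k + 1L, n)]),
            class = "extreme_selection")
}

#' @export
print.extreme_selection <- function(x, ...) {
  cat("Extreme groups (k =", x$k, ")\n  best: ",
      paste(x$best, collapse = ", "), "\n  worst:",
      paste(x$worst, collapse = ", "), "\n")
  invisible(x)
}

#' Distribution summary of model scores
#'
#' Quartiles plus, per threshold t, the number and fraction of models with
#' score <= t (default thresholds 0 and 0.1, the two the score distribution
#' of a model ensemble is usually summarized by).
#'
#' @param scores numeric vector of aggregate model scores.
#' @param thresholds numeric vector of thresholds.
#' @return list with `quartiles` and data.frame `threshold_counts`
#'   (`threshold`, `n_le`, `frac_le`).
#' @export
score_distribution_summary <- function(scores, thresholds = c(0, 0.1)) {
  if (!length(scores)) stop("no scores to summarize")
  list(quartiles = stats::quantile(scores, c(0, 0.25, 0.5, 0.75, 1)),
       threshold_counts = data.frame(
         threshold = thresholds,
         n_le = vapply(thresholds, function(t) sum(scores <= t), 0L),
         frac_le = vapply(thresholds, function(t) mean(scores <= t), 0)))
}

#' Score a collection of pose sets against their receptor models
#'
#' Convenience wrapper running [ionic_contacts()] + [score_pose_set()] over
#' matched (model, pose set) pairs and assembling the long score table for
#' [rank_models()].
#'
#' @param models named list of `receptor_model`s (names = model ids).
#' @param pose_sets list of [pose_set()]s (their `model_id` must occur in
#'   `models`).
#' @param bwmap a `bw_map`.
#' @param site a [binding_site_spec()].
#' @param criterion an [ionic_criterion()].
#' @return long data.frame (`model_id`, `run_id`, `score`, `n_poses`,
#'   `n_interacting`).
#' @export
score_models <- function(models, pose_sets, bwmap,
                         site = binding_site_spec(),
                         criterion = ionic_criterion()) {
  anchors <- lapply(models, resolve_bw, bwmap = bwmap,
                    bw_label = site$anchor)
  rows <- lapply(pose_sets, function(ps) {
    anchor <- anchors[[ps$model_id]]
    if (is.null(anchor))
      stop("pose set references unknown model '", ps$model_id, "'")
    s <- score_pose_set(ionic_contacts(ps, anchor, criterion))
    data.frame(model_id = ps$model_id, run_id = ps$run_id, score = s$score,
               n_poses = s$n_poses, n_interacting = s$n_interacting,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
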