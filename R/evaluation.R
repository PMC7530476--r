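#' Jackknife level values for the positive proteins
#'
#' Each positive `q` is singled out in turn: it joins the unlabelled pool
#' (pool size `|unlabelled| + 1`), the pool is re-partitioned into `P`
#' parts with a fresh seed derived from `seed` and `q`'s rank, `P` forests
#' are trained on the remaining positives plus each part, and `q`'s level
#' value is the mean vote-fraction probability from the `P - 1` models
#' whose training part does not contain it.
#'
#' @param features Feature matrix with id rownames.
#' @param labels A `label_set` with at least two positives.
#' @param P Number of negative parts (e.g. from
#'   [choose_partition_count()]).
#' @param params An [rf_params()].
#' @param seed Base seed for the per-positive partitions.
#' @return A `level_value_table` over the positives.
#' @export
jackknife_positive_scores <- function(features, labels, P,
                                      params = rf_params(), seed = 1L) {
  pos <- labels$positives
  if (length(pos) < 2L) stop("jackknife needs at least two positives")
  lv <- numeric(length(pos))
  for (qi in seq_along(pos)) {
    q <- pos[qi]
    labels_q <- label_set(setdiff(pos, q), c(labels$unlabelled, q))
    part_q <- partition_negatives(labels_q, P, seed = seed + qi)
    params_q <- params
    params_q$seed <- params$seed + qi * (P + 1L)
    ens_q <- train_ensemble(features, labels_q, part_q, params_q)
    own <- ens_q$part_of[q]
    eligible <- setdiff(seq_len(P), own)
    if (length(eligible) == 0L) eligible <- own
    probs <- vapply(ens_q$models[eligible], function(m) {
      rf_vote_prob(m, features[q, , drop = FALSE])
    }, numeric(1L))
    lv[qi] <- mean(probs)
  }
  structure(data.frame(id = pos, level_value = lv,
                       models_used = if (P > 1L) P - 1L else 1L,
                       stringsAsFactors = FALSE),
            class = c("level_value_table", "data.frame"))
}

#' Confusion counts and threshold metrics
#'
#' A protein is predicted positive iff its level value is strictly larger
#' than the threshold. Sensitivity (recall) is `TP / (TP + FN)`,
#' specificity `TN / (TN + FP)`, precision `TP / (TP + FP)`. When no
#' protein is predicted positive, precision is reported as 1 by convention
#' and flagged via `precision_defined = FALSE`.
#'
#' @param scores A level-value table covering every id in `labels`.
#' @param labels A `label_set`.
#' @param t Threshold.
#' @return List with `TP`, `FP`, `TN`, `FN`, `SN`, `SP`, `precision`,
#'   `precision_defined`.
#' @export
confusion_at_threshold <- function(scores, labels, t) {
  all_ids <- c(labels$positives, labels$unlabelled)
  missing <- setdiff(all_ids, scores$id)
  if (length(missing) > 0L) {
    stop(sprintf("unscored id(s): %s",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  s <- setNames(scores$level_value, scores$id)
  pred_pos <- s[all_ids] > t
  is_pos <- all_ids %in% labels$positives
  TP <- sum(pred_pos & is_pos)
  FP <- sum(pred_pos & !is_pos)
  FN <- sum(!pred_pos & is_pos)
  TN <- sum(!pred_pos & !is_pos)
  prec_def <- (TP + FP) > 0L
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       SN = TP / (TP + FN), SP = TN / (TN + FP),
       precision = if (prec_def) TP / (TP + FP) else 1,
       precision_defined = prec_def)
}

#' ROC and PR curves with AUROC / AUPRC
#'
#' Sweeps the threshold over every distinct score value (prediction rule:
#' level value strictly greater than the threshold). The ROC curve plots
#' sensitivity against 1 - specificity; AUROC is its trapezoidal area and
#' equals the tie-corrected pairwise-comparison (Mann-Whitney) statistic.
#' The PR curve plots precision against recall; AUPRC uses the step-wise
#' rule (precision at each recall increment) by default, since trapezoidal
#' interpolation over-estimates PR area, but `pr_trapezoid = TRUE` switches
#' to trapezoids.
#'
#' @param scores Level-value table covering every id in `labels`.
#' @param labels A `label_set` with at least one positive and one negative.
#' @param pr_trapezoid Use trapezoidal PR integration instead of the
#'   step-wise rule.
#' @return An `eval_curves`: list with `roc_points` (`fpr`, `tpr`),
#'   `pr_points` (`recall`, `precision`), `auroc`, `auprc`.
#' @export
roc_pr_curves <- function(scores, labels, pr_trapezoid = FALSE) {
  all_ids <- c(labels$positives, labels$unlabelled)
  if (length(labels$positives) == 0L || length(labels$unlabelled) == 0L) {
    stop("curves need at least one positive and one negative")
  }
  s <- setNames(scores$level_value, scores$id)[all_ids]
  if (anyNA(s)) stop("every id must be scored")
  y <- all_ids %in% labels$positives
  nP <- sum(y); nN <- sum(!y)

  ord <- order(-s)
  s <- s[ord]; y <- y[ord]
  # group ties: cumulative counts at each distinct-score boundary
  boundary <- which(!duplicated(s, fromLast = TRUE))  # last position of each tie group
  cumTP <- cumsum(y)[boundary]
  cumFP <- cumsum(!y)[boundary]

  tpr <- c(0, cumTP / nP)
  fpr <- c(0, cumFP / nN)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)

  recall <- cumTP / nP
  precision <- cumTP / (cumTP + cumFP)
  if (pr_trapezoid) {
    r <- c(0, recall)
    p <- c(precision[1L], precision)
    auprc <- sum(diff(r) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
  } else {
    auprc <- sum(diff(c(0, recall)) * precision)
  }

  structure(list(
    roc_points = data.frame(fpr = fpr, tpr = tpr),
    pr_points = data.frame(recall = recall, precision = precision),
    auroc = auroc, auprc = auprc
  ), class = "eval_curves")
}

#' @export
print.eval_curves <- function(x, ...) {
  cat(sprintf("eval_curves: AUROC = %.4f, AUPRC = %.4f (%d ROC points)\n",
              x$auroc, x$auprc, nrow(x$roc_points)))
  invisible(x)
}

#' @export
plot.eval_curves <- function(x, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    plot(x$roc_points$fpr, x$roc_points$tpr, type = "l",
         xlab = "1 - specificity", ylab = "sensitivity",
         main = sprintf("ROC (AUROC = %.4f)", x$auroc), ...)
    abline(0, 1, lty = 2, col = "grey")
  } else {
    plot(x$pr_points$recall, x$pr_points$precision, type = "s",
         xlab = "recall", ylab = "precision", ylim = c(0, 1),
         main = sprintf("PR (AUPRC = %.4f)", x$auprc), ...)
  }
  invisible(x)
}

#' Score every protein and evaluate the ranking
#'
#' Convenience wrapper for the full scoring stage at a fixed embedding:
#' trains the negative-partition ensemble to obtain unlabelled level
#' values, runs the jackknife for positive level values, and computes
#' ROC/PR curves over the combined table.
#'
#' @param features Feature matrix with id rownames.
#' @param labels A `label_set`.
#' @param P Number of parts, or `"auto"` for the floor rule.
#' @param params An [rf_params()].
#' @param seed Base seed for partitions.
#' @return List with `P`, `levels` (unlabelled table), `jackknife`
#'   (positives table), `scores` (combined table) and `curves`.
#' @export
evaluate_prioritization <- function(features, labels, P = "auto",
                                    params = rf_params(), seed = 1L) {
  if (identical(P, "auto")) {
    P <- choose_partition_count(length(labels$unlabelled),
                                length(labels$positives))
  }
  partition <- partition_negatives(labels, P, seed = seed)
  ensemble <- train_ensemble(features, labels, partition, params)
  levels_tab <- level_values(ensemble, features, labels)
  jack <- jackknife_positive_scores(features, labels, P, params, seed = seed)
  scores <- rbind(jack, levels_tab)
  scores <- scores[order(scores$id), ]
  rownames(scores) <- NULL
  curves <- roc_pr_curves(scores, labels)
  list(P = P, levels = levels_tab, jackknife = jack,
       scores = scores, curves = curves)
}

#' Embedding-dimension sweep
#'
#' Re-runs embed -> score -> evaluate for each candidate dimension and
#' selects the dimension maximizing the average of AUROC and AUPRC (ties
#' go to the smaller dimension, which is cheaper and less noisy).
#'
#' @param profiles A `diffusion_profile`.
#' @param labels A `label_set`.
#' @param dims Integer vector of dimensions to try.
#' @param base_config An [embedding_config()] whose `d` is overridden per
#'   sweep row.
#' @param P Parts, or `"auto"`.
#' @param params An [rf_params()].
#' @param seed Base seed for partitions.
#' @return List with `rows` (data frame `d`, `auroc`, `auprc`, `average`)
#'   and `selected` (the chosen dimension).
#' @export
dimension_sweep <- function(profiles, labels, dims,
                            base_config = embedding_config(),
                            P = "auto", params = rf_params(), seed = 1L) {
  if (length(dims) == 0L) stop("dims must be non-empty")
  rows <- lapply(dims, function(d) {
    cfg <- base_config
    cfg$d <- as.integer(d)
    model <- fit_embedding(profiles, cfg)
    X <- feature_matrix(model)
    ev <- evaluate_prioritization(X, labels, P = P, params = params,
                                  seed = seed)
    data.frame(d = d, auroc = ev$curves$auroc, auprc = ev$curves$auprc,
               average = (ev$curves$auroc + ev$curves$auprc) / 2)
  })
  rows <- do.call(rbind, rows)
  best <- rows$d[order(-rows$average, rows$d)][1L]
  list(rows = rows, selected = best)
}
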