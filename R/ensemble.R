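#' Number of negative parts from the class-imbalance ratio
#'
#' The unlabelled pool is split into `floor(n_neg / n_pos)` parts (minimum
#' 1), so each part is approximately the size of the positive set and every
#' training set is roughly balanced. With 18,766 unlabelled and 481
#' positive proteins this gives 39 parts.
#'
#' @param n_neg Number of unlabelled (negative-by-convention) samples.
#' @param n_pos Number of positive samples (>= 1).
#' @return Integer part count.
#' @export
choose_partition_count <- function(n_neg, n_pos) {
  if (n_pos < 1L) stop("at least one positive sample is required")
  max(1L, as.integer(floor(n_neg / n_pos)))
}

#' Randomly partition the unlabelled pool
#'
#' Seeded uniform shuffle followed by a round-robin split into `P` parts,
#' so part sizes differ by at most one. Deterministic per seed.
#'
#' @param labels A `label_set` (or character vector of unlabelled ids).
#' @param P Number of parts.
#' @param seed Integer seed.
#' @return A `partition_scheme`: list with `parts` (list of id vectors),
#'   `P` and `seed`.
#' @export
partition_negatives <- function(labels, P, seed = 1L) {
  ids <- if (inherits(labels, "label_set")) labels$unlabelled else sort(labels)
  P <- as.integer(P)
  if (P < 1L) stop("P must be >= 1")
  if (P > length(ids)) {
    stop(sprintf("cannot split %d unlabelled ids into %d parts", length(ids), P))
  }
  set.seed(seed)
  shuffled <- sample(ids)
  parts <- split(shuffled, rep_len(seq_len(P), length(shuffled)))
  names(parts) <- NULL
  structure(list(parts = parts, P = P, seed = as.integer(seed)),
            class = "partition_scheme")
}

#' Random-forest parameters
#'
#' @param n_trees Trees per forest; default 10.
#' @param mtry Features tried per split; default `floor(log2(d)) + 1` where
#'   `d` is the feature dimension (resolved at fit time), capped at `d`.
#' @param seed Base seed; model `k` of an ensemble uses `seed + k`.
#' @return An `rf_params` list.
#' @export
rf_params <- function(n_trees = 10L, mtry = NULL, seed = 1L) {
  stopifnot(n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed)),
            class = "rf_params")
}

resolve_mtry <- function(params, d) {
  m <- params$mtry %||% (floor(log2(d)) + 1L)
  as.integer(min(m, d))
}

fit_one_rf <- function(X, y, params, seed) {
  df <- as.data.frame(unclass(X))
  df$.y <- y
  ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = params$n_trees,
    mtry = resolve_mtry(params, ncol(X)),
    seed = seed, num.threads = 1L
  )
}

# fraction of trees voting for the positive class, for each row of X
rf_vote_prob <- function(model, X) {
  pred <- predict(model, as.data.frame(unclass(X)),
                  predict.all = TRUE, num.threads = 1L)$predictions
  pos_code <- which(model$forest$levels == "pos")
  rowMeans(pred == pos_code)
}

#' Train the negative-partition random-forest ensemble
#'
#' Model `k` is a random forest trained on all positives (label `pos`)
#' together with negative part `k` (label `neg`). Per-model seeds are
#' `params$seed + k`, so the whole ensemble is reproducible.
#'
#' @param features Numeric feature matrix with protein ids as rownames.
#' @param labels A `label_set`.
#' @param partition A `partition_scheme` over `labels$unlabelled`.
#' @param params An [rf_params()].
#' @return A `trained_ensemble`: list with `models` (length `P`), `part_of`
#'   (named integer mapping each unlabelled id to its part), `P`, `params`.
#' @export
train_ensemble <- function(features, labels, partition, params = rf_params()) {
  stopifnot(inherits(labels, "label_set"),
            inherits(partition, "partition_scheme"))
  needed <- c(labels$positives, labels$unlabelled)
  missing <- setdiff(needed, rownames(features))
  if (length(missing) > 0L) {
    stop(sprintf("no feature row for id(s): %s",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  if (!setequal(unlist(partition$parts), labels$unlabelled)) {
    stop("partition does not cover the unlabelled set")
  }
  models <- vector("list", partition$P)
  for (k in seq_len(partition$P)) {
    ids_k <- c(labels$positives, partition$parts[[k]])
    y <- factor(rep(c("pos", "neg"),
                    c(length(labels$positives), length(partition$parts[[k]]))),
                levels = c("neg", "pos"))
    models[[k]] <- fit_one_rf(features[ids_k, , drop = FALSE], y,
                              params, seed = params$seed + k)
  }
  part_of <- integer(0)
  for (k in seq_len(partition$P)) {
    part_of[partition$parts[[k]]] <- k
  }
  structure(list(models = models, part_of = part_of, P = partition$P,
                 params = params),
            class = "trained_ensemble")
}

#' Level values of the unlabelled proteins
#'
#' Each unlabelled protein is scored by the `P - 1` ensemble models whose
#' training part does not contain it; a single model's probability is the
#' fraction of its trees voting positive, and the level value is the mean
#' over the eligible models. Positives are not scored here (their scores
#' come from the jackknife in the evaluation stage).
#'
#' @param ensemble A `trained_ensemble`.
#' @param features Feature matrix with id rownames.
#' @param labels A `label_set`.
#' @return A `level_value_table` data frame: `id`, `level_value`,
#'   `models_used`, sorted by id.
#' @export
level_values <- function(ensemble, features, labels) {
  ids <- labels$unlabelled
  X <- features[ids, , drop = FALSE]
  P <- ensemble$P
  prob <- vapply(ensemble$models, function(m) rf_vote_prob(m, X),
                 numeric(length(ids)))
  prob <- matrix(prob, nrow = length(ids))
  own <- ensemble$part_of[ids]
  if (P > 1L) {
    lv <- (rowSums(prob) - prob[cbind(seq_along(ids), own)]) / (P - 1L)
    used <- P - 1L
  } else {
    # degenerate single-part ensemble: the only model contains every id
    lv <- prob[, 1L]
    used <- 1L
  }
  structure(data.frame(id = ids, level_value = lv, models_used = used,
                       stringsAsFactors = FALSE),
            class = c("level_value_table", "data.frame"))
}

#' Rank candidates by decreasing level value
#'
#' Ties are broken by lexicographic id so the ranking is deterministic.
#'
#' @param table A `level_value_table` (any data frame with `id` and
#'   `level_value` columns).
#' @return Character vector of ids, best candidate first.
#' @export
rank_candidates <- function(table) {
  if (nrow(table) == 0L) stop("empty level-value table")
  table$id[order(-table$level_value, table$id)]
}
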