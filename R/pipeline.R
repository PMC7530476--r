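#' Run the full prioritization pipeline
#'
#' Chains the four stages: random-walk diffusion over every channel, joint
#' KL embedding, negative-partition random-forest scoring of the
#' unlabelled proteins, and the leave-one-positive-out jackknife with
#' ROC/PR evaluation. With fixed seeds the whole pipeline is
#' bit-reproducible.
#'
#' @param collection A `network_collection`.
#' @param labels A `label_set` over the collection's index.
#' @param alpha Restart probability of the random walk (default 0.5).
#' @param config An [embedding_config()].
#' @param P Number of negative parts, or `"auto"` for the floor rule.
#' @param params An [rf_params()].
#' @param seed Base seed for the partition draws.
#' @param tol,max_iter Random-walk convergence controls.
#' @return List with `features` (the embedding matrix), `P`, `levels`,
#'   `jackknife`, `scores` and `curves` (see
#'   [evaluate_prioritization()]).
#' @export
run_pipeline <- function(collection, labels, alpha = 0.5,
                         config = embedding_config(), P = "auto",
                         params = rf_params(), seed = 1L,
                         tol = 1e-8, max_iter = 1000L) {
  profiles <- diffuse_all(collection, alpha = alpha, tol = tol,
                          max_iter = max_iter)
  model <- fit_embedding(profiles, config)
  X <- feature_matrix(model)
  ev <- evaluate_prioritization(X, labels, P = P, params = params,
                                seed = seed)
  c(list(features = X), ev)
}

#' Write a level-value table as TSV
#'
#' Columns: `rank`, `id`, `level_value`, `models_used`, ordered by
#' decreasing level value (ties by id), mirroring a supplementary-style
#' full ranking table.
#'
#' @param table A `level_value_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_level_values <- function(table, path) {
  ord <- order(-table$level_value, table$id)
  out <- data.frame(rank = seq_len(nrow(table)),
                    table[ord, c("id", "level_value", "models_used")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a level-value table written by [write_level_values()]
#'
#' @param path TSV path.
#' @return A `level_value_table`.
#' @export
read_level_values <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(id = "character"))
  structure(df[order(df$id),
               c("id", "level_value", intersect("models_used", names(df)))],
            class = c("level_value_table", "data.frame"))
}
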