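# percentages formatted the conventional way: round half up to 2 decimals
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Candidate set above a level-value threshold
#'
#' Membership uses strict inequality (`level value > t`), consistent with a
#' top-ranked value of 0.8053 entering the 0.8-threshold set.
#'
#' @param table Level-value table (`id`, `level_value`).
#' @param t Threshold.
#' @return A `candidate_set`: list with `threshold` and sorted `ids`.
#' @export
infer_at_threshold <- function(table, t) {
  if (nrow(table) == 0L) stop("empty level-value table")
  structure(list(threshold = t,
                 ids = sort(table$id[table$level_value > t])),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d ids with level value > %g\n",
              length(x$ids), x$threshold))
  invisible(x)
}

#' Percentage of inferred candidates exclusive to this method
#'
#' @param inferred A `candidate_set` (or character vector), non-empty.
#' @param externals List of character vectors: candidate sets of external
#'   methods.
#' @return Percentage (0-100), rounded half-up to 2 decimals.
#' @export
exclusive_fraction <- function(inferred, externals = list()) {
  ids <- if (inherits(inferred, "candidate_set")) inferred$ids else inferred
  if (length(ids) == 0L) stop("inferred candidate set is empty")
  shared_with <- unique(unlist(externals))
  round_half_up(100 * length(setdiff(ids, shared_with)) / length(ids))
}

#' Three-set Venn region counts
#'
#' @param inferred,setA,setB Character vectors (or `candidate_set` for
#'   `inferred`).
#' @return Named integer vector with the seven region counts:
#'   `inferred_only`, `A_only`, `B_only`, `inferred_A`, `inferred_B`,
#'   `A_B` (pairwise-only regions) and `inferred_A_B` (triple).
#' @export
intersection_counts <- function(inferred, setA, setB) {
  I <- unique(if (inherits(inferred, "candidate_set")) inferred$ids else inferred)
  A <- unique(setA)
  B <- unique(setB)
  all_ids <- unique(c(I, A, B))
  inI <- all_ids %in% I
  inA <- all_ids %in% A
  inB <- all_ids %in% B
  c(inferred_only = sum(inI & !inA & !inB),
    A_only = sum(!inI & inA & !inB),
    B_only = sum(!inI & !inA & inB),
    inferred_A = sum(inI & inA & !inB),
    inferred_B = sum(inI & !inA & inB),
    A_B = sum(!inI & inA & inB),
    inferred_A_B = sum(inI & inA & inB))
}

#' Level-value histogram
#'
#' Bins are half-open `(low, high]`; values equal to the lowest edge are
#' counted in the first bin so the closed range `[e_1, e_K]` is fully
#' covered. Values outside the edge range are collected in an overflow
#' count and flagged with a warning.
#'
#' @param table Level-value table.
#' @param bin_edges Strictly increasing numeric vector of edges.
#' @return Data frame `bin_low`, `bin_high`, `count`, `percentage`
#'   (percent of all tabled values), with an `overflow` attribute.
#' @export
distribution_histogram <- function(table, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  v <- table$level_value
  k <- length(bin_edges) - 1L
  lo <- bin_edges[1L]; hi <- bin_edges[length(bin_edges)]
  inside <- v >= lo & v <= hi
  overflow <- sum(!inside)
  if (overflow > 0L) {
    warning(sprintf("%d value(s) outside [%g, %g] counted as overflow",
                    overflow, lo, hi))
  }
  x <- v[inside]
  # (low, high], except values equal to the bottom edge fall in bin 1
  bin <- findInterval(x, bin_edges, left.open = TRUE)
  bin[x == lo] <- 1L
  counts <- tabulate(bin, nbins = k)
  out <- data.frame(bin_low = bin_edges[-length(bin_edges)],
                    bin_high = bin_edges[-1L],
                    count = counts,
                    percentage = if (length(v) > 0L)
                      round_half_up(100 * counts / length(v)) else rep(0, k))
  attr(out, "overflow") <- overflow
  out
}

#' Threshold comparison report against external candidate lists
#'
#' For each threshold, reports the inferred candidate count, the seven
#' Venn regions against two external sets, and the exclusive count and
#' percentage.
#'
#' @param table Level-value table.
#' @param thresholds Numeric vector of thresholds.
#' @param setA,setB External candidate id vectors.
#' @return Data frame, one row per threshold.
#' @export
comparison_report <- function(table, thresholds, setA, setB) {
  rows <- lapply(thresholds, function(t) {
    cs <- infer_at_threshold(table, t)
    venn <- intersection_counts(cs, setA, setB)
    excl <- length(setdiff(cs$ids, union(setA, setB)))
    data.frame(threshold = t,
               n_inferred = length(cs$ids),
               t(venn),
               exclusive = excl,
               exclusive_pct = if (length(cs$ids) > 0L)
                 round_half_up(100 * excl / length(cs$ids)) else NA_real_)
  })
  do.call(rbind, rows)
}
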