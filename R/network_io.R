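#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif setNames predict
#' @importFrom utils read.table write.table
#' @importFrom graphics abline plot
NULL

# Evidence channels recognized in STRING-style headers. "experiment" is
# accepted as an alias for "experimental"; "combined_score" is the Bayesian
# integration of the others and is dropped by default because it is
# redundant with the individual channels.
STRING_CHANNELS <- c(
  "neighborhood", "fusion", "cooccurrence", "coexpression",
  "experimental", "database", "textmining"
)

#' Parse a STRING-style multi-channel protein links file
#'
#' Reads a whitespace- or tab-separated file in the
#' `protein.links.detailed` dialect: a header row naming two protein-ID
#' columns followed by integer score columns, then one record per protein
#' pair. One undirected weighted network is built per score column: an edge
#' exists in a channel iff its score is strictly positive, and the raw score
#' (0-1000 scale) becomes the edge weight. Scores are kept as-is; downstream
#' random-walk normalization makes only relative weights matter.
#'
#' Column discovery is header-driven, so partial files with fewer channels
#' parse. Symmetric duplicate records `(a,b)` / `(b,a)` collapse to a single
#' edge; if their scores disagree parsing aborts. Self-loop records are
#' dropped with a warning, but their IDs still enter the protein index.
#'
#' @param path Path to the links file (or a connection).
#' @param drop_combined Drop the `combined_score` column if present
#'   (default `TRUE`).
#' @return A `network_collection`: list with `ids` (lexicographically sorted
#'   protein index) and `channels` (named list of edge data frames with
#'   columns `from`, `to`, `weight`, canonicalized so `from < to`).
#' @export
parse_string_links <- function(path, drop_combined = TRUE) {
  lines <- readLines(path)
  keep_line <- nzchar(trimws(lines))
  line_no <- which(keep_line)
  lines <- lines[keep_line]
  if (length(lines) == 0L) stop("links file is empty")

  toks <- strsplit(trimws(lines), "[ \t]+")
  header <- tolower(toks[[1]])
  if (length(header) < 3L) {
    stop("header must name two ID columns and at least one score column")
  }
  score_names <- header[-(1:2)]
  score_names[score_names == "experiment"] <- "experimental"
  if (anyDuplicated(score_names)) stop("duplicated score columns in header")

  records <- toks[-1L]
  rec_line <- line_no[-1L]
  if (length(records) == 0L) stop("links file has a header but no records")

  bad <- which(lengths(records) != length(header))
  if (length(bad) > 0L) {
    stop(sprintf("malformed record at line %d: expected %d fields, found %d",
                 rec_line[bad[1L]], length(header), lengths(records)[bad[1L]]))
  }

  flat <- matrix(unlist(records, use.names = FALSE),
                 ncol = length(header), byrow = TRUE)
  a <- flat[, 1L]
  b <- flat[, 2L]
  scores <- suppressWarnings(
    matrix(as.numeric(flat[, -(1:2), drop = FALSE]), ncol = length(score_names))
  )
  bad <- which(rowSums(is.na(scores) | scores < 0) > 0L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed score at line %d: scores must be integers >= 0",
                 rec_line[bad[1L]]))
  }
  colnames(scores) <- score_names

  ids <- sort(unique(c(a, b)))

  self <- a == b
  if (any(self)) {
    warning(sprintf("dropped %d self-loop record(s)", sum(self)))
    a <- a[!self]; b <- b[!self]
    scores <- scores[!self, , drop = FALSE]
    rec_line <- rec_line[!self]
  }

  # canonical unordered pair: from < to
  from <- pmin(a, b)
  to <- pmax(a, b)
  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key)) {
    first <- match(key, key)
    dup <- which(first != seq_along(key))
    conflict <- dup[rowSums(scores[dup, , drop = FALSE] !=
                            scores[first[dup], , drop = FALSE]) > 0L]
    if (length(conflict) > 0L) {
      stop(sprintf("conflicting duplicate scores for pair (%s, %s) at line %d",
                   from[conflict[1L]], to[conflict[1L]], rec_line[conflict[1L]]))
    }
    keep <- first == seq_along(key)
    from <- from[keep]; to <- to[keep]
    scores <- scores[keep, , drop = FALSE]
  }

  keep_cols <- score_names
  if (drop_combined) keep_cols <- setdiff(keep_cols, "combined_score")
  channels <- lapply(keep_cols, function(ch) {
    w <- scores[, ch]
    sel <- w > 0
    data.frame(from = from[sel], to = to[sel], weight = w[sel],
               stringsAsFactors = FALSE)
  })
  names(channels) <- keep_cols

  new_network_collection(ids, channels)
}

new_network_collection <- function(ids, channels) {
  structure(list(ids = ids, channels = channels),
            class = "network_collection")
}

#' Validate a network collection
#'
#' Checks the structural invariants every channel network must satisfy:
#' strictly positive weights, no self-loops, at most one edge per unordered
#' pair, and all endpoints present in the shared protein index.
#'
#' @param x A `network_collection`.
#' @return `x`, invisibly; aborts on violation.
#' @export
validate_collection <- function(x) {
  stopifnot(inherits(x, "network_collection"))
  if (length(x$ids) < 1L) stop("protein index is empty")
  if (anyDuplicated(x$ids)) stop("protein index has duplicated ids")
  if (is.unsorted(x$ids)) stop("protein index must be sorted")
  if (length(x$channels) < 1L) stop("collection has no channels")
  if (anyDuplicated(names(x$channels))) stop("channel names must be distinct")
  for (ch in names(x$channels)) {
    e <- x$channels[[ch]]
    if (nrow(e) == 0L) next
    if (any(e$weight <= 0)) stop(sprintf("channel %s has non-positive weights", ch))
    if (any(e$from == e$to)) stop(sprintf("channel %s has self-loops", ch))
    if (any(e$from > e$to)) stop(sprintf("channel %s edges not canonicalized", ch))
    if (anyDuplicated(paste(e$from, e$to, sep = "\r"))) {
      stop(sprintf("channel %s has duplicated edges", ch))
    }
    if (!all(c(e$from, e$to) %in% x$ids)) {
      stop(sprintf("channel %s references ids outside the index", ch))
    }
  }
  invisible(x)
}

#' @export
print.network_collection <- function(x, ...) {
  cat(sprintf("network_collection: %d proteins, %d channel(s)\n",
              length(x$ids), length(x$channels)))
  s <- network_stats(x)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Load the positive / unlabelled label partition
#'
#' Reads a plain-text list of positive protein IDs (one per line, `#`
#' comments and blank lines allowed) and partitions the protein index into
#' positives and unlabelled proteins. Listed IDs absent from the index are
#' dropped with a message (they cannot be scored without network features)
#' and recorded in the `dropped` attribute.
#'
#' @param path Path to the positives file (or a connection), or a character
#'   vector of IDs.
#' @param collection A `network_collection` (or a character vector of ids)
#'   providing the protein index.
#' @return A `label_set`: list with sorted `positives` and `unlabelled`.
#' @export
load_labels <- function(path, collection) {
  ids <- if (inherits(collection, "network_collection")) collection$ids
         else sort(collection)
  listed <- if (is.character(path) && length(path) > 1L) path else {
    x <- readLines(path)
    x <- sub("#.*$", "", x)
    x <- trimws(x)
    x[nzchar(x)]
  }
  listed <- unique(listed)
  dropped <- setdiff(listed, ids)
  pos <- intersect(listed, ids)
  if (length(dropped) > 0L) {
    message(sprintf("dropped %d listed id(s) absent from the network index: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")))
  }
  if (length(pos) == 0L) stop("no positives remain after filtering against the index")
  out <- label_set(pos, setdiff(ids, pos))
  attr(out, "dropped") <- dropped
  out
}

#' Construct a label set
#'
#' @param positives Character vector of positive ids.
#' @param unlabelled Character vector of unlabelled ids.
#' @return A `label_set` with both components sorted.
#' @export
label_set <- function(positives, unlabelled) {
  positives <- sort(unique(positives))
  unlabelled <- sort(unique(unlabelled))
  if (length(intersect(positives, unlabelled)) > 0L) {
    stop("positives and unlabelled sets overlap")
  }
  if (length(positives) < 1L) stop("at least one positive is required")
  structure(list(positives = positives, unlabelled = unlabelled),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label_set: %d positives, %d unlabelled\n",
              length(x$positives), length(x$unlabelled)))
  invisible(x)
}

#' Per-channel network summary
#'
#' @param collection A `network_collection`.
#' @return Data frame with one row per channel: `channel`, `nodes` (count of
#'   nodes with degree >= 1) and `edges` (each undirected edge counted once).
#' @export
network_stats <- function(collection) {
  stopifnot(inherits(collection, "network_collection"))
  rows <- lapply(names(collection$channels), function(ch) {
    e <- collection$channels[[ch]]
    data.frame(channel = ch,
               nodes = length(unique(c(e$from, e$to))),
               edges = nrow(e),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize a collection to a STRING-dialect links file
#'
#' Writes one record per unordered protein pair that carries a positive
#' score in at least one channel, with a header naming the channels.
#' `parse_string_links()` on the output reproduces the collection exactly.
#'
#' @param collection A `network_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_string_links <- function(collection, path) {
  validate_collection(collection)
  chs <- names(collection$channels)
  all_pairs <- unique(do.call(rbind, lapply(collection$channels,
                                            function(e) e[c("from", "to")])))
  if (is.null(all_pairs) || nrow(all_pairs) == 0L) {
    all_pairs <- data.frame(from = character(), to = character())
  }
  # all-zero records keep isolated ids in the index across a round trip
  connected <- unique(c(all_pairs$from, all_pairs$to))
  isolated <- setdiff(collection$ids, connected)
  if (length(isolated) > 0L) {
    partner <- vapply(isolated, function(id) {
      other <- collection$ids[collection$ids != id]
      if (length(other) > 0L) other[1L] else id
    }, character(1L))
    all_pairs <- rbind(all_pairs,
                       data.frame(from = pmin(isolated, partner),
                                  to = pmax(isolated, partner)))
    all_pairs <- unique(all_pairs)
  }
  key <- paste(all_pairs$from, all_pairs$to, sep = "\r")
  out <- all_pairs[order(key), , drop = FALSE]
  okey <- paste(out$from, out$to, sep = "\r")
  for (ch in chs) {
    e <- collection$channels[[ch]]
    w <- numeric(nrow(out))
    w[match(paste(e$from, e$to, sep = "\r"), okey)] <- e$weight
    out[[ch]] <- w
  }
  names(out)[1:2] <- c("protein1", "protein2")
  write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a positives list
#'
#' @param labels A `label_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  writeLines(labels$positives, path)
  invisible(path)
}
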