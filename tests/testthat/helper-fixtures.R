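# Shared fixtures and independent oracles, all built in code.

# Three-record STRING-dialect fixture: neighborhood scores {0, 150, 0},
# textmining scores {800, 0, 700}.
links_fixture_lines <- function() {
  c("protein1 protein2 neighborhood textmining",
    "A B 0 800",
    "A C 150 0",
    "B C 0 700")
}

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

make_collection <- function(ids, channels) {
  cl <- lapply(channels, function(e) {
    data.frame(from = pmin(e$from, e$to), to = pmax(e$from, e$to),
               weight = e$weight, stringsAsFactors = FALSE)
  })
  structure(list(ids = sort(ids), channels = cl),
            class = "network_collection")
}

# random connected-ish weighted network over n nodes for RWR oracle tests
random_edges <- function(n, p = 0.4) {
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  ids <- sprintf("N%03d", seq_len(n))
  data.frame(from = ids[pairs[1, keep]], to = ids[pairs[2, keep]],
             weight = sample(1:1000, sum(keep), replace = TRUE),
             stringsAsFactors = FALSE)
}

# independent oracle: RWR fixed point by direct linear solve
rwr_solve <- function(model, seed_node) {
  n <- length(model$ids)
  Tm <- as.matrix(model$transition)
  e <- as.numeric(model$ids == seed_node)
  a <- model$alpha
  unname(drop(solve(diag(n) - (1 - a) * Tm, a * e)))
}

# independent oracle: AUROC as the tie-corrected pairwise statistic
brute_auroc <- function(scores_pos, scores_neg) {
  comp <- outer(scores_pos, scores_neg,
                function(a, b) (a > b) + 0.5 * (a == b))
  mean(comp)
}

as_score_table <- function(ids, values) {
  data.frame(id = ids, level_value = values, stringsAsFactors = FALSE)
}

# central finite differences of the KL objective w.r.t. one parameter matrix
numeric_grad <- function(f, M, h = 1e-6) {
  G <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      up <- M; up[i, j] <- up[i, j] + h
      dn <- M; dn[i, j] <- dn[i, j] - h
      G[i, j] <- (f(up) - f(dn)) / (2 * h)
    }
  }
  G
}

# tiny diffusion profile for embedding unit tests
tiny_profiles <- function(n = 4, m = 2, seed = 7, ids = sprintf("T%02d", seq_len(n))) {
  set.seed(seed)
  chans <- lapply(seq_len(m), function(j) {
    k <- n - (j - 1L)  # vary coverage across channels
    V <- matrix(stats::rexp(n * k), n, k)
    V <- sweep(V, 2, colSums(V), "/")
    rownames(V) <- ids
    colnames(V) <- ids[seq_len(k)]
    V
  })
  names(chans) <- paste0("channel", seq_len(m))
  structure(list(ids = ids, alpha = 0.5, channels = chans),
            class = "diffusion_profile")
}

table1_path <- function() {
  system.file("extdata", "table1_top15.tsv", package = "netonco")
}

read_table1 <- function() {
  utils::read.table(table1_path(), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

# study-condition embedding settings used across desk-scale pipeline tests
desk_config <- function(d = 16L, seed = 1L) {
  embedding_config(d = d, learning_rate = 10, max_epochs = 1000L,
                   checkpoint_every = 50L, seed = seed)
}
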