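test_that("channel networks are built from strictly positive scores only", {
  col <- parse_string_links(write_lines_tmp(links_fixture_lines()))
  expect_s3_class(col, "network_collection")
  expect_identical(col$ids, c("A", "B", "C"))
  expect_identical(names(col$channels), c("neighborhood", "textmining"))

  nb <- col$channels$neighborhood
  expect_equal(nrow(nb), 1L)
  expect_equal(nb$from, "A")
  expect_equal(nb$to, "C")
  expect_equal(nb$weight, 150)

  tm <- col$channels$textmining
  expect_equal(nrow(tm), 2L)
  expect_setequal(tm$weight, c(800, 700))
  expect_no_error(validate_collection(col))
})

test_that("all-zero scores give empty channels but a full index", {
  lines <- c("protein1 protein2 neighborhood fusion cooccurrence coexpression experimental database textmining",
             "A B 0 0 0 0 0 0 0",
             "C D 0 0 0 0 0 0 0")
  col <- parse_string_links(write_lines_tmp(lines))
  expect_length(col$channels, 7L)
  expect_true(all(vapply(col$channels, nrow, integer(1)) == 0L))
  expect_identical(col$ids, c("A", "B", "C", "D"))
})

test_that("combined_score is dropped and the seven channels remain", {
  lines <- c("protein1 protein2 neighborhood fusion cooccurrence coexpression experimental database textmining combined_score",
             "A B 10 20 30 40 50 60 70 900")
  col <- parse_string_links(write_lines_tmp(lines), drop_combined = TRUE)
  expect_length(col$channels, 7L)
  expect_false("combined_score" %in% names(col$channels))
  col2 <- parse_string_links(write_lines_tmp(lines), drop_combined = FALSE)
  expect_true("combined_score" %in% names(col2$channels))
})

test_that("header aliases, duplicates and malformed input are handled", {
  # 'experiment' alias maps onto 'experimental'
  col <- parse_string_links(write_lines_tmp(
    c("p1 p2 experiment", "A B 42")))
  expect_identical(names(col$channels), "experimental")

  # symmetric duplicates collapse; conflicting duplicates abort
  col <- parse_string_links(write_lines_tmp(
    c("p1 p2 textmining", "A B 700", "B A 700")))
  expect_equal(nrow(col$channels$textmining), 1L)
  expect_error(
    parse_string_links(write_lines_tmp(
      c("p1 p2 textmining", "A B 700", "B A 699"))),
    "conflicting")

  # self-loops dropped with warning, id kept
  expect_warning(
    col <- parse_string_links(write_lines_tmp(
      c("p1 p2 textmining", "A A 500", "A B 700"))),
    "self-loop")
  expect_identical(col$ids, c("A", "B"))
  expect_equal(nrow(col$channels$textmining), 1L)

  expect_error(parse_string_links(write_lines_tmp(
    c("p1 p2 textmining", "A B"))), "line 2")
  expect_error(parse_string_links(write_lines_tmp(
    c("p1 p2 textmining", "A B -5"))), "line 2")
  expect_error(parse_string_links(write_lines_tmp(character(0))), "empty")
})

test_that("label loading partitions the index and reports dropped ids", {
  idx <- c("A", "B", "C", "D")
  lab <- load_labels(write_lines_tmp(c("A", "C")), idx)
  expect_identical(lab$positives, c("A", "C"))
  expect_identical(lab$unlabelled, c("B", "D"))

  expect_message(
    lab <- load_labels(write_lines_tmp(c("A", "Z")), c("A", "B")),
    "dropped 1")
  expect_identical(lab$positives, "A")
  expect_identical(lab$unlabelled, "B")
  expect_identical(attr(lab, "dropped"), "Z")

  expect_error(load_labels(write_lines_tmp("# only a comment"), "A"),
               "no positives")
})

test_that("labels always partition the index", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3:30, 1)
    idx <- sort(sprintf("ID%03d", sample(1:500, n)))
    listed <- sample(idx, sample(seq_len(n), 1))
    lab <- load_labels(write_lines_tmp(listed), idx)
    expect_length(c(lab$positives, lab$unlabelled), n)
    expect_setequal(c(lab$positives, lab$unlabelled), idx)
    expect_length(intersect(lab$positives, lab$unlabelled), 0L)
  }
})

test_that("network stats count undirected edges and connected nodes", {
  col <- parse_string_links(write_lines_tmp(links_fixture_lines()))
  s <- network_stats(col)
  expect_equal(s$edges[s$channel == "neighborhood"], 1L)
  expect_equal(s$edges[s$channel == "textmining"], 2L)
  expect_equal(s$nodes[s$channel == "textmining"], 3L)

  col2 <- make_collection(c("A", "B", "C"), list(
    ch1 = data.frame(from = c("A", "B"), to = c("B", "C"), weight = c(1, 2)),
    ch2 = data.frame(from = character(), to = character(), weight = numeric())))
  s2 <- network_stats(col2)
  expect_equal(s2$edges, c(2L, 0L))
  expect_equal(s2$nodes, c(3L, 0L))
})

test_that("parse -> serialize -> reparse round-trips the collection", {
  set.seed(7)
  for (rep in 1:3) {
    spec <- sim_spec(n = 40L, channels = 3L, blocks = c(10L, 30L),
                     p_in = 0.5, p_out = 0.05, channel_dropout = 0.2,
                     seed = 100 + rep)
    sim <- simulate_collection(spec)
    f <- withr::local_tempfile()
    write_string_links(sim$collection, f)
    back <- suppressWarnings(parse_string_links(f))
    expect_identical(back$ids, sim$collection$ids)
    expect_identical(names(back$channels), names(sim$collection$channels))
    for (ch in names(back$channels)) {
      a <- sim$collection$channels[[ch]]
      b <- back$channels[[ch]]
      ord_a <- order(a$from, a$to); ord_b <- order(b$from, b$to)
      expect_equal(a[ord_a, ], b[ord_b, ], ignore_attr = TRUE)
    }
  }
})

test_that("channel edge counts add up to the positive scores in the input", {
  lines <- c("p1 p2 neighborhood textmining database",
             "A B 1 0 5", "A C 0 3 0", "B C 2 2 2", "C D 0 0 0")
  col <- parse_string_links(write_lines_tmp(lines))
  total_edges <- sum(vapply(col$channels, nrow, integer(1)))
  scores <- matrix(c(1, 0, 5, 0, 3, 0, 2, 2, 2, 0, 0, 0), byrow = TRUE, ncol = 3)
  expect_equal(total_edges, sum(scores > 0))
})
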