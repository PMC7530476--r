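#' Build the column-stochastic transition operator for one channel
#'
#' Edge weights are normalized by weighted degree: entry `(u, v)` of the
#' transition matrix is `w(u, v) / strength(v)`, so each column over
#' connected nodes sums to one. Columns of nodes absent from the channel
#' (weighted degree zero) are all-zero; such nodes receive no diffusion
#' profile in this channel.
#'
#' @param edges Edge data frame (`from`, `to`, `weight`) for one channel,
#'   as stored in a `network_collection`.
#' @param ids Shared protein index (sorted character vector).
#' @param alpha Restart probability in `(0, 1]` carried along for
#'   [rwr_profile()]. Default 0.5.
#' @param channel Optional channel name used in error messages.
#' @return A `transition_model`: list with the sparse `transition` matrix,
#'   `alpha`, `connected` (logical per node) and `ids`.
#' @export
build_transition <- function(edges, ids, alpha = 0.5, channel = NULL) {
  stopifnot(alpha > 0, alpha <= 1)
  n <- length(ids)
  i <- match(edges$from, ids)
  j <- match(edges$to, ids)
  if (anyNA(i) || anyNA(j)) stop("edge endpoints missing from the index")
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = c(edges$weight, edges$weight),
                            dims = c(n, n), dimnames = list(ids, ids))
  strength <- Matrix::colSums(A)
  inv <- ifelse(strength > 0, 1 / strength, 0)
  Tmat <- A %*% Matrix::Diagonal(n, inv)
  dimnames(Tmat) <- list(ids, ids)
  structure(list(channel = channel, transition = Tmat, alpha = alpha,
                 connected = strength > 0, ids = ids),
            class = "transition_model")
}

# Fixed-point RWR iteration for a set of seed columns at once:
#   P <- (1 - alpha) * T %*% P + alpha * E
# starting from P = E, until the max-norm change drops below tol.
rwr_iterate <- function(model, seed_idx, tol, max_iter) {
  n <- length(model$ids)
  k <- length(seed_idx)
  E <- matrix(0, n, k)
  E[cbind(seed_idx, seq_len(k))] <- 1
  P <- E
  a <- model$alpha
  Tmat <- model$transition
  for (iter in seq_len(max_iter)) {
    Pnew <- (1 - a) * as.matrix(Tmat %*% P) + a * E
    delta <- max(abs(Pnew - P))
    P <- Pnew
    if (delta < tol) {
      colnames(P) <- model$ids[seed_idx]
      rownames(P) <- model$ids
      return(P)
    }
  }
  stop(sprintf("RWR did not converge in %d iterations (channel %s, seed %s)",
               max_iter, model$channel %||% "?", model$ids[seed_idx[1L]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random walk with restart from one seed node
#'
#' Iterates `p <- (1 - alpha) * T p + alpha * e_seed` from `p = e_seed`
#' until the max-norm change falls below `tol`. The fixed point solves
#' `p = (1 - alpha) T p + alpha e_seed` and measures the proximity of every
#' node to the seed; it is the raw per-channel feature vector of the seed.
#'
#' @param model A `transition_model`.
#' @param seed_node Protein id with degree >= 1 in the channel.
#' @param tol Max-norm convergence tolerance (default 1e-8).
#' @param max_iter Iteration budget (default 1000).
#' @return Named non-negative numeric vector over all nodes, summing to 1.
#' @export
rwr_profile <- function(model, seed_node, tol = 1e-8, max_iter = 1000L) {
  idx <- match(seed_node, model$ids)
  if (is.na(idx)) stop(sprintf("seed %s not in the index", seed_node))
  if (!model$connected[idx]) {
    stop(sprintf("seed %s has no edges in channel %s",
                 seed_node, model$channel %||% "?"))
  }
  drop(rwr_iterate(model, idx, tol, max_iter))
}

#' Diffusion profiles for every connected node in every channel
#'
#' Runs [rwr_profile()] with each connected node as seed, channel by
#' channel. Nodes with no edges in a channel get no profile there (they are
#' simply uncovered in that channel); nodes may therefore be covered by any
#' subset of channels. Fully deterministic.
#'
#' @param collection A `network_collection`.
#' @param alpha Restart probability (default 0.5).
#' @param tol,max_iter Convergence controls passed to the iteration.
#' @return A `diffusion_profile`: list with `ids`, `alpha` and `channels`,
#'   a named list of `n x k_j` matrices whose columns are seed profiles
#'   (column names are the seed ids).
#' @export
diffuse_all <- function(collection, alpha = 0.5, tol = 1e-8, max_iter = 1000L) {
  validate_collection(collection)
  ids <- collection$ids
  channels <- lapply(names(collection$channels), function(ch) {
    model <- build_transition(collection$channels[[ch]], ids,
                              alpha = alpha, channel = ch)
    seeds <- which(model$connected)
    if (length(seeds) == 0L) {
      return(matrix(0, length(ids), 0, dimnames = list(ids, NULL)))
    }
    rwr_iterate(model, seeds, tol, max_iter)
  })
  names(channels) <- names(collection$channels)
  structure(list(ids = ids, alpha = alpha, channels = channels),
            class = "diffusion_profile")
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cov <- vapply(x$channels, ncol, integer(1L))
  cat(sprintf("diffusion_profile: %d nodes, alpha = %g\n",
              length(x$ids), x$alpha))
  cat(sprintf("  covered seeds per channel: %s\n",
              paste(sprintf("%s=%d", names(cov), cov), collapse = ", ")))
  invisible(x)
}
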