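#' Restrict a perturbation matrix to a variant set
#'
#' @param P A [perturbation_matrix()].
#' @param U A `variant_set`.
#' @return An N x nrow(U) matrix of deltas, rows named by read id.
#' @export
variant_deltas <- function(P, U) {
  N <- dim(P)[1]
  M <- matrix(0, N, nrow(U), dimnames = list(dimnames(P)[[1]], NULL))
  ei <- match(U$edit, edit_names())
  for (v in seq_len(nrow(U))) M[, v] <- P[, U$pos[v], ei[v]]
  M
}

#' Clustering objective
#'
#' `sum_k sum_{(i,e) in U} max( sum_{r in R_k} P[r, i, e], 0 )`: the total
#' log-likelihood gain obtainable by applying each collected variant to the
#' chunk separately within each cluster, counting only clusters that
#' support it.
#'
#' @param P A [perturbation_matrix()] or a pre-extracted delta matrix
#'   ([variant_deltas()]).
#' @param U A `variant_set` (ignored when `P` is already a delta matrix).
#' @param assignment Integer cluster labels (1..K), one per read of `P`,
#'   optionally named by read id.
#' @return The objective value (>= 0).
#' @export
cluster_objective <- function(P, U = NULL, assignment) {
  Pu <- if (length(dim(P)) == 3) variant_deltas(P, U) else P
  if (length(assignment) != nrow(Pu))
    stop("assignment does not cover the reads of the perturbation matrix")
  if (!is.null(names(assignment)) && !is.null(rownames(Pu))) {
    if (!setequal(names(assignment), rownames(Pu)))
      stop("assignment read ids do not match the perturbation matrix")
    assignment <- assignment[rownames(Pu)]
  }
  if (ncol(Pu) == 0) return(0)
  obj <- 0
  for (k in unique(assignment)) {
    s <- colSums(Pu[assignment == k, , drop = FALSE])
    obj <- obj + sum(pmax(s, 0))
  }
  obj
}

#' Clustering configuration
#'
#' @param iterations Number of single-read moves (default `2000 * n`, set
#'   when NULL at run time).
#' @param restarts Independent restarts, keeping the best.
#' @param seed Integer seed.
#' @return A `clustering_config` list.
#' @export
clustering_config <- function(iterations = NULL, restarts = 4L, seed = 1L) {
  structure(list(iterations = iterations, restarts = as.integer(restarts),
                 seed = as.integer(seed)), class = "clustering_config")
}

#' Separate the reads on a chunk into K copy clusters
#'
#' Starts from a uniform-random K-partition and performs single-read moves
#' between random clusters: an improvement of the objective is always
#' accepted, a worsening with probability `exp(delta)`. The best assignment
#' seen across restarts is returned. With no usable variants (or K = 1)
#' all reads form a single cluster.
#'
#' @param P A [perturbation_matrix()] or delta matrix.
#' @param U A `variant_set` (ignored for a delta matrix).
#' @param K Copy number of the chunk.
#' @param config A [clustering_config()].
#' @return A `read_clustering`: list with `assignment` (named integer
#'   vector, clusters 1..K), `K`, `objective`, and `deltas` (the restricted
#'   matrix, for downstream correction).
#' @export
cluster_reads <- function(P, U = NULL, K, config = clustering_config()) {
  Pu <- if (length(dim(P)) == 3) variant_deltas(P, U) else P
  N <- nrow(Pu)
  if (K < 1) stop("K must be >= 1")
  if (K > N) stop("more clusters (K) than reads")
  ids <- rownames(Pu) %||% as.character(seq_len(N))
  if (K == 1 || ncol(Pu) == 0) {
    # no usable variants: the chunk cannot be separated; a single cluster
    # is returned and K reports the effective cluster count
    asg <- setNames(rep(1L, N), ids)
    res <- list(assignment = asg, K = 1L,
                objective = cluster_objective(Pu, assignment = asg), deltas = Pu)
    class(res) <- "read_clustering"
    return(res)
  }
  T <- config$iterations %||% (2000 * N)
  fit <- .ca_cluster_cpp(Pu, as.integer(K), as.numeric(T), config$restarts,
                         config$seed)
  asg <- setNames(fit$assignment + 1L, ids)
  res <- list(assignment = asg, K = K, objective = fit$objective, deltas = Pu)
  class(res) <- "read_clustering"
  res
}

#' @export
print.read_clustering <- function(x, ...) {
  cat(sprintf("read clustering: %d reads in %d clusters (objective %.2f)\n",
              length(x$assignment), length(unique(x$assignment)), x$objective))
  invisible(x)
}

#' Rand index of two partitions
#'
#' The number of element pairs that are co-clustered in both partitions or
#' separated in both, divided by the total number of pairs.
#'
#' @param truth,predicted Cluster labels over the same elements (matched by
#'   names when both are named).
#' @return Rand index in [0, 1].
#' @export
rand_index <- function(truth, predicted) {
  if (!is.null(names(truth)) && !is.null(names(predicted))) {
    if (!setequal(names(truth), names(predicted)))
      stop("partitions cover different element sets")
    predicted <- predicted[names(truth)]
  }
  n <- length(truth)
  if (n < 2 || length(predicted) != n) stop("need >= 2 elements in both partitions")
  tab <- table(truth, predicted)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2)) - a
  c <- sum(choose(colSums(tab), 2)) - a
  total <- choose(n, 2)
  d <- total - a - b - c
  (a + d) / total
}

#' Correct clusterings using nearby chunks
#'
#' Reads co-clustered on a neighboring chunk vote for being co-clustered
#' here: for each read, each neighbor chunk sharing it proposes the cluster
#' (on this chunk) that most of the read's neighbor-side cluster mates
#' occupy. A read is moved to the top-voted cluster when the vote is
#' strictly ahead and the move does not decrease this chunk's objective by
#' more than `slack`. Sweeps run to a fixed point or `max_sweeps`.
#'
#' @param clusterings Named list of `read_clustering` objects (per chunk).
#' @param alignments A `chunk_alignments` data.frame (defines chunk
#'   neighborhoods via shared reads).
#' @param min_shared Minimum shared reads for two chunks to be neighbors.
#' @param slack Largest tolerated objective decrease per move.
#' @param max_sweeps Maximum sweeps.
#' @return The corrected named list of `read_clustering` objects.
#' @export
correct_with_neighbors <- function(clusterings, alignments, min_shared = 4L,
                                   slack = 0, max_sweeps = 10L) {
  chunk_reads <- lapply(clusterings, function(cl) names(cl$assignment))
  ids <- names(clusterings)
  neighbors <- lapply(ids, function(cid) {
    shared <- vapply(ids, function(o)
      length(intersect(chunk_reads[[cid]], chunk_reads[[o]])), integer(1))
    setdiff(ids[shared >= min_shared], cid)
  })
  names(neighbors) <- ids
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (cid in ids) {
      cl <- clusterings[[cid]]
      if (cl$K < 2) next
      for (r in names(cl$assignment)) {
        votes <- numeric(cl$K)
        for (nid in neighbors[[cid]]) {
          ncl <- clusterings[[nid]]
          if (!(r %in% names(ncl$assignment)) || ncl$K < 2) next
          mates <- setdiff(names(ncl$assignment)[ncl$assignment == ncl$assignment[r]], r)
          mates <- intersect(mates, names(cl$assignment))
          if (length(mates) == 0) next
          tl <- tabulate(cl$assignment[mates], nbins = cl$K)
          votes[which.max(tl)] <- votes[which.max(tl)] + 1
        }
        if (all(votes == 0)) next
        top <- which.max(votes)
        cur <- cl$assignment[r]
        if (top == cur || votes[top] <= votes[cur]) next
        trial <- cl$assignment
        trial[r] <- top
        new_obj <- cluster_objective(cl$deltas, assignment = trial)
        if (new_obj >= cl$objective - slack) {
          cl$assignment <- trial
          cl$objective <- new_obj
          changed <- TRUE
        }
      }
      clusterings[[cid]] <- cl
    }
    if (!changed) break
  }
  clusterings
}
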