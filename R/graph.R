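node_name <- function(chunk_id, copy) paste0(chunk_id, "/", copy)

side_key <- function(node, end) paste0(node, ":", end)

edge_key <- function(n1, e1, n2, e2) {
  a <- side_key(n1, e1)
  b <- side_key(n2, e2)
  if (a <= b) paste(a, b, sep = "--") else paste(b, a, sep = "--")
}

#' Build the copy graph
#'
#' Nodes are (chunk, copy) pairs; an edge links two copies adjacent in a
#' read, i.e. assigned to consecutive chunk alignments along it. Chunks are
#' unoriented, so each node has two ends ("L"/"R" in chunk-forward frame)
#' and edges connect ends (a bidirected graph). Edges supported by fewer
#' than `min_edge_support` reads are dropped; self loops need twice that.
#'
#' Each edge also records, per supporting read, the gap between the two
#' alignments on the read (negative = overlap) and, for positive gaps, the
#' read subsequence spanning it -- the material later used to joint chunk
#' copies into a draft.
#'
#' @param clusterings Named list of `read_clustering` per chunk.
#' @param alignments A `chunk_alignments` data.frame.
#' @param min_edge_support Minimum supporting reads per edge.
#' @param reads Optional read sequences (enables gap-fill extraction).
#' @param copy_numbers Optional named copy numbers per chunk (labels
#'   unseparated multi-copy chunks "unresolved").
#' @return A `copy_graph` list: `nodes` data.frame (node_id, chunk_id,
#'   copy_index, label, n_reads), `node_reads`, `edges` data.frame
#'   (edge_id, node1, end1, node2, end2, support), `edge_data`.
#' @export
build_graph <- function(clusterings, alignments, min_edge_support = 2L,
                        reads = NULL, copy_numbers = NULL) {
  rseq <- if (!is.null(reads)) read_seqs(reads) else NULL
  node_reads <- new.env(parent = emptyenv())
  edges <- new.env(parent = emptyenv())
  aln_of <- new.env(parent = emptyenv())  # node|read -> alignment row
  by_read <- split(alignments, alignments$read_id)
  for (rid in names(by_read)) {
    al <- by_read[[rid]]
    al <- al[order(al$read_start), , drop = FALSE]
    nodes_seq <- character(0)
    rows_seq <- integer(0)
    for (i in seq_len(nrow(al))) {
      cid <- al$chunk_id[i]
      cl <- clusterings[[cid]]
      if (is.null(cl) || !(rid %in% names(cl$assignment))) next
      nd <- node_name(cid, cl$assignment[[rid]])
      nodes_seq <- c(nodes_seq, nd)
      rows_seq <- c(rows_seq, i)
    }
    for (t in seq_along(nodes_seq)) {
      nd <- nodes_seq[t]
      node_reads[[nd]] <- c(node_reads[[nd]], rid)
      k <- paste0(nd, "|", rid)
      if (is.null(aln_of[[k]])) aln_of[[k]] <- al[rows_seq[t], ]
    }
    if (length(nodes_seq) < 2) next
    for (t in seq_len(length(nodes_seq) - 1)) {
      i <- rows_seq[t]; j <- rows_seq[t + 1]
      u <- nodes_seq[t]; v <- nodes_seq[t + 1]
      end_u <- if (al$strand[i] == "+") "R" else "L"
      end_v <- if (al$strand[j] == "+") "L" else "R"
      ek <- edge_key(u, end_u, v, end_v)
      fwd_first <- side_key(u, end_u) <= side_key(v, end_v)
      gap <- al$read_start[j] - al$read_end[i]
      fill <- NA_character_
      if (gap > 0 && !is.null(rseq)) {
        fill <- substr(rseq[[rid]], al$read_end[i] + 1L, al$read_start[j])
        if (!fwd_first) fill <- revcomp(fill)
      }
      e <- edges[[ek]]
      if (is.null(e)) {
        e <- list(node1 = if (fwd_first) u else v,
                  end1 = if (fwd_first) end_u else end_v,
                  node2 = if (fwd_first) v else u,
                  end2 = if (fwd_first) end_v else end_u,
                  reads = character(0), gaps = integer(0), fills = character(0))
      }
      e$reads <- c(e$reads, rid)
      e$gaps <- c(e$gaps, gap)
      e$fills <- c(e$fills, fill)
      edges[[ek]] <- e
    }
  }
  nd_ids <- ls(node_reads)
  nodes <- data.frame(node_id = nd_ids,
                      chunk_id = sub("/[0-9]+$", "", nd_ids),
                      copy_index = as.integer(sub("^.*/", "", nd_ids)),
                      stringsAsFactors = FALSE)
  nodes$n_reads <- vapply(nd_ids, function(n) length(unique(node_reads[[n]])), integer(1))
  nodes$label <- vapply(seq_len(nrow(nodes)), function(i) {
    cid <- nodes$chunk_id[i]
    K <- clusterings[[cid]]$K
    cn <- if (!is.null(copy_numbers) && cid %in% names(copy_numbers))
      copy_numbers[[cid]] else K
    if (cn >= 2 && K == 1) "unresolved" else "haplotype_phased"
  }, character(1))
  ekeys <- ls(edges)
  keep_edges <- list()
  edge_data <- list()
  for (ek in ekeys) {
    e <- edges[[ek]]
    sup <- length(unique(e$reads))
    need <- if (e$node1 == e$node2) 2L * min_edge_support else min_edge_support
    if (sup < need) next
    keep_edges[[length(keep_edges) + 1L]] <-
      data.frame(edge_id = ek, node1 = e$node1, end1 = e$end1, node2 = e$node2,
                 end2 = e$end2, support = sup, stringsAsFactors = FALSE)
    edge_data[[ek]] <- e
  }
  edf <- if (length(keep_edges)) do.call(rbind, keep_edges) else
    data.frame(edge_id = character(0), node1 = character(0), end1 = character(0),
               node2 = character(0), end2 = character(0), support = integer(0),
               stringsAsFactors = FALSE)
  rownames(edf) <- NULL
  g <- list(nodes = nodes, node_reads = as.list(node_reads), edges = edf,
            edge_data = edge_data, min_edge_support = min_edge_support,
            aln_of = as.list(aln_of))
  class(g) <- "copy_graph"
  g
}

#' @export
print.copy_graph <- function(x, ...) {
  cat(sprintf("copy graph: %d nodes (%s), %d edges\n", nrow(x$nodes),
              paste(names(table(x$nodes$label)), table(x$nodes$label),
                    sep = "=", collapse = ", "), nrow(x$edges)))
  invisible(x)
}

graph_sides <- function(graph) {
  e <- graph$edges
  c(side_key(e$node1, e$end1), side_key(e$node2, e$end2))
}

side_edges <- function(graph, node, end) {
  e <- graph$edges
  which((e$node1 == node & e$end1 == end) | (e$node2 == node & e$end2 == end))
}

other_side <- function(edge_row, node, end) {
  # the far (node, end) of an edge as seen from (node, end)
  if (edge_row$node1 == node && edge_row$end1 == end) {
    c(edge_row$node2, edge_row$end2)
  } else {
    c(edge_row$node1, edge_row$end1)
  }
}

drop_nodes <- function(graph, nodes) {
  keep <- !(graph$nodes$node_id %in% nodes)
  graph$nodes <- graph$nodes[keep, , drop = FALSE]
  ekeep <- !(graph$edges$node1 %in% nodes | graph$edges$node2 %in% nodes)
  graph$edge_data <- graph$edge_data[graph$edges$edge_id[ekeep]]
  graph$edges <- graph$edges[ekeep, , drop = FALSE]
  graph$node_reads <- graph$node_reads[setdiff(names(graph$node_reads), nodes)]
  graph
}

#' Prune transitive edges, weak tips and parallel edges
#'
#' First removes transitive edges: an edge fully explained by a two-edge
#' path whose edges each carry at least `trans_ratio` times its support
#' (reads occasionally miss the middle chunk of three consecutive ones,
#' creating a skip edge). Then removes dangling chains of at most
#' `tip_max_nodes` nodes whose attachment is dominated by an alternative
#' continuation at `ratio`-to-one support.
#'
#' @param graph A `copy_graph`.
#' @param tip_max_nodes Maximum tip chain length removed.
#' @param ratio Required support ratio for tip pruning.
#' @param trans_ratio Required support ratio for transitive reduction.
#' @return The simplified `copy_graph`.
#' @export
simplify_graph <- function(graph, tip_max_nodes = 2L, ratio = 5,
                           trans_ratio = 3) {
  graph <- reduce_transitive(graph, trans_ratio)
  graph <- disambiguate_copy_pairs(graph)
  graph <- prune_dominated(graph, ratio)
  repeat {
    removed <- FALSE
    # parallel edges between the same pair of sides cannot exist (keyed),
    # but two edges may join the same two sides via opposite ends; treat
    # edges sharing BOTH sides as parallel
    # tips
    for (nid in graph$nodes$node_id) {
      degL <- length(side_edges(graph, nid, "L"))
      degR <- length(side_edges(graph, nid, "R"))
      if (xor(degL == 0, degR == 0)) {
        # chain starting at dead side
        chain <- nid
        cur <- nid
        cur_in <- if (degL == 0) "R" else "L"  # side attaching inward
        ok <- TRUE
        repeat {
          es <- side_edges(graph, cur, cur_in)
          if (length(es) != 1) break
          far <- other_side(graph$edges[es, ], cur, cur_in)
          sup_chain <- graph$edges$support[es]
          far_es <- side_edges(graph, far[1], far[2])
          if (length(far_es) > 1) {
            alt <- max(graph$edges$support[setdiff(far_es, es)])
            if (length(chain) <= tip_max_nodes && alt >= ratio * sup_chain) {
              graph <- drop_nodes(graph, chain)
              removed <- TRUE
            }
            break
          }
          if (far[1] %in% chain) break
          chain <- c(chain, far[1])
          if (length(chain) > tip_max_nodes + 1L) break
          cur <- far[1]
          cur_in <- if (far[2] == "L") "R" else "L"
        }
        if (removed) break
      }
    }
    if (!removed) break
  }
  graph
}

# When two copies of chunk X and two copies of chunk Y are joined by three
# or four edges (read misassignment blurs the true one-to-one adjacency),
# keep the copy pairing with the larger read co-occurrence and drop the
# crossing edges.
disambiguate_copy_pairs <- function(graph, margin = 2L) {
  if (nrow(graph$edges) == 0) return(graph)
  e <- graph$edges
  cx <- sub("/.*", "", e$node1)
  cy <- sub("/.*", "", e$node2)
  pair_key <- ifelse(cx <= cy, paste(cx, cy), paste(cy, cx))
  for (pk in unique(pair_key[cx != cy])) {
    idx <- which(pair_key == pk & cx != cy)
    if (length(idx) < 3) next
    ends <- c(e$node1[idx], e$node2[idx])
    echunk <- sub("/.*", "", ends)
    us <- unique(ends[echunk == sub(" .*", "", pk)])
    vs <- unique(ends[echunk == sub(".* ", "", pk)])
    if (length(us) != 2 || length(vs) != 2) next
    co <- function(a, b)
      length(intersect(graph$node_reads[[a]], graph$node_reads[[b]]))
    straight <- co(us[1], vs[1]) + co(us[2], vs[2])
    cross <- co(us[1], vs[2]) + co(us[2], vs[1])
    if (abs(straight - cross) < margin) next
    bad <- if (straight > cross) {
      idx[(e$node1[idx] == us[1] & e$node2[idx] == vs[2]) |
          (e$node1[idx] == vs[2] & e$node2[idx] == us[1]) |
          (e$node1[idx] == us[2] & e$node2[idx] == vs[1]) |
          (e$node1[idx] == vs[1] & e$node2[idx] == us[2])]
    } else {
      idx[(e$node1[idx] == us[1] & e$node2[idx] == vs[1]) |
          (e$node1[idx] == vs[1] & e$node2[idx] == us[1]) |
          (e$node1[idx] == us[2] & e$node2[idx] == vs[2]) |
          (e$node1[idx] == vs[2] & e$node2[idx] == us[2])]
    }
    if (length(bad)) {
      graph$edge_data[graph$edges$edge_id[bad]] <- NULL
      graph$edges <- graph$edges[-bad, , drop = FALSE]
      return(disambiguate_copy_pairs(graph, margin))
    }
  }
  graph
}

# drop edges dominated ratio-to-one by a parallel edge on BOTH of their
# sides (spurious connections from occasional read misassignment)
prune_dominated <- function(graph, ratio = 5) {
  repeat {
    if (nrow(graph$edges) == 0) break
    drop <- NULL
    for (i in order(graph$edges$support)) {
      e <- graph$edges[i, ]
      dom1 <- side_edges(graph, e$node1, e$end1)
      dom2 <- side_edges(graph, e$node2, e$end2)
      d1 <- length(dom1) > 1 && max(graph$edges$support[setdiff(dom1, i)]) >= ratio * e$support
      d2 <- length(dom2) > 1 && max(graph$edges$support[setdiff(dom2, i)]) >= ratio * e$support
      if (d1 && d2) {
        drop <- i
        break
      }
    }
    if (is.null(drop)) break
    ek <- graph$edges$edge_id[drop]
    graph$edges <- graph$edges[-drop, , drop = FALSE]
    graph$edge_data[[ek]] <- NULL
  }
  graph
}

reduce_transitive <- function(graph, trans_ratio = 3) {
  repeat {
    if (nrow(graph$edges) == 0) break
    ord <- order(graph$edges$support)
    dropped <- NULL
    for (i in ord) {
      e <- graph$edges[i, ]
      if (e$node1 == e$node2) next
      # two-edge path: (node1,end1) -> (m, em) then (m, flip(em)) -> (node2,end2)
      found <- FALSE
      for (f in side_edges(graph, e$node1, e$end1)) {
        if (f == i) next
        mid <- other_side(graph$edges[f, ], e$node1, e$end1)
        if (mid[1] == e$node2) next
        for (g in side_edges(graph, mid[1], flip_end(mid[2]))) {
          far <- other_side(graph$edges[g, ], mid[1], flip_end(mid[2]))
          if (far[1] == e$node2 && far[2] == e$end2 &&
              graph$edges$support[f] >= trans_ratio * e$support &&
              graph$edges$support[g] >= trans_ratio * e$support) {
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (found) {
        dropped <- i
        break
      }
    }
    if (is.null(dropped)) break
    ek <- graph$edges$edge_id[dropped]
    graph$edges <- graph$edges[-dropped, , drop = FALSE]
    graph$edge_data[[ek]] <- NULL
  }
  graph
}

#' Resolve homozygous runs by read co-occurrence
#'
#' A homozygous run is a chain of unresolved nodes where two phased paths
#' merge and re-split. When reads spanning the run support one in/out
#' pairing at a ratio of at least `resolve_ratio` over the crossing
#' pairing, the run is duplicated into two copies and the phases connected
#' straight through; otherwise it is left unresolved.
#'
#' @param graph A `copy_graph`.
#' @param resolve_ratio Required straight-to-crossing co-occurrence ratio.
#' @param min_span Minimum winning co-occurrence count.
#' @return The resolved `copy_graph`.
#' @export
resolve_homozygous <- function(graph, resolve_ratio = 3, min_span = 2L) {
  repeat {
    done <- TRUE
    runs <- find_unresolved_runs(graph)
    for (run in runs) {
      ins <- run$ins
      outs <- run$outs
      if (length(ins) != 2 || length(outs) != 2) next
      rs <- function(n) unique(graph$node_reads[[n]])
      c11 <- length(intersect(rs(ins[1]), rs(outs[1])))
      c22 <- length(intersect(rs(ins[2]), rs(outs[2])))
      c12 <- length(intersect(rs(ins[1]), rs(outs[2])))
      c21 <- length(intersect(rs(ins[2]), rs(outs[1])))
      straight <- c11 + c22
      crossing <- c12 + c21
      hi <- max(straight, crossing)
      lo <- min(straight, crossing)
      if (hi < min_span || hi < resolve_ratio * max(lo, 1)) next
      pairing <- if (straight >= crossing) list(c(1, 1), c(2, 2)) else
        list(c(1, 2), c(2, 1))
      graph <- duplicate_run(graph, run, pairing)
      done <- FALSE
      break
    }
    if (done) break
  }
  graph
}

find_unresolved_runs <- function(graph) {
  # candidates: nodes that are the sole copy of their chunk -- explicitly
  # unresolved multi-copy chunks, but also chunks whose copy number was
  # underestimated; a genuinely single-copy node has one edge per side and
  # never matches the two-in/two-out motif below
  tab <- table(graph$nodes$chunk_id)
  unres <- graph$nodes$node_id[tab[graph$nodes$chunk_id] == 1]
  seen <- character(0)
  runs <- list()
  for (nid in unres) {
    if (nid %in% seen) next
    # grow a chain of unresolved nodes through simple connections
    chain <- nid
    ends <- list()
    for (dir in c("L", "R")) {
      cur <- nid
      cur_out <- dir
      repeat {
        es <- side_edges(graph, cur, cur_out)
        if (length(es) != 1) break
        far <- other_side(graph$edges[es, ], cur, cur_out)
        if (!(far[1] %in% unres) || far[1] %in% chain) break
        if (length(side_edges(graph, far[1], far[2])) != 1) break
        if (dir == "L") chain <- c(far[1], chain) else chain <- c(chain, far[1])
        cur <- far[1]
        cur_out <- if (far[2] == "L") "R" else "L"
      }
      ends[[dir]] <- c(cur, cur_out)
    }
    seen <- c(seen, chain)
    # neighbors at the outer sides
    outer <- function(endpt) {
      es <- side_edges(graph, endpt[1], endpt[2])
      nb <- character(0)
      for (ei in es) {
        far <- other_side(graph$edges[ei, ], endpt[1], endpt[2])
        if (!(far[1] %in% chain)) nb <- c(nb, far[1])
      }
      unique(nb)
    }
    ins <- outer(ends$L)
    outs <- outer(ends$R)
    lab <- function(v) graph$nodes$label[match(v, graph$nodes$node_id)]
    if (length(ins) == 2 && length(outs) == 2 &&
        all(lab(c(ins, outs)) == "haplotype_phased")) {
      runs[[length(runs) + 1L]] <- list(chain = chain, left = ends$L,
                                        right = ends$R, ins = ins, outs = outs)
    }
  }
  runs
}

duplicate_run <- function(graph, run, pairing) {
  chain <- run$chain
  # reads anchored to each phase
  anchor <- lapply(pairing, function(p)
    unique(c(graph$node_reads[[run$ins[p[1]]]], graph$node_reads[[run$outs[p[2]]]])))
  new_ids <- list()
  for (ph in 1:2) {
    ids <- paste0(chain, letters[ph])
    new_ids[[ph]] <- ids
    for (t in seq_along(chain)) {
      old <- chain[t]
      oi <- match(old, graph$nodes$node_id)
      mem <- graph$node_reads[[old]]
      mine <- intersect(mem, anchor[[ph]])
      other <- intersect(mem, anchor[[3 - ph]])
      keep <- union(mine, setdiff(mem, other))  # ambiguous reads go to both
      graph$nodes <- rbind(graph$nodes,
                           data.frame(node_id = ids[t],
                                      chunk_id = graph$nodes$chunk_id[oi],
                                      copy_index = ph,
                                      n_reads = length(keep),
                                      label = "haplotype_phased",
                                      stringsAsFactors = FALSE))
      graph$node_reads[[ids[t]]] <- keep
      for (rid in keep) {
        graph$aln_of[[paste0(ids[t], "|", rid)]] <- graph$aln_of[[paste0(old, "|", rid)]]
      }
    }
  }
  # rewire edges
  add_edge <- function(n1, e1, n2, e2, data) {
    ek <- edge_key(n1, e1, n2, e2)
    fwd <- side_key(n1, e1) <= side_key(n2, e2)
    nd <- data
    nd$node1 <- if (fwd) n1 else n2
    nd$end1 <- if (fwd) e1 else e2
    nd$node2 <- if (fwd) n2 else n1
    nd$end2 <- if (fwd) e2 else e1
    if (!fwd && length(nd$fills)) nd$fills <- ifelse(is.na(nd$fills), nd$fills,
                                                     revcomp_safe(nd$fills))
    graph$edges <<- rbind(graph$edges,
                          data.frame(edge_id = ek, node1 = nd$node1, end1 = nd$end1,
                                     node2 = nd$node2, end2 = nd$end2,
                                     support = length(unique(nd$reads)),
                                     stringsAsFactors = FALSE))
    graph$edge_data[[ek]] <<- nd
  }
  edge_between <- function(a, aend, b, bend) {
    ek <- edge_key(a, aend, b, bend)
    graph$edge_data[[ek]]
  }
  flip <- function(e) if (e == "L") "R" else "L"
  # internal orientation of the chain: sides along the walk
  chain_sides <- chain_side_walk(graph, run)
  for (ph in 1:2) {
    ids <- new_ids[[ph]]
    in_node <- run$ins[pairing[[ph]][1]]
    out_node <- run$outs[pairing[[ph]][2]]
    # boundary edge left: from in_node to chain[1]
    eL <- NULL
    for (ei in side_edges(graph, run$left[1], run$left[2])) {
      far <- other_side(graph$edges[ei, ], run$left[1], run$left[2])
      if (far[1] == in_node) eL <- graph$edges[ei, ]
    }
    if (!is.null(eL)) {
      dat <- graph$edge_data[[eL$edge_id]]
      far <- other_side(eL, run$left[1], run$left[2])
      add_edge(far[1], far[2], ids[match(run$left[1], chain)], run$left[2], dat)
    }
    eR <- NULL
    for (ei in side_edges(graph, run$right[1], run$right[2])) {
      far <- other_side(graph$edges[ei, ], run$right[1], run$right[2])
      if (far[1] == out_node) eR <- graph$edges[ei, ]
    }
    if (!is.null(eR)) {
      dat <- graph$edge_data[[eR$edge_id]]
      far <- other_side(eR, run$right[1], run$right[2])
      add_edge(far[1], far[2], ids[match(run$right[1], chain)], run$right[2], dat)
    }
    # internal edges
    if (length(chain) > 1) {
      for (t in seq_len(length(chain) - 1)) {
        s <- chain_sides[[t]]
        dat <- edge_between(s$n1, s$e1, s$n2, s$e2)
        add_edge(ids[match(s$n1, chain)], s$e1, ids[match(s$n2, chain)], s$e2, dat)
      }
    }
  }
  drop_nodes(graph, chain)
}

revcomp_safe <- function(x) {
  ok <- !is.na(x) & nchar(x) > 0
  x[ok] <- revcomp(x[ok])
  x
}

chain_side_walk <- function(graph, run) {
  # internal edge side pairs along the chain from left to right
  out <- list()
  cur <- run$left[1]
  cur_out <- flip_end(run$left[2])
  for (t in seq_len(length(run$chain) - 1)) {
    es <- side_edges(graph, cur, cur_out)
    stopifnot(length(es) == 1)
    far <- other_side(graph$edges[es, ], cur, cur_out)
    out[[t]] <- list(n1 = cur, e1 = cur_out, n2 = far[1], e2 = far[2])
    cur <- far[1]
    cur_out <- flip_end(far[2])
  }
  out
}

flip_end <- function(e) if (e == "L") "R" else "L"

#' Extract haplotype paths from the copy graph
#'
#' Nodes with a branching end (two or more incident edges on one side)
#' are emitted as separate single-node multicopy paths. The remaining
#' nodes form maximal simple paths, emitted with per-node orientations.
#'
#' @param graph A `copy_graph`.
#' @return List of `haplotype_path` objects: data.frame (node_id,
#'   orientation) with a `label` attribute ("haplotype_phased" or
#'   "multicopy").
#' @export
extract_paths <- function(graph) {
  if (nrow(graph$nodes) == 0) return(list())
  branching <- vapply(graph$nodes$node_id, function(n)
    length(side_edges(graph, n, "L")) > 1 || length(side_edges(graph, n, "R")) > 1,
    logical(1))
  names(branching) <- graph$nodes$node_id
  paths <- list()
  for (nid in graph$nodes$node_id[branching]) {
    p <- data.frame(node_id = nid, orientation = "+", stringsAsFactors = FALSE)
    attr(p, "label") <- "multicopy"
    class(p) <- c("haplotype_path", "data.frame")
    paths[[length(paths) + 1L]] <- p
  }
  linear <- graph$nodes$node_id[!branching]
  visited <- character(0)
  can_step <- function(node, end) {
    es <- side_edges(graph, node, end)
    if (length(es) != 1) return(NULL)
    far <- other_side(graph$edges[es, ], node, end)
    b <- branching[far[1]]
    if (is.na(b) || b) return(NULL)
    if (length(side_edges(graph, far[1], far[2])) != 1) return(NULL)
    far
  }
  for (nid in linear) {
    if (nid %in% visited) next
    # walk left to a terminus
    cur <- nid
    cur_back <- "L"
    guard <- character(0)
    repeat {
      far <- can_step(cur, cur_back)
      if (is.null(far) || far[1] %in% guard || far[1] == nid) break
      guard <- c(guard, cur)
      cur <- far[1]
      cur_back <- flip_end(far[2])
    }
    # now walk right collecting the path; entering side of start = cur_back flipped
    start <- cur
    enter <- cur_back  # dead/branch side
    nodes_p <- character(0)
    orient_p <- character(0)
    cur <- start
    repeat {
      nodes_p <- c(nodes_p, cur)
      orient_p <- c(orient_p, if (enter == "L") "+" else "-")
      visited <- c(visited, cur)
      exit <- flip_end(enter)
      far <- can_step(cur, exit)
      if (is.null(far) || far[1] %in% nodes_p) break
      cur <- far[1]
      enter <- far[2]
    }
    p <- data.frame(node_id = nodes_p, orientation = orient_p,
                    stringsAsFactors = FALSE)
    attr(p, "label") <- "haplotype_phased"
    class(p) <- c("haplotype_path", "data.frame")
    paths[[length(paths) + 1L]] <- p
  }
  paths
}
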