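# Build a synthetic linear diploid scenario directly at the alignment /
# clustering level: `layout` gives the chunk order along the genome; each
# "read" covers a window of consecutive chunks on one haplotype.
make_graph_fixture <- function(n_chunks, reads_per_hap = 8, span = 3,
                               unresolved = integer(0), seed = 1) {
  set.seed(seed)
  chunks <- sprintf("C%02d", seq_len(n_chunks))
  rows <- list()
  clusterings <- list()
  read_hap <- character(0)
  rid <- 0
  mk_reads <- function(hap) {
    out <- list()
    for (s in seq_len(reads_per_hap)) {
      start <- ((s - 1) %% max(n_chunks - span + 1, 1)) + 1
      rid <<- rid + 1
      id <- sprintf("r%03d_%s", rid, hap)
      read_hap[id] <<- hap
      for (t in seq_len(span)) {
        ci <- start + t - 1
        if (ci > n_chunks) next
        out[[length(out) + 1]] <- data.frame(
          chunk_id = chunks[ci], read_id = id,
          read_start = (t - 1) * 2000, read_end = t * 2000, strand = "+",
          edit_distance = 0, identity = 1, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }
  aligns <- rbind(mk_reads("A"), mk_reads("B"))
  for (ci in seq_len(n_chunks)) {
    on_chunk <- unique(aligns$read_id[aligns$chunk_id == chunks[ci]])
    if (ci %in% unresolved) {
      asg <- setNames(rep(1L, length(on_chunk)), on_chunk)
      K <- 1L
    } else {
      asg <- setNames(ifelse(read_hap[on_chunk] == "A", 1L, 2L), on_chunk)
      K <- 2L
    }
    cl <- list(assignment = asg, K = K, objective = 0,
               deltas = matrix(0, length(on_chunk), 0,
                               dimnames = list(on_chunk, NULL)),
               chunk_id = chunks[ci])
    class(cl) <- "read_clustering"
    clusterings[[chunks[ci]]] <- cl
  }
  cn <- setNames(rep(2L, n_chunks), chunks)
  list(clusterings = clusterings, aligns = aligns, cn = cn, chunks = chunks)
}

test_that("single-copy chunks covered in order form a simple path", {
  fx <- make_graph_fixture(3, unresolved = 1:3)
  g <- build_graph(fx$clusterings, fx$aligns, min_edge_support = 2,
                   copy_numbers = setNames(rep(1L, 3), fx$chunks))
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 2)
  paths <- extract_paths(g)
  expect_equal(length(paths), 1)
  expect_equal(nrow(paths[[1]]), 3)
  expect_equal(attr(paths[[1]], "label"), "haplotype_phased")
})

test_that("edge support is witnessed by distinct reads", {
  fx <- make_graph_fixture(4)
  g <- build_graph(fx$clusterings, fx$aligns, min_edge_support = 2)
  for (ek in g$edges$edge_id) {
    ed <- g$edge_data[[ek]]
    expect_gte(length(unique(ed$reads)), 2)
    expect_equal(length(unique(ed$reads)),
                 g$edges$support[g$edges$edge_id == ek])
  }
})

test_that("an unseparated chunk between phased chunks forms the bubble motif", {
  fx <- make_graph_fixture(3, unresolved = 2)
  g <- build_graph(fx$clusterings, fx$aligns, min_edge_support = 2,
                   copy_numbers = fx$cn)
  # nodes: 2 copies of C01, 1 of C02 (unresolved), 2 of C03
  expect_equal(nrow(g$nodes), 5)
  expect_equal(sum(g$nodes$label == "unresolved"), 1)
  mid <- g$nodes$node_id[g$nodes$label == "unresolved"]
  expect_equal(length(chunkasm:::side_edges(g, mid, "L")), 2)
  expect_equal(length(chunkasm:::side_edges(g, mid, "R")), 2)
})

test_that("an infinite support threshold leaves the graph edgeless", {
  fx <- make_graph_fixture(3)
  g <- build_graph(fx$clusterings, fx$aligns, min_edge_support = 10000L)
  expect_equal(nrow(g$edges), 0)
  expect_equal(extract_paths(g) |> length(), nrow(g$nodes))
})

test_that("homozygous runs are resolved by read co-occurrence", {
  fx <- make_graph_fixture(5, reads_per_hap = 10, span = 4, unresolved = 3)
  g <- build_graph(fx$clusterings, fx$aligns, min_edge_support = 2,
                   copy_numbers = fx$cn)
  expect_equal(length(extract_paths(g)), 5)  # bubble breaks the line
  g2 <- resolve_homozygous(g, resolve_ratio = 3)
  expect_equal(sum(g2$nodes$label == "unresolved"), 0)
  paths <- extract_paths(g2)
  expect_equal(length(paths), 2)
  expect_true(all(vapply(paths, nrow, integer(1)) == 5))
  # consecutive path nodes are joined by existing edges
  for (p in paths) {
    for (t in seq_len(nrow(p) - 1)) {
      exit <- if (p$orientation[t] == "+") "R" else "L"
      enter <- if (p$orientation[t + 1] == "+") "L" else "R"
      ek <- chunkasm:::edge_key(p$node_id[t], exit, p$node_id[t + 1], enter)
      expect_true(ek %in% g2$edges$edge_id)
    }
  }
})

test_that("a homozygous run with no spanning evidence stays unresolved", {
  # reads span only 2 chunks: nobody crosses the middle chunk to both sides
  fx <- make_graph_fixture(5, reads_per_hap = 10, span = 2, unresolved = 3)
  g <- build_graph(fx$clusterings, fx$aligns, min_edge_support = 2,
                   copy_numbers = fx$cn)
  g2 <- resolve_homozygous(g, resolve_ratio = 3)
  expect_equal(sum(g2$nodes$label == "unresolved"), 1)
  expect_gt(length(extract_paths(g2)), 2)
})

test_that("an empty graph yields no paths", {
  g <- build_graph(list(), data.frame(chunk_id = character(0),
                                      read_id = character(0),
                                      read_start = integer(0),
                                      read_end = integer(0),
                                      strand = character(0),
                                      edit_distance = integer(0),
                                      identity = numeric(0)),
                   min_edge_support = 2)
  expect_equal(length(extract_paths(g)), 0)
})
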