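test_that("polishing a perfect draft applies zero edits", {
  truthseq <- rseq(1000, 51)
  segs <- setNames(rep(truthseq, 10), paste0("r", 1:10))
  res <- polish_sequence(truthseq, segs, band = 60)
  expect_equal(res$n_edits, 0)
  expect_true(res$converged)
  expect_identical(res$sequence, truthseq)
})

test_that("polishing recovers the truth from a one-deletion draft", {
  recovered <- 0
  for (s in 1:10) {
    truthseq <- rseq(1000, 60 + s)
    reads <- copy_reads(truthseq, 20, 0.10, seed = 80 + s)
    segs <- oriented_segs(reads)
    draft <- apply_edit(truthseq, 500, "del")
    res <- polish_sequence(draft, segs, band = 80)
    if (res$sequence == truthseq) recovered <- recovered + 1
  }
  expect_gte(recovered, 9)
})

test_that("total read log-likelihood never decreases across polishing rounds", {
  truthseq <- rseq(800, 71)
  reads <- copy_reads(truthseq, 15, 0.10, seed = 72)
  segs <- oriented_segs(reads)
  draft <- mutate_seq(truthseq, 40, 73)  # 5% corrupted draft
  res <- polish_sequence(draft, segs, band = 80)
  expect_true(all(diff(res$loglik_trace) > -1e-6))
  expect_gt(res$loglik_trace[length(res$loglik_trace)], res$loglik_trace[1])
})

test_that("polishing a polished sequence is a fixed point", {
  truthseq <- rseq(800, 74)
  reads <- copy_reads(truthseq, 15, 0.08, seed = 75)
  segs <- oriented_segs(reads)
  once <- polish_sequence(mutate_seq(truthseq, 30, 76), segs, band = 80)
  again <- polish_sequence(once$sequence, segs, band = 80)
  expect_equal(again$n_edits, 0)
  expect_identical(again$sequence, once$sequence)
})

# zero-error fixture: a genome, two chunk copies with known layout, reads
# covering both; used for draft-joint arithmetic
draft_fixture <- function(gap, seed = 90) {
  g <- rseq(9000, seed)
  c1 <- substr(g, 2001, 4000)
  c2_start <- 4001 + gap
  c2 <- substr(g, c2_start, c2_start + 1999)
  n <- 8
  reads <- setNames(vapply(seq_len(n), function(i)
    substr(g, 1 + (i - 1) * 100, 7500 + (i - 1) * 100), character(1)),
    paste0("r", 1:n))
  aligns <- do.call(rbind, lapply(seq_len(n), function(i) {
    off <- (i - 1) * 100
    data.frame(chunk_id = c("X", "Y"), read_id = paste0("r", i),
               read_start = c(2000, c2_start - 1) - off,
               read_end = c(4000, c2_start + 1999) - off,
               strand = "+", edit_distance = 0, identity = 1,
               stringsAsFactors = FALSE)
  }))
  asg <- setNames(rep(1L, n), paste0("r", 1:n))
  mkcl <- function(cid) {
    cl <- list(assignment = asg, K = 1L, objective = 0,
               deltas = matrix(0, n, 0, dimnames = list(names(asg), NULL)),
               chunk_id = cid)
    class(cl) <- "read_clustering"
    cl
  }
  graph <- build_graph(list(X = mkcl("X"), Y = mkcl("Y")), aligns,
                       min_edge_support = 2, reads = reads)
  path <- extract_paths(graph)[[1]]
  list(graph = graph, path = path, reads = reads,
       node_seqs = setNames(list(c1, c2), paste0(c("X", "Y"), "/1")),
       truth = substr(g, 2001, c2_start + 1999))
}

test_that("drafting joins chunks across a positive gap with read sequence", {
  fx <- draft_fixture(gap = 100)
  d <- make_draft(fx$path, fx$graph, fx$node_seqs, reads = fx$reads)
  expect_equal(nchar(d$sequence), 2000 + 100 + 2000)
  expect_identical(d$sequence, fx$truth)
})

test_that("drafting trims overlapping chunks to emit the overlap once", {
  fx <- draft_fixture(gap = -500)
  d <- make_draft(fx$path, fx$graph, fx$node_seqs, reads = fx$reads)
  expect_identical(d$sequence, fx$truth)
  expect_equal(nchar(d$sequence), 3500)
})

test_that("a single-node path drafts the node sequence itself", {
  fx <- draft_fixture(gap = 100)
  p1 <- fx$path[1, , drop = FALSE]
  attr(p1, "label") <- "haplotype_phased"
  class(p1) <- class(fx$path)
  d <- make_draft(p1, fx$graph, fx$node_seqs, reads = fx$reads)
  expect_identical(d$sequence, fx$node_seqs[["X/1"]])
})

test_that("windowed polishing corrects a corrupted region of a draft", {
  set.seed(95)
  fx <- draft_fixture(gap = 100, seed = 96)
  d <- make_draft(fx$path, fx$graph, fx$node_seqs, reads = fx$reads)
  # corrupt the middle of the draft and also feed noisy reads
  bad <- d
  mid <- mutate_seq(substr(d$sequence, 1800, 2400), 40)
  bad$sequence <- paste0(substr(d$sequence, 1, 1799), mid,
                         substr(d$sequence, 2401, nchar(d$sequence)))
  ctg <- polish(bad, fx$reads, window = 2000, stride = 1000, band = 80)
  expect_identical(ctg$sequence, fx$truth)
  expect_true(ctg$converged)
})
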