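make_test_reads <- function(genome, n, len, seed) {
  set.seed(seed)
  starts <- sample.int(nchar(genome) - len + 1, n, replace = TRUE)
  setNames(vapply(starts, function(s) substr(genome, s, s + len - 1),
                  character(1)), paste0("r", seq_len(n)))
}

test_that("chunk sampling hits the target count and is deterministic", {
  g <- rseq(50000, 1)
  reads <- make_test_reads(g, 60, 6000, 2)
  ch <- sample_chunks(reads, L = 2000, target_span = 50000, seed = 3)
  expect_equal(nrow(ch), 25)
  expect_true(all(nchar(ch$sequence) == 2000))
  ch2 <- sample_chunks(reads, L = 2000, target_span = 50000, seed = 3)
  expect_identical(ch, ch2)
  # no overlapping chunks on the same read
  for (rid in unique(ch$source_read_id)) {
    iv <- ch[ch$source_read_id == rid, ]
    iv <- iv[order(iv$source_offset), ]
    if (nrow(iv) > 1)
      expect_true(all(diff(iv$source_offset) >= 2000))
  }
})

test_that("a read of exactly L yields its single possible chunk", {
  reads <- c(r1 = rseq(2000, 4))
  ch <- sample_chunks(reads, L = 2000, target_span = 2000, seed = 1)
  expect_equal(nrow(ch), 1)
  expect_identical(ch$sequence, unname(reads))
  expect_equal(ch$source_offset, 0)
  expect_error(sample_chunks(c(r1 = rseq(500, 5)), L = 2000, target_span = 2000),
               "shorter")
})

test_that("chunk-to-read alignment finds exact, noisy and reverse hits", {
  set.seed(6)
  chunk <- rseq(2000)
  left <- rseq(1500)
  right <- rseq(1500)
  reads <- c(exact = paste0(left, chunk, right),
             noisy = paste0(left, mutate_seq(chunk, 200), right),   # 10%
             rc = paste0(left, revcomp(chunk), right),
             far = paste0(left, mutate_seq(chunk, 600), right))     # 30%
  al <- align_chunks_to_reads(c(C1 = chunk), reads)
  expect_setequal(al$read_id, c("exact", "noisy", "rc"))
  ex <- al[al$read_id == "exact", ]
  expect_equal(ex$edit_distance, 0)
  expect_equal(ex$read_start, 1500)
  expect_equal(ex$read_end, 3500)
  expect_equal(ex$strand, "+")
  expect_equal(al$strand[al$read_id == "rc"], "-")
  expect_true(all(al$identity >= 0.80))
})

test_that("the copy-number estimator reproduces the coverage-ratio rule", {
  expect_equal(estimate_copy_number_raw(80, 20), 4L)
  expect_equal(estimate_copy_number_raw(0, 20), 0L)
  expect_equal(estimate_copy_number_raw(20, 20), 1L)
  expect_equal(estimate_copy_number_raw(c(80, 20, 45), 20), c(4L, 1L, 2L))
  expect_error(estimate_copy_number_raw(10, 0), "positive")
})

linear_adjacency <- function(ids) {
  # chain c1 - c2 - ... with R->L links
  n <- length(ids)
  data.frame(chunk_a = ids[-n], end_a = "R", chunk_b = ids[-1], end_b = "L",
             support = 10L, stringsAsFactors = FALSE)
}

test_that("flow refinement fixes a miscounted chunk on a linear path", {
  adj <- linear_adjacency(c("c1", "c2", "c3"))
  raw <- c(c1 = 2L, c2 = 3L, c3 = 2L)
  refined <- refine_copy_numbers(raw, adj)
  # brute-force oracle over {0..5}^3: minimize squared deviation subject to
  # the flow constraints cn2 == cn1 and cn2 == cn3
  best <- NULL
  bestq <- Inf
  for (a in 0:5) for (b in 0:5) for (c in 0:5) {
    if (b != a || b != c) next
    q <- (a - 2)^2 + (b - 3)^2 + (c - 2)^2
    if (q < bestq) {
      bestq <- q
      best <- c(a, b, c)
    }
  }
  expect_equal(unname(refined), best)
  expect_equal(unname(refined[2]), 2L)
})

test_that("a chunk joining two two-copy chunks gets copy number four", {
  adj <- data.frame(chunk_a = c("p1", "p2"), end_a = "R",
                    chunk_b = c("m", "m"), end_b = "L",
                    support = 10L, stringsAsFactors = FALSE)
  raw <- c(p1 = 2L, p2 = 2L, m = 3L)
  refined <- refine_copy_numbers(raw, adj)
  expect_equal(unname(refined["m"]), 4L)
})

test_that("refinement is the identity on consistent copy numbers", {
  adj <- linear_adjacency(paste0("c", 1:5))
  raw <- setNames(rep(1L, 5), paste0("c", 1:5))
  expect_equal(refine_copy_numbers(raw, adj), raw)
})

test_that("alignment count equals read depth on noise-free data", {
  g <- rseq(30000, 7)
  set.seed(8)
  reads <- make_test_reads(g, 90, 5000, 9)   # ~15x
  chunk <- substr(g, 14001, 16000)
  al <- align_chunks_to_reads(c(C1 = chunk), reads)
  depth <- sum(vapply(seq_along(reads), function(i) {
    # read fully contains the chunk locus
    s <- regexpr(substr(reads[[i]], 1, 30), g, fixed = TRUE)  # read start on g
    s >= 0 && s <= 14001 && s + 5000 - 1 >= 16000
  }, logical(1)))
  expect_lte(abs(nrow(al) - depth), 1)
})
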