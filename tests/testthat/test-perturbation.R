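test_that("banded forward likelihood matches the unbanded log-space oracle", {
  p <- pairhmm_params()
  for (s in 1:5) {
    ch <- rseq(60, s)
    rd <- mutate_seq(ch, 6, s + 100)
    expect_equal(loglik(ch, rd, p, band = 60), oracle_loglik(ch, rd, p),
                 tolerance = 1e-10)
  }
})

test_that("single-base likelihood equals the closed form of the model", {
  p <- pairhmm_params()
  # only path: start->M (prob 1 - 2 gap_open), emit match, M->end (prob 1)
  expect_equal(loglik("A", "A", p, band = 4),
               log((1 - 2 * p$gap_open) * p$match_prob), tolerance = 1e-12)
  expect_equal(loglik("A", "C", p, band = 4),
               log((1 - 2 * p$gap_open) * (1 - p$match_prob) / 3),
               tolerance = 1e-12)
})

test_that("the true sequence maximizes its own likelihood", {
  p <- pairhmm_params()
  s <- rseq(200, 42)
  s2 <- apply_edit(s, 77, "subA")
  if (s2 == s) s2 <- apply_edit(s, 77, "subC")
  expect_gt(loglik(s, s, p), loglik(s2, s, p))
})

test_that("banded equals unbanded forward on divergent pairs", {
  p <- pairhmm_params()
  for (s in 1:10) {
    ch <- rseq(200, s + 400)
    rd <- mutate_seq(ch, 20, s + 500)  # 10% divergence
    full <- loglik(ch, rd, p, band = max(nchar(ch), nchar(rd)))
    banded <- loglik(ch, rd, p, band = 50)
    expect_equal(banded, full, tolerance = 1e-6)
  }
})

test_that("every perturbation entry matches full recomputation", {
  p <- pairhmm_params()
  worst <- 0
  for (s in 1:2) {
    ch <- rseq(50, s + 20)
    rd <- mutate_seq(ch, 5, s + 30)
    P <- perturbation_matrix(ch, rd, p, band = 50)
    base <- oracle_loglik(ch, rd, p)
    for (i in seq_len(nchar(ch))) for (e in 1:9) {
      bf <- oracle_loglik(apply_edit(ch, i, e), rd, p) - base
      worst <- max(worst, abs(P[1, i, e] - bf))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("identity substitutions have exactly zero delta", {
  ch <- rseq(100, 9)
  rd <- mutate_seq(ch, 10, 10)
  P <- perturbation_matrix(ch, rd, band = 60)
  b <- strsplit(ch, "")[[1]]
  idx <- match(b, c("A", "C", "G", "T"))
  expect_true(all(P[cbind(1, seq_len(100), idx)] == 0))
})

test_that("a read identical to the chunk rejects every real edit", {
  ch <- rseq(150, 11)
  P <- perturbation_matrix(ch, ch, band = 60)
  b <- strsplit(ch, "")[[1]]
  idx <- match(b, c("A", "C", "G", "T"))
  nonid <- P[1, , ]
  nonid[cbind(seq_len(150), idx)] <- NA  # drop identity entries
  expect_true(all(nonid < 0, na.rm = TRUE))
})

test_that("the edit a read carries is the top entry of its column", {
  set.seed(12)
  ch <- rseq(200)
  rd <- apply_edit(ch, 100, "del")
  P <- perturbation_matrix(ch, rd, band = 60)
  expect_gt(P[1, 100, "del"], 0)
  expect_equal(which.max(P[1, 100, ]), c(del = 9))
  # and a substitution carried by the read
  b <- substr(ch, 120, 120)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  rd2 <- apply_edit(ch, 120, paste0("sub", alt))
  P2 <- perturbation_matrix(ch, rd2, band = 60)
  expect_gt(P2[1, 120, paste0("sub", alt)], 0)
  expect_equal(unname(which.max(P2[1, 120, ])),
               match(paste0("sub", alt), edit_names()))
})

test_that("applying the top variant raises total likelihood by about its gain", {
  set.seed(33)
  mk <- make_copies(400, 2, 1, seed = 77)
  reads <- copy_reads(mk$copies, 12, 0.08, seed = 78)
  segs <- oriented_segs(reads)
  P <- perturbation_matrix(mk$copies[1], segs, band = 60)
  U <- collect_variants(P)
  expect_gte(nrow(U), 1)
  top <- U[1, ]
  edited <- apply_edit(mk$copies[1], top$pos, top$edit)
  supp <- P[, top$pos, top$edit] > 0
  before <- vapply(segs[supp], function(r) loglik(mk$copies[1], r), numeric(1))
  after <- vapply(segs[supp], function(r) loglik(edited, r), numeric(1))
  expect_equal(sum(after - before), top$gain, tolerance = 0.1 * top$gain)
})

test_that("variant collection sums positive deltas and applies thresholds", {
  # constructed matrix: one bimodal variant, one all-negative column
  N <- 20
  P <- array(-2, dim = c(N, 50, 9),
             dimnames = list(paste0("r", 1:N), NULL, edit_names()))
  P[, , ] <- -2
  P[1:10, 25, "subG"] <- 2
  attr(P, "chunk") <- paste(rep("ACGT", 13), collapse = "")  # no homopolymers
  class(P) <- c("perturbation_matrix", "array")
  U <- collect_variants(P, chunk = NULL)
  expect_equal(nrow(U), 1)
  expect_equal(U$pos, 25)
  expect_equal(U$edit, "subG")
  expect_equal(U$gain, 10 * 2)  # N reads at +2 each, half supporting
  expect_equal(U$support, 10)
})

test_that("homopolymer, strand-bias and low-gain candidates are discarded", {
  cand <- data.frame(pos = c(10, 30, 50), edit = c("del", "subA", "subC"),
                     gain = c(50, 50, 1), support = c(10, 20, 10),
                     support_plus = c(5, 20, 5), support_minus = c(5, 0, 5),
                     stringsAsFactors = FALSE)
  class(cand) <- c("variant_set", "data.frame")
  chunk <- paste0(strrep("ACGT", 2), strrep("A", 6),  # run of 6 at pos 9-14
                  strrep("ACGT", 40))
  out <- filter_variants(cand, chunk = chunk, homopolymer_min = 5,
                         strand_alpha = 0.01, min_gain = 4)
  expect_equal(nrow(out), 0)  # pos 10 in run, pos 30 strand-biased, pos 50 weak
  # balanced, high-gain, outside runs -> retained
  ok <- cand[1, ]
  ok$pos <- 30
  ok$edit <- "subA"
  out2 <- filter_variants(ok, chunk = chunk)
  expect_equal(nrow(out2), 1)
})

test_that("overlong and overshort reads are excluded with a warning", {
  ch <- rseq(200, 5)
  expect_warning(P <- perturbation_matrix(ch, c(a = ch, b = rseq(50, 6))),
                 "excluding")
  expect_equal(dim(P)[1], 1)
})
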