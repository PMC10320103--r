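test_that("QV and genome fraction follow their definitions", {
  set.seed(101)
  truth <- make_diploid(30000, divergence = 0.001, seed = 101)
  contigs <- c(c1 = truth$hapA, c2 = truth$hapB)
  m <- qv_from_alignment(contigs, truth)
  expect_equal(m$errors, 0)
  expect_equal(m$qv, 60)  # capped on a perfect assembly
  expect_equal(m$genome_fraction, 1, tolerance = 1e-6)
  expect_equal(m$n_contigs, 2)

  # exactly one error in 10,000 aligned bases -> QV 40
  t2 <- list(hapA = rseq(10000, 102), hapB = rseq(10000, 103))
  class(t2) <- "diploid_truth"
  one_err <- apply_edit(t2$hapA, 5000, "del")
  m2 <- qv_from_alignment(c(c1 = one_err), list(A = t2$hapA, B = t2$hapB) |>
                            unlist(), qv_cap = 60)
  expect_equal(m2$errors, 1)
  expect_equal(m2$qv, -10 * log10(1 / nchar(one_err)), tolerance = 1e-6)
})

test_that("partial coverage yields the matching genome fraction", {
  truth <- list(A = rseq(20000, 104), B = rseq(20000, 105))
  contigs <- c(c1 = substr(truth$A, 1, 19000),     # 95% of hap A
               c2 = substr(truth$B, 1001, 20000))  # 95% of hap B
  m <- qv_from_alignment(contigs, unlist(truth))
  expect_equal(m$genome_fraction, 0.95, tolerance = 0.01)
  expect_equal(unname(m$genome_fraction_by_hap["A"]), 0.95, tolerance = 0.01)
})

test_that("QV decreases monotonically with injected errors", {
  truthseq <- c(A = rseq(20000, 106), B = rseq(20000, 107))
  qvs <- vapply(c(2, 10, 40), function(k) {
    bad <- mutate_seq(truthseq[["A"]], k, 108)
    qv_from_alignment(c(c1 = bad), truthseq)$qv
  }, numeric(1))
  expect_true(all(diff(qvs) < 0))
})

test_that("an unalignable contig counts as fully erroneous", {
  truthseq <- c(A = rseq(20000, 109), B = rseq(20000, 110))
  junk <- rseq(5000, 111)
  m <- qv_from_alignment(c(c1 = truthseq[["A"]], c2 = junk), truthseq)
  expect_equal(m$errors, 5000)
})

test_that("switch errors count phase changes along a contig", {
  truth <- make_diploid(30000, divergence = 0.003, seed = 112)
  expect_gt(nrow(truth$snv_ledger), 10)
  # a contig equal to one haplotype has no switches
  expect_equal(as.integer(switch_errors(c(c1 = truth$hapA), truth)), 0L)
  # a chimera with one crossover has exactly one
  cross <- 15000
  chimera <- paste0(substr(truth$hapA, 1, cross),
                    substr(truth$hapB, cross + 1, nchar(truth$hapB)))
  n_left <- sum(truth$snv_ledger$pos <= cross - 20)
  n_right <- sum(truth$snv_ledger$pos > cross + 20)
  if (n_left > 0 && n_right > 0)
    expect_equal(as.integer(switch_errors(c(c1 = chimera), truth)), 1L)
})
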