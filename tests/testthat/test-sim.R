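test_that("diploid simulation obeys SV arithmetic and ledger replay", {
  truth <- make_diploid(100000, divergence = 0.001,
                        svs = list(sv_spec("A", "insertion", 5000),
                                   sv_spec("B", "deletion", 5000)),
                        seed = 3, end_margin = 10000)
  expect_equal(nchar(truth$hapA), 105000)
  expect_equal(nchar(truth$hapB), 95000)
  # replay the ledgers independently of the constructor's internals
  for (h in c("A", "B")) {
    b <- strsplit(truth$ancestral, "")[[1]]
    led <- truth$snv_ledger[truth$snv_ledger$hap == h, ]
    expect_true(all(b[led$pos] == led$ref))
    b[led$pos] <- led$alt
    s <- paste(b, collapse = "")
    sv <- truth$sv_ledger[truth$sv_ledger$hap == h, ]
    sv <- sv[order(-sv$pos), ]
    for (i in seq_len(nrow(sv))) {
      s <- if (sv$kind[i] == "insertion")
        paste0(substr(s, 1, sv$pos[i] - 1), sv$seq[i],
               substr(s, sv$pos[i], nchar(s)))
      else paste0(substr(s, 1, sv$pos[i] - 1),
                  substr(s, sv$pos[i] + sv$length[i], nchar(s)))
    }
    expect_identical(s, truth[[paste0("hap", h)]])
    expect_identical(replay_haplotype(truth, h), truth[[paste0("hap", h)]])
  }
})

test_that("zero divergence and no SVs give identical haplotypes", {
  truth <- make_diploid(5000, divergence = 0, svs = list(), seed = 1)
  expect_identical(truth$hapA, truth$hapB)
  expect_identical(truth$hapA, truth$ancestral)
})

test_that("SNV counts are binomial at the stated divergence", {
  n <- vapply(1:20, function(s)
    nrow(make_diploid(100000, divergence = 0.001, seed = s)$snv_ledger),
    integer(1))
  # 3 sigma of Binomial(100000, 0.001) around mean 100
  expect_lt(abs(mean(n) - 100), 3 * sqrt(100000 * 0.001 * 0.999) / sqrt(20))
})

test_that("diploid simulation rejects bad inputs", {
  expect_error(make_diploid(10000, divergence = 0.2), "divergence")
  expect_error(make_diploid(50000, svs = list(
    sv_spec("A", "deletion", 1000, pos = 20000),
    sv_spec("B", "deletion", 1000, pos = 20500)), seed = 1), "overlap")
})

test_that("copies differ from the template by the stated edit count", {
  mk <- make_copies(2000, 2, 1, seed = 4)
  expect_equal(edit_distance(mk$copies[1], mk$copies[2]), 1)
  mk4 <- make_copies(2000, 4, 1, seed = 5)
  expect_equal(length(unique(mk4$copies)), 4)
  for (i in 1:3) for (j in (i + 1):4)
    expect_lte(edit_distance(mk4$copies[i], mk4$copies[j]), 2)
  expect_error(make_copies(2000, 4, 0), "edits_per_copy")
  expect_error(make_copies(2000, 1, 1), "n_copies")
})

test_that("zero-noise reads are exact substrings of their source", {
  truth <- make_diploid(20000, divergence = 0.001, seed = 6)
  model <- sim_read_model(0, 0, 0, coverage = 3, max_length = 5000,
                          length_distribution = list(family = "lognormal",
                                                     meanlog = log(3000),
                                                     sdlog = 0.3))
  reads <- simulate_reads(truth, model, seed = 7)
  src <- list(A = truth$hapA, B = truth$hapB)
  for (i in seq_len(nrow(reads))) {
    frag <- substr(src[[reads$haplotype[i]]], reads$start[i] + 1, reads$end[i])
    got <- if (reads$strand[i] == "-") revcomp(reads$sequence[i]) else reads$sequence[i]
    expect_identical(got, frag)
  }
})

test_that("coverage and read-length accounting is approximately right", {
  tmpl <- setNames(rseq(2000, 1), "t")
  model <- sim_read_model(coverage = 20, max_length = 2000,
                          length_distribution = list(family = "fixed",
                                                     length = 2000))
  reads <- simulate_reads(tmpl, model, seed = 8)
  expect_equal(nrow(reads), 20)
  expect_true(all(nchar(reads$sequence) > 1500))
  total <- sum(reads$end - reads$start)
  expect_lt(abs(total - 20 * 2000) / (20 * 2000), 0.1)
})

test_that("empirical error rate matches the nominal model", {
  tmpl <- rseq(2000, 2)
  model <- sim_read_model(0.04, 0.03, 0.03, coverage = 100,
                          max_length = 2000,
                          length_distribution = list(family = "fixed",
                                                     length = 2000))
  reads <- simulate_reads(setNames(tmpl, "t"), model, seed = 9)
  segs <- oriented_segs(reads)
  eds <- vapply(segs, function(s)
    chunkasm:::.ca_edit_distance_cpp(s, tmpl, -300L, 300L, FALSE)[1], integer(1))
  rate <- sum(eds) / sum(nchar(segs))
  expect_gt(rate, 0.08)
  expect_lt(rate, 0.12)
})

test_that("simulation is seed-deterministic", {
  truth <- make_diploid(20000, divergence = 0.001, seed = 10)
  m <- sim_read_model(coverage = 2, max_length = 4000)
  expect_identical(simulate_reads(truth, m, seed = 11),
                   simulate_reads(truth, m, seed = 11))
  expect_identical(make_diploid(20000, divergence = 0.001, seed = 10)$hapA,
                   truth$hapA)
})

test_that("reads and truth round-trip through FASTQ/FASTA/TSV", {
  truth <- make_diploid(10000, divergence = 0.001, seed = 12)
  m <- sim_read_model(coverage = 1, max_length = 3000)
  reads <- simulate_reads(truth, m, seed = 13)
  td <- withr::local_tempdir()
  fq <- file.path(td, "reads.fastq")
  fa <- file.path(td, "haps.fasta")
  write_fastq(reads, fq)
  write_fasta(c(A = truth$hapA, B = truth$hapB), fa)
  write_truth_tsv(reads, file.path(td, "truth.tsv"))
  back <- read_sequences(fq)
  expect_identical(unname(back[reads$id]), reads$sequence)
  expect_identical(unname(read_sequences(fa)["A"]), truth$hapA)
  tsv <- read.delim(file.path(td, "truth.tsv"))
  expect_equal(tsv$start, reads$start)
})
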