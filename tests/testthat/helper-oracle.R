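# Independent unbanded log-space forward algorithm for the pair-HMM.
# Written directly from the model definition (match/insertion/deletion
# states, affine gaps, start behaves like M, end absorbs at the corner);
# deliberately naive so it can serve as an oracle for the banded C++ path.

lse <- function(...) {
  x <- c(...)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

oracle_loglik <- function(chunk, read, p = pairhmm_params()) {
  cb <- strsplit(chunk, "")[[1]]
  rb <- strsplit(read, "")[[1]]
  L <- length(cb)
  l <- length(rb)
  m <- p$match_prob
  q <- (1 - m) / 3
  d <- p$gap_open
  e <- p$gap_extend
  tMM <- log(1 - 2 * d); tMI <- log(d); tMD <- log(d)
  tII <- log(e); tIM <- log(1 - e); tDD <- log(e); tDM <- log(1 - e)
  eM <- function(a, b) if (a == b) log(m) else log(q)
  M <- rep(-Inf, l + 1); I <- rep(-Inf, l + 1); D <- rep(-Inf, l + 1)
  M[1] <- 0
  for (j in seq_len(l) + 1)
    I[j] <- log(0.25) + lse(tMI + M[j - 1], tII + I[j - 1])
  for (i in seq_len(L)) {
    nM <- rep(-Inf, l + 1); nI <- rep(-Inf, l + 1); nD <- rep(-Inf, l + 1)
    for (j in seq_len(l + 1)) {
      if (j > 1) nM[j] <- eM(cb[i], rb[j - 1]) +
          lse(tMM + M[j - 1], tIM + I[j - 1], tDM + D[j - 1])
      nD[j] <- lse(tMD + M[j], tDD + D[j])
      if (j > 1) nI[j] <- log(0.25) + lse(tMI + nM[j - 1], tII + nI[j - 1])
    }
    M <- nM; I <- nI; D <- nD
  }
  lse(M[l + 1], I[l + 1], D[l + 1])
}

# random sequence and simple i.i.d. mutation helpers for fixtures
rseq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, n_err, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- strsplit(s, "")[[1]]
  for (k in seq_len(n_err)) {
    i <- sample(length(b), 1)
    op <- sample(3, 1)
    if (op == 1) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
    else if (op == 2) b <- append(b, sample(c("A", "C", "G", "T"), 1), after = i)
    else b <- b[-i]
  }
  paste(b, collapse = "")
}

edit_distance <- function(a, b) {
  w <- max(nchar(a), nchar(b))
  chunkasm:::.ca_edit_distance_cpp(a, b, -w, w, FALSE)[1]
}

# reads for the chunk-clustering benchmarks: full-length noisy copies
copy_reads <- function(copies, per_copy, err, seed) {
  model <- sim_read_model(mismatch_rate = err * 0.4, insertion_rate = err * 0.3,
                          deletion_rate = err * 0.3,
                          length_distribution = list(family = "fixed",
                                                     length = nchar(copies[1])),
                          max_length = nchar(copies[1]),
                          min_length = nchar(copies[1]) %/% 2,
                          coverage = per_copy)
  simulate_reads(setNames(copies, paste0("c", seq_along(copies))), model,
                 seed = seed)
}

# orient simulated reads back to the template frame
oriented_segs <- function(reads) {
  seg <- ifelse(reads$strand == "-", revcomp(reads$sequence), reads$sequence)
  setNames(seg, reads$id)
}

# exhaustive maximum of the clustering objective over all K-labelings
enumerate_optimum <- function(Pu, K) {
  N <- nrow(Pu)
  best <- -Inf
  labels <- rep(1L, N)
  repeat {
    obj <- cluster_objective(Pu, assignment = labels)
    if (obj > best) best <- obj
    i <- 1L
    while (i <= N && labels[i] == K) {
      labels[i] <- 1L
      i <- i + 1L
    }
    if (i > N) break
    labels[i] <- labels[i] + 1L
  }
  best
}
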