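#' Sample chunks from reads
#'
#' Draws approximately `target_span / L` chunks of length `L` from random
#' reads at random offsets, so that the target region is represented at
#' about 1-fold chunk coverage. Offsets keep a full chunk inside the read,
#' and no two chunks are drawn from overlapping intervals of the same read.
#'
#' @param reads A `sim_reads` data.frame or named character vector of read
#'   sequences.
#' @param L Chunk length in bp (default 2000).
#' @param target_span Haploid span of the target region in bp.
#' @param seed Integer seed.
#' @return A `chunk_set` data.frame: chunk_id, sequence, source_read_id,
#'   source_offset (0-based).
#' @export
sample_chunks <- function(reads, L = 2000L, target_span, seed = 1L) {
  seqs <- read_seqs(reads)
  if (L < 100) stop("L must be >= 100")
  lens <- nchar(seqs)
  eligible <- which(lens >= L)
  if (length(eligible) == 0) stop("all reads are shorter than the chunk length")
  set.seed(seed)
  n_target <- max(1L, as.integer(round(target_span / L)))
  w <- lens[eligible] - L + 1
  used <- vector("list", length(seqs))
  out <- vector("list", n_target)
  got <- 0L
  tries <- 0L
  while (got < n_target && tries < 60L * n_target) {
    tries <- tries + 1L
    ri <- eligible[sample.int(length(eligible), 1L, prob = w)]
    off <- sample.int(lens[ri] - L + 1L, 1L) - 1L  # 0-based
    iv <- used[[ri]]
    if (!is.null(iv) && any(off < iv[, 2] & off + L > iv[, 1])) next
    used[[ri]] <- rbind(iv, c(off, off + L))
    got <- got + 1L
    out[[got]] <- data.frame(chunk_id = sprintf("C%04d", got),
                             sequence = substr(seqs[ri], off + 1L, off + L),
                             source_read_id = names(seqs)[ri],
                             source_offset = off, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[seq_len(got)])
  rownames(res) <- NULL
  class(res) <- c("chunk_set", "data.frame")
  res
}

read_seqs <- function(reads) {
  if (inherits(reads, "data.frame")) {
    setNames(reads$sequence, reads$id)
  } else {
    if (is.null(names(reads))) names(reads) <- paste0("r", seq_along(reads))
    reads
  }
}

#' Align chunks to all reads at relaxed identity
#'
#' Every read region within edit distance `max_error * L` of a chunk, on
#' either strand, yields one alignment; overlapping candidate hits on the
#' same read are reduced to the best one. Candidates are seeded by exact
#' k-mer matches and verified by banded semi-global edit distance (band
#' width proportional to `max_error * L`).
#'
#' @param chunks A `chunk_set` or named character vector.
#' @param reads A `sim_reads` data.frame or named character vector.
#' @param max_error Maximum error fraction (default 0.20).
#' @param k Seed k-mer size.
#' @param min_seeds Minimum seed count to trigger verification.
#' @param max_kmer_hits Seeds occurring more often than this in the chunk
#'   index are ignored (guards against tandem repeats).
#' @return A `chunk_alignments` data.frame: chunk_id, read_id, read_start,
#'   read_end (0-based half-open, forward read coordinates), strand,
#'   edit_distance, identity.
#' @export
align_chunks_to_reads <- function(chunks, reads, max_error = 0.20, k = 15L,
                                  min_seeds = 2L, max_kmer_hits = 200L) {
  if (max_error <= 0 || max_error >= 0.5) stop("max_error must be in (0, 0.5)")
  cseq <- if (inherits(chunks, "data.frame")) setNames(chunks$sequence, chunks$chunk_id) else chunks
  rseq <- read_seqs(reads)
  hits <- .ca_map_chunks_cpp(unname(cseq), unname(rseq), max_error,
                             as.integer(k), as.integer(min_seeds),
                             as.integer(max_kmer_hits))
  alen <- pmax(hits$read_end - hits$read_start, nchar(cseq)[hits$chunk])
  res <- data.frame(chunk_id = names(cseq)[hits$chunk],
                    read_id = names(rseq)[hits$read],
                    read_start = hits$read_start, read_end = hits$read_end,
                    strand = ifelse(hits$strand == 0, "+", "-"),
                    edit_distance = hits$edit_distance,
                    identity = 1 - hits$edit_distance / alen,
                    stringsAsFactors = FALSE)
  res <- res[order(res$read_id, res$read_start), ]
  rownames(res) <- NULL
  class(res) <- c("chunk_alignments", "data.frame")
  res
}

#' Raw copy-number estimate of a chunk
#'
#' The alignment count divided by the genome-wide haploid coverage, rounded
#' to the nearest integer: with haploid coverage 20 and 80 alignments the
#' copy number is 4.
#'
#' @param alignment_count Number of read alignments of the chunk (vectorized).
#' @param haploid_coverage Genome-wide haploid coverage (fold).
#' @return Integer copy number(s), minimum 0.
#' @export
estimate_copy_number_raw <- function(alignment_count, haploid_coverage) {
  if (haploid_coverage <= 0) stop("haploid_coverage must be positive")
  pmax(0L, as.integer(round(alignment_count / haploid_coverage)))
}

#' Estimate haploid coverage from chunk alignments
#'
#' Median per-chunk alignment count divided by 2 (most chunks of a diploid
#' region have copy number two).
#' @param alignments A `chunk_alignments` data.frame.
#' @return Estimated haploid coverage.
#' @export
estimate_haploid_coverage <- function(alignments) {
  cnt <- table(alignments$chunk_id)
  as.numeric(median(cnt)) / 2
}

#' Chunk adjacency from consecutive hits on reads
#'
#' Two chunks are adjacent when their alignments are consecutive along some
#' read. Each chunk has two ends ("L"/"R", in chunk-forward orientation);
#' an adjacency records which end of each chunk faces the other.
#'
#' @param alignments A `chunk_alignments` data.frame.
#' @param min_support Minimum number of supporting reads.
#' @return data.frame: chunk_a, end_a, chunk_b, end_b, support.
#' @export
chunk_adjacency <- function(alignments, min_support = 2L) {
  key <- character(0)
  tally <- new.env(parent = emptyenv())
  by_read <- split(alignments, alignments$read_id)
  for (al in by_read) {
    if (nrow(al) < 2) next
    al <- al[order(al$read_start), ]
    for (i in seq_len(nrow(al) - 1)) {
      a <- al[i, ]; b <- al[i + 1, ]
      end_a <- if (a$strand == "+") "R" else "L"
      end_b <- if (b$strand == "+") "L" else "R"
      k1 <- paste(a$chunk_id, end_a, b$chunk_id, end_b, sep = "\r")
      k2 <- paste(b$chunk_id, end_b, a$chunk_id, end_a, sep = "\r")
      k <- min(k1, k2)
      tally[[k]] <- (tally[[k]] %||% 0L) + 1L
    }
  }
  keys <- ls(tally)
  if (length(keys) == 0) {
    return(data.frame(chunk_a = character(0), end_a = character(0),
                      chunk_b = character(0), end_b = character(0),
                      support = integer(0), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  res <- data.frame(chunk_a = parts[, 1], end_a = parts[, 2],
                    chunk_b = parts[, 3], end_b = parts[, 4],
                    support = vapply(keys, function(k) tally[[k]], integer(1)),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[res$support >= min_support, , drop = FALSE]
}

#' Refine copy numbers with neighbor-flow constraints
#'
#' Integer copy numbers minimizing the squared deviation from the raw
#' estimates subject to flow consistency: wherever the adjacency is
#' unambiguous (every neighbor on one end of a chunk connects back only to
#' that chunk), the chunk's copy number must equal the sum over those
#' neighbors -- e.g. a chunk flanked by two copy-number-2 chunks on the
#' same end gets copy number 4. Solved by penalized integer coordinate
#' descent; if the active constraints remain violated the raw estimates
#' are returned with a warning.
#'
#' @param raw Named integer vector of raw copy numbers (names = chunk ids),
#'   or a data.frame with columns chunk_id, copy_number.
#' @param adjacency Output of [chunk_adjacency()].
#' @param max_cn Largest copy number considered.
#' @param penalty Constraint penalty weight.
#' @param max_sweeps Maximum coordinate-descent sweeps.
#' @return Named integer vector of refined copy numbers.
#' @export
refine_copy_numbers <- function(raw, adjacency, max_cn = 8L, penalty = 4,
                                max_sweeps = 30L) {
  if (inherits(raw, "data.frame")) raw <- setNames(raw$copy_number, raw$chunk_id)
  ids <- names(raw)
  cn <- as.numeric(raw)
  names(cn) <- ids
  # neighbor sets per (chunk, end)
  nb <- list()
  addnb <- function(c1, e1, c2, e2) {
    k <- paste0(c1, ".", e1)
    nb[[k]] <<- unique(c(nb[[k]], paste0(c2, ".", e2)))
  }
  for (i in seq_len(nrow(adjacency))) {
    addnb(adjacency$chunk_a[i], adjacency$end_a[i], adjacency$chunk_b[i], adjacency$end_b[i])
    addnb(adjacency$chunk_b[i], adjacency$end_b[i], adjacency$chunk_a[i], adjacency$end_a[i])
  }
  side_chunk <- function(s) sub("\\.[LR]$", "", s)
  # active constraints: chunk end whose neighbors each connect back only here
  constraints <- list()
  for (k in names(nb)) {
    self <- side_chunk(k)
    ns <- nb[[k]]
    if (length(ns) == 0) next
    exclusive <- all(vapply(ns, function(s) identical(nb[[s]], k), logical(1)))
    if (exclusive && all(side_chunk(ns) %in% ids) && self %in% ids)
      constraints[[length(constraints) + 1L]] <- list(self = self, nbrs = side_chunk(ns))
  }
  # chunks serving as flow sources for others are slightly more trusted,
  # so a conflict is resolved by moving the constrained chunk
  wt <- setNames(rep(1, length(ids)), ids)
  for (con in constraints) wt[con$nbrs] <- wt[con$nbrs] + 0.1
  qcost <- function(cnv) {
    q <- sum(wt * (cnv - raw)^2)
    for (con in constraints)
      q <- q + penalty * (cnv[con$self] - sum(cnv[con$nbrs]))^2
    q
  }
  descend <- function(cnv) {
    for (sweep in seq_len(max_sweeps)) {
      changed <- FALSE
      for (id in ids) {
        vals <- 0:max_cn
        costs <- vapply(vals, function(v) {
          tmp <- cnv
          tmp[id] <- v
          qcost(tmp)
        }, numeric(1))
        best <- vals[which.min(costs)]
        if (best != cnv[id]) {
          cnv[id] <- best
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    cnv
  }
  # coordinate descent from several starts (raw, +-1, constraint-propagated)
  starts <- list(cn, pmax(cn - 1, 0), pmin(cn + 1, max_cn))
  prop <- cn
  for (con in constraints) prop[con$self] <- min(sum(prop[con$nbrs]), max_cn)
  starts <- c(starts, list(prop))
  best_cn <- NULL
  best_q <- Inf
  for (st in starts) {
    fit <- descend(st)
    q <- qcost(fit)
    if (q < best_q) {
      best_q <- q
      best_cn <- fit
    }
  }
  cn <- best_cn
  violated <- any(vapply(constraints, function(con)
    cn[con$self] != sum(cn[con$nbrs]), logical(1)))
  if (violated) {
    warning("flow constraints infeasible; falling back to raw copy numbers")
    return(setNames(as.integer(raw), ids))
  }
  setNames(as.integer(cn), ids)
}
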