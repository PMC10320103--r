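#' Align a contig to a set of truth sequences
#'
#' Seeds with exact k-mer anchors against each truth sequence on both
#' strands, picks the best-supported one, and verifies with a banded
#' semi-global edit distance around the anchor diagonals (the contig is
#' consumed in full; truth start/end are free).
#'
#' @param contig Contig sequence.
#' @param truths Named character vector of truth sequences.
#' @param k Anchor k-mer size.
#' @param band_slack Extra band half-width beyond the anchor diagonal range.
#' @return List: `truth` (name or NA), `strand`, `edit_distance`,
#'   `truth_start`, `truth_end` (0-based half-open), `anchors` (matrix of
#'   contig/truth positions, on the oriented contig).
#' @export
align_to_truth <- function(contig, truths, k = 17L, band_slack = 200L) {
  best <- NULL
  for (tn in names(truths)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") contig else revcomp(contig)
      an <- .ca_anchors_cpp(q, truths[[tn]], as.integer(k), 20L, 5L)
      if (nrow(an) < 5) next
      d <- an[, 2] - an[, 1]
      dmed <- median(d)
      keep <- abs(d - dmed) < 0.1 * nchar(q) + 2000
      if (sum(keep) < 5) next
      score <- sum(keep)
      if (is.null(best) || score > best$score) {
        best <- list(truth = tn, strand = strand, anchors = an[keep, , drop = FALSE],
                     score = score, q = q)
      }
    }
  }
  if (is.null(best)) {
    return(list(truth = NA_character_, strand = NA_character_,
                edit_distance = NA_integer_, truth_start = NA_integer_,
                truth_end = NA_integer_, anchors = NULL))
  }
  d <- best$anchors[, 2] - best$anchors[, 1]
  dlo <- min(d) - band_slack
  dhi <- max(d) + band_slack
  r <- .ca_edit_distance_cpp(best$q, truths[[best$truth]], as.integer(dlo),
                             as.integer(dhi), TRUE)
  list(truth = best$truth, strand = best$strand, edit_distance = r[1],
       truth_start = r[2], truth_end = r[3], anchors = best$anchors)
}

#' Assembly metrics against a simulated truth
#'
#' Aligns each contig to the truth haplotypes, sums edit errors over the
#' alignments, and reports QV = -10 log10(errors / aligned bases) (capped
#' at `qv_cap` when no errors remain), the per-haplotype and pooled genome
#' fraction covered, and contig counts. Unalignable contigs are counted as
#' fully erroneous.
#'
#' @param contigs Named character vector of contig sequences, or a list of
#'   `contig` objects, or the result of [run_pipeline()].
#' @param truth A `diploid_truth` or named character vector of haplotypes.
#' @param qv_cap QV reported when the error count is 0.
#' @return An `assembly_metrics` list: `n_contigs`, `n_multicopy`,
#'   `total_bases`, `qv`, `errors`, `aligned_bases`, `genome_fraction`,
#'   `genome_fraction_by_hap`, `per_contig`.
#' @export
qv_from_alignment <- function(contigs, truth, qv_cap = 60) {
  truths <- if (inherits(truth, "diploid_truth"))
    c(A = truth$hapA, B = truth$hapB) else truth
  cs <- contig_seqs(contigs)
  labels <- contig_labels(contigs)
  if (length(cs) == 0 || length(truths) == 0) stop("contigs and truth must be non-empty")
  per <- list()
  errors <- 0
  aligned <- 0
  cov <- lapply(truths, function(x) matrix(numeric(0), ncol = 2))
  for (ci in seq_along(cs)) {
    a <- align_to_truth(cs[[ci]], truths)
    if (is.na(a$truth)) {
      errors <- errors + nchar(cs[[ci]])
      aligned <- aligned + nchar(cs[[ci]])
      per[[ci]] <- data.frame(contig = names(cs)[ci], truth = NA, strand = NA,
                              length = nchar(cs[[ci]]), edit_distance = nchar(cs[[ci]]),
                              stringsAsFactors = FALSE)
      next
    }
    errors <- errors + a$edit_distance
    aligned <- aligned + nchar(cs[[ci]])
    cov[[a$truth]] <- rbind(cov[[a$truth]], c(a$truth_start, a$truth_end))
    per[[ci]] <- data.frame(contig = names(cs)[ci], truth = a$truth,
                            strand = a$strand, length = nchar(cs[[ci]]),
                            edit_distance = a$edit_distance,
                            stringsAsFactors = FALSE)
  }
  qv <- if (errors == 0) qv_cap else min(qv_cap, -10 * log10(errors / aligned))
  merged <- function(iv) {
    if (nrow(iv) == 0) return(0)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    tot <- 0
    cur <- iv[1, ]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv[i, 1] <= cur[2]) cur[2] <- max(cur[2], iv[i, 2]) else {
        tot <- tot + cur[2] - cur[1]
        cur <- iv[i, ]
      }
    }
    tot + cur[2] - cur[1]
  }
  gf_hap <- vapply(names(truths), function(tn)
    merged(cov[[tn]]) / nchar(truths[[tn]]), numeric(1))
  gf <- sum(vapply(names(truths), function(tn) merged(cov[[tn]]), numeric(1))) /
    sum(nchar(truths))
  res <- list(n_contigs = sum(labels == "haplotype_phased"),
              n_multicopy = sum(labels == "multicopy"),
              total_bases = sum(nchar(unlist(cs))),
              qv = qv, errors = errors, aligned_bases = aligned,
              genome_fraction = min(gf, 1),
              genome_fraction_by_hap = pmin(gf_hap, 1),
              per_contig = do.call(rbind, per))
  class(res) <- "assembly_metrics"
  res
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat(sprintf("assembly: %d phased contigs (+%d multicopy), %d bases\n",
              x$n_contigs, x$n_multicopy, x$total_bases))
  cat(sprintf("QV %.1f (%d errors / %d aligned bases), genome fraction %.3f\n",
              x$qv, x$errors, x$aligned_bases, x$genome_fraction))
  invisible(x)
}

contig_seqs <- function(contigs) {
  if (is.list(contigs) && !is.null(contigs$contigs)) contigs <- contigs$contigs
  if (inherits(contigs, "data.frame")) return(setNames(as.list(contigs$sequence), contigs$id))
  if (is.character(contigs)) {
    if (is.null(names(contigs))) names(contigs) <- paste0("contig", seq_along(contigs))
    return(as.list(contigs))
  }
  # list of contig objects
  setNames(lapply(contigs, `[[`, "sequence"),
           paste0("contig", seq_along(contigs)))
}

contig_labels <- function(contigs) {
  if (is.list(contigs) && !is.null(contigs$contigs)) contigs <- contigs$contigs
  if (inherits(contigs, "data.frame")) return(contigs$label)
  if (is.character(contigs)) return(rep("haplotype_phased", length(contigs)))
  vapply(contigs, function(x) x$label %||% "haplotype_phased", character(1))
}

#' Count switch errors of contigs against the SNV ledger
#'
#' For every heterozygous SNV whose ancestral context maps inside a
#' contig's truth alignment, the contig base is matched against the two
#' allele contexts (21-bp windows); the resulting A/B calls along the
#' contig are scanned and each phase change counts as one switch error.
#'
#' @param contigs Contigs (as in [qv_from_alignment()]).
#' @param truth A `diploid_truth`.
#' @param flank Context half-width around each SNV.
#' @param search Search radius on the contig around the expected position.
#' @return Total switch errors (integer); per-contig detail in attribute
#'   `calls`.
#' @export
switch_errors <- function(contigs, truth, flank = 10L, search = 60L) {
  truths <- c(A = truth$hapA, B = truth$hapB)
  led <- truth$snv_ledger
  if (nrow(led) < 2) return(0L)
  anc <- truth$ancestral
  cs <- contig_seqs(contigs)
  # ancestral -> haplotype coordinate shift from SVs
  shift_for <- function(hap, pos) {
    sv <- truth$sv_ledger[truth$sv_ledger$hap == hap, , drop = FALSE]
    s <- pos
    for (i in seq_len(nrow(sv))) {
      if (sv$kind[i] == "insertion" && sv$pos[i] <= pos) s <- s + sv$length[i]
      if (sv$kind[i] == "deletion" && sv$pos[i] + sv$length[i] <= pos) s <- s - sv$length[i]
    }
    s
  }
  total <- 0L
  all_calls <- list()
  for (ci in seq_along(cs)) {
    a <- align_to_truth(cs[[ci]], truths)
    if (is.na(a$truth)) next
    q <- if (a$strand == "+") cs[[ci]] else revcomp(cs[[ci]])
    am <- list(dx = a$anchors[, 2], rx = a$anchors[, 1])  # truth -> contig
    o <- order(am$dx)
    am <- list(dx = am$dx[o], rx = am$rx[o])
    keep <- !duplicated(am$dx)
    am <- list(dx = am$dx[keep], rx = am$rx[keep])
    calls <- character(0)
    at <- integer(0)
    for (v in seq_len(nrow(led))) {
      pos_t <- shift_for(a$truth, led$pos[v])
      if (pos_t < a$truth_start + flank || pos_t > a$truth_end - flank) next
      ctx <- substr(anc, led$pos[v] - flank, led$pos[v] + flank)
      alt_ctx <- ctx
      substr(alt_ctx, flank + 1L, flank + 1L) <- led$alt[v]
      carrier_ctx <- if (led$hap[v] == "A") alt_ctx else ctx
      other_ctx <- if (led$hap[v] == "A") ctx else alt_ctx
      # expected contig position
      cp <- round(map_draft_to_read(am, pos_t))
      lo <- max(1L, cp - search)
      hi <- min(nchar(q), cp + search)
      if (hi - lo < 2 * flank + 1) next
      win <- substr(q, lo, hi)
      w <- 2L * flank + 10L
      dA <- .ca_edit_distance_cpp(if (a$truth == "A") carrier_ctx else other_ctx,
                                  win, -w, nchar(win), TRUE)[1]
      dB <- .ca_edit_distance_cpp(if (a$truth == "A") other_ctx else carrier_ctx,
                                  win, -w, nchar(win), TRUE)[1]
      if (is.na(dA) || is.na(dB) || dA == dB) next
      calls <- c(calls, if (dA < dB) "A" else "B")
      at <- c(at, pos_t)
    }
    if (length(calls) >= 2) {
      o <- order(at)
      total <- total + sum(calls[o][-1] != calls[o][-length(calls)])
    }
    all_calls[[names(cs)[ci]]] <- calls
  }
  attr(total, "calls") <- all_calls
  total
}

#' Read-length sweep
#'
#' Simulates reads at several maximum lengths (several replicates each),
#' runs the full pipeline, and records the number of phased contigs,
#' reporting the smallest maximum length at which every replicate yields
#' two.
#'
#' @param genome A `diploid_truth`.
#' @param max_lengths Maximum read lengths (bp) to test.
#' @param replicates Replicates per length.
#' @param config A [pipeline_config()].
#' @param model Base [sim_read_model()] (its `max_length` is overridden).
#' @return List: `table` (data.frame max_length, replicate, n_contigs),
#'   `threshold` (smallest all-replicates-2 length, NA if none).
#' @export
length_sweep <- function(genome, max_lengths, replicates = 10L,
                         config = pipeline_config(), model = sim_read_model()) {
  rows <- list()
  for (ml in max_lengths) {
    for (rep in seq_len(replicates)) {
      m <- model
      m$max_length <- as.integer(ml)
      seed <- derive_seed(config$seed, sprintf("sweep_%d_%d", ml, rep))
      rds <- simulate_reads(genome, m, seed = seed)
      cfg <- config
      cfg$seed <- derive_seed(seed, "asm")
      res <- run_pipeline(rds, config = cfg)
      rows[[length(rows) + 1L]] <-
        data.frame(max_length = ml, replicate = rep,
                   n_contigs = sum(res$contigs$label == "haplotype_phased"))
    }
  }
  tab <- do.call(rbind, rows)
  ok <- vapply(max_lengths, function(ml)
    all(tab$n_contigs[tab$max_length == ml] == 2L), logical(1))
  list(table = tab, threshold = if (any(ok)) min(max_lengths[ok]) else NA_integer_)
}
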