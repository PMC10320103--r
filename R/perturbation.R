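#' Pair-HMM parameters
#'
#' Parameters of the 3-state (match / insertion / deletion) pair hidden
#' Markov model used to score a read given a chunk. The model is
#' conditional on the chunk: the match state emits a read base (probability
#' `match_prob` of agreeing with the chunk base, `(1 - match_prob)/3` for
#' each other base), the insertion state emits a read base uniformly, and
#' the deletion state consumes a chunk base silently. Gaps are affine:
#' `gap_open` is the M->I and M->D transition probability, `gap_extend` the
#' I->I and D->D self transition. There are no I<->D transitions; the start
#' state behaves like M and the model terminates with probability 1 once
#' both sequences are consumed.
#'
#' Defaults are tuned to reads with roughly 10% total error dominated by
#' single-base events (4% substitutions, 3% + 3% short indels).
#'
#' @param match_prob Emission agreement probability in the match state.
#' @param gap_open M->I and M->D transition probability.
#' @param gap_extend I->I and D->D transition probability.
#' @return An object of class `pairhmm_params`.
#' @export
pairhmm_params <- function(match_prob = 0.95, gap_open = 0.035, gap_extend = 0.15) {
  stopifnot(match_prob > 0, match_prob < 1,
            gap_open > 0, 2 * gap_open < 1,
            gap_extend > 0, gap_extend < 1)
  structure(list(match_prob = match_prob, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "pairhmm_params")
}

#' @export
print.pairhmm_params <- function(x, ...) {
  cat(sprintf("pair-HMM: match_prob=%.3f gap_open=%.3f gap_extend=%.3f\n",
              x$match_prob, x$gap_open, x$gap_extend))
  invisible(x)
}

default_band <- function(chunk, read) {
  max(16L, as.integer(ceiling(0.25 * max(nchar(chunk), nchar(read)))))
}

#' Log-likelihood of a read given a chunk
#'
#' Forward-algorithm log probability of generating `read` from `chunk`
#' under the pair-HMM, computed with a banded dynamic program (band
#' half-width `band`; the default, a quarter of the longer sequence, leaves
#' results unchanged to well below 1e-6 for alignable pairs).
#'
#' @param chunk,read DNA strings over A/C/G/T.
#' @param params A [pairhmm_params()] object.
#' @param band Band half-width in bp.
#' @return The log-likelihood (natural log).
#' @export
loglik <- function(chunk, read, params = pairhmm_params(),
                   band = default_band(chunk, read)) {
  stopifnot(nchar(chunk) > 0, nchar(read) > 0)
  .ca_loglik_cpp(chunk, read, params$match_prob, params$gap_open,
                 params$gap_extend, as.integer(band))
}

#' Names of the nine single-base edits
#'
#' Order used throughout: substitutions to A/C/G/T at a position,
#' insertions of A/C/G/T immediately before a position, and deletion of
#' the position.
#' @return Character vector of length 9.
#' @export
edit_names <- function() {
  c("subA", "subC", "subG", "subT", "insA", "insC", "insG", "insT", "del")
}

#' Apply a single-base edit to a sequence
#'
#' @param seq DNA string.
#' @param i Position, 1-based.
#' @param e Edit: an index 1..9 or a name from [edit_names()].
#' @return The edited string.
#' @export
apply_edit <- function(seq, i, e) {
  if (is.character(e)) e <- match(e, edit_names())
  stopifnot(!is.na(e), e >= 1, e <= 9, i >= 1, i <= nchar(seq))
  bases <- c("A", "C", "G", "T")
  if (e <= 4) {
    substr(seq, i, i) <- bases[e]
    seq
  } else if (e <= 8) {
    paste0(substr(seq, 1, i - 1), bases[e - 4], substr(seq, i, nchar(seq)))
  } else {
    paste0(substr(seq, 1, i - 1), substr(seq, i + 1, nchar(seq)))
  }
}

#' Perturbation matrix of a chunk
#'
#' For every read, chunk position `i`, and single-base edit `e`, the change
#' in log-likelihood `P[r, i, e] = loglik(apply_edit(chunk, i, e), r) -
#' loglik(chunk, r)`. Entries are computed from stored forward and backward
#' matrices (each alignment path consumes chunk base `i` exactly once,
#' which turns each edit into an O(band) cut sum), so the total cost is
#' O(N * L * band) rather than a full recomputation per edit.
#'
#' Reads must already be oriented to the chunk strand and trimmed to the
#' aligned segment; reads whose length is outside `[0.5, 2]` times the
#' chunk length are excluded with a warning.
#'
#' @param chunk Chunk sequence (length L).
#' @param reads Character vector of oriented read segments.
#' @param params A [pairhmm_params()] object.
#' @param band Band half-width in bp.
#' @param read_ids Optional read identifiers (default names or seq_along).
#' @return An object of class `perturbation_matrix`: a 3-d array
#'   `[read, position, edit]` with attributes `loglik` (per-read baseline
#'   log-likelihoods), `chunk`, and `read_ids`.
#' @export
perturbation_matrix <- function(chunk, reads, params = pairhmm_params(),
                                band = NULL, read_ids = NULL) {
  if (is.null(read_ids)) read_ids <- names(reads) %||% as.character(seq_along(reads))
  lens <- nchar(reads)
  L <- nchar(chunk)
  ok <- lens >= 0.5 * L & lens <= 2 * L
  if (!all(ok)) {
    warning(sprintf("excluding %d read(s) with length outside [0.5, 2] x chunk length",
                    sum(!ok)))
    reads <- reads[ok]
    read_ids <- read_ids[ok]
  }
  if (length(reads) == 0) stop("no usable reads on chunk")
  if (is.null(band)) band <- max(16L, as.integer(ceiling(0.25 * L)))
  res <- .ca_perturbation_cpp(chunk, unname(reads), params$match_prob,
                              params$gap_open, params$gap_extend,
                              as.integer(band), FALSE)
  P <- res$P
  dimnames(P) <- list(read_ids, NULL, edit_names())
  structure(P, loglik = res$loglik, chunk = chunk, read_ids = read_ids,
            class = c("perturbation_matrix", "array"))
}

#' Summed perturbation of a draft sequence
#'
#' `Ps[i, e] = sum_r P[r, i, e]` computed without materializing the
#' per-read matrices; used by consensus polishing.
#'
#' @inheritParams perturbation_matrix
#' @return A list with `Ps` (L x 9 matrix, columns [edit_names()]) and
#'   `loglik` (per-read baseline log-likelihoods).
#' @export
summed_perturbation <- function(chunk, reads, params = pairhmm_params(),
                                band = NULL) {
  L <- nchar(chunk)
  if (is.null(band)) band <- max(16L, as.integer(ceiling(0.25 * L)))
  res <- .ca_perturbation_cpp(chunk, unname(reads), params$match_prob,
                              params$gap_open, params$gap_extend,
                              as.integer(band), TRUE)
  colnames(res$Ps) <- edit_names()
  res
}

#' Collect candidate variants from a perturbation matrix
#'
#' A candidate edit `(i, e)` is scored by its gain, the summed positive
#' perturbation `sum_r max(P[r, i, e], 0)`. Candidates are retained when
#' the gain reaches `min_gain` and the fraction of positively supporting
#' reads lies in `[min_support_fraction, max_support_fraction]` (the upper
#' bound removes near-unanimous edits, which correct errors of the chunk
#' sequence itself rather than distinguish its copies), then passed through
#' [filter_variants()] when `strand` and the chunk sequence are supplied.
#'
#' @param P A [perturbation_matrix()].
#' @param min_gain Minimum summed positive log-likelihood gain (nats).
#' @param min_support_fraction Minimum fraction of reads with positive delta.
#' @param max_support_fraction Maximum fraction of reads with positive delta.
#' @param min_mean_gain Minimum gain per supporting read (nats). Reads that
#'   genuinely carry a variant gain several nats each, while sloppy
#'   alignment regions yield many small positive deltas; this separates the
#'   two regimes.
#' @param noise_rate_sub,noise_rate_indel,noise_alpha Per-position
#'   probabilities that a read spuriously supports a substitution or indel
#'   edit (sequencing-error driven). A candidate must have more supporters
#'   than the `1 - noise_alpha / (9 L)` binomial quantile (a Bonferroni
#'   bound over all candidate edits), which adapts the support requirement
#'   to the read depth: low-coverage chunks would otherwise pass dozens of
#'   coincident-indel-error candidates.
#' @param decisive_delta,min_decisive_fraction A genuine difference between
#'   copies splits the reads bimodally: carriers gain several nats, the
#'   rest lose several. A candidate is kept only if at least
#'   `min_decisive_fraction` of the reads have `|delta| >=
#'   decisive_delta`, and the supporting share among those decisive reads
#'   lies within the support-fraction window. Alignment slop (short
#'   homopolymer indels) leaves most reads near zero and is removed.
#' @param strand Optional per-read strand ("+" / "-") for the bias filter.
#' @param chunk Optional chunk sequence for the homopolymer filter
#'   (defaults to the sequence stored in `P`).
#' @param ... Passed to [filter_variants()].
#' @return A `variant_set`: data.frame with columns `pos`, `edit`, `gain`,
#'   `support`, `support_plus`, `support_minus`.
#' @export
collect_variants <- function(P, min_gain = 4.0, min_support_fraction = 0.2,
                             max_support_fraction = 0.85, min_mean_gain = 1.5,
                             noise_rate_sub = 0.02, noise_rate_indel = 0.08,
                             noise_alpha = 0.05,
                             decisive_delta = 1.5, min_decisive_fraction = 0.6,
                             strand = NULL, chunk = attr(P, "chunk"), ...) {
  N <- dim(P)[1]
  if (N < 4) stop("need at least 4 reads to collect variants")
  L <- dim(P)[2]
  gain <- matrix(colSums(pmax(P, 0)), L, 9)
  supp <- matrix(colSums(P > 0), L, 9)
  sdec <- matrix(colSums(P >= decisive_delta), L, 9)
  ndec <- sdec + matrix(colSums(P <= -decisive_delta), L, 9)
  sfrac <- sdec / pmax(ndec, 1)
  q <- 1 - noise_alpha / (9 * L)
  min_count <- matrix(rep(c(rep(stats::qbinom(q, N, noise_rate_sub) + 1L, 4),
                            rep(stats::qbinom(q, N, noise_rate_indel) + 1L, 5)),
                          each = L), L, 9)
  keep <- which(gain >= min_gain &
                supp >= min_count &
                supp / N >= min_support_fraction &
                supp / N <= max_support_fraction &
                gain >= min_mean_gain * pmax(supp, 1) &
                ndec / N >= min_decisive_fraction &
                sfrac >= min_support_fraction & sfrac <= max_support_fraction,
                arr.ind = TRUE)
  if (nrow(keep) == 0) {
    return(empty_variant_set())
  }
  sp <- sm <- integer(nrow(keep))
  if (!is.null(strand)) {
    plus <- strand == "+"
    for (v in seq_len(nrow(keep))) {
      supp_reads <- P[, keep[v, 1], keep[v, 2]] > 0
      sp[v] <- sum(supp_reads & plus)
      sm[v] <- sum(supp_reads & !plus)
    }
  }
  out <- data.frame(pos = keep[, 1],
                    edit = edit_names()[keep[, 2]],
                    gain = gain[keep],
                    support = supp[keep],
                    support_plus = sp,
                    support_minus = sm,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gain), , drop = FALSE]
  # one candidate per position; nearby equivalent indel candidates collapse
  # to the top-gain one (an insertion in a short run scores at every slot)
  kept <- integer(0)
  for (v in seq_len(nrow(out))) {
    clash <- FALSE
    for (w in kept) {
      if (out$pos[v] == out$pos[w] ||
          (substr(out$edit[v], 1, 3) %in% c("ins", "del") &&
           substr(out$edit[w], 1, 3) %in% c("ins", "del") &&
           abs(out$pos[v] - out$pos[w]) <= 2)) {
        clash <- TRUE
        break
      }
    }
    if (!clash) kept <- c(kept, v)
  }
  out <- out[kept, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_set", "data.frame")
  filter_variants(out, chunk = chunk, min_gain = min_gain,
                  both_strands_present = !is.null(strand) &&
                    length(unique(strand)) > 1, ...)
}

empty_variant_set <- function() {
  out <- data.frame(pos = integer(0), edit = character(0), gain = numeric(0),
                    support = integer(0), support_plus = integer(0),
                    support_minus = integer(0), stringsAsFactors = FALSE)
  class(out) <- c("variant_set", "data.frame")
  out
}

#' Homopolymer run length covering each position of a sequence
#' @param seq DNA string.
#' @return Integer vector, per-position length of the run containing it.
#' @export
homopolymer_runs <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  r <- rle(b)
  rep(r$lengths, r$lengths)
}

#' Filter unreliable candidate variants
#'
#' Discards candidates that (a) fall inside a homopolymer run of at least
#' `homopolymer_min` bases, (b) show strand bias (two-sided binomial test
#' among supporting reads at level `strand_alpha`, applied only when both
#' strands are present on the chunk), or (c) have gain below `min_gain`.
#'
#' @param candidates A `variant_set` data.frame.
#' @param chunk Chunk sequence (NULL skips the homopolymer filter).
#' @param homopolymer_min Minimum run length that disqualifies a position.
#' @param strand_alpha Two-sided binomial p-value threshold.
#' @param min_gain Minimum gain.
#' @param both_strands_present Whether the chunk has reads on both strands
#'   (the bias test is skipped otherwise).
#' @return The filtered `variant_set`.
#' @export
filter_variants <- function(candidates, chunk = NULL, homopolymer_min = 5L,
                            strand_alpha = 0.01, min_gain = 4.0,
                            both_strands_present = TRUE) {
  keep <- candidates$gain >= min_gain
  if (!is.null(chunk) && nrow(candidates) > 0) {
    runs <- homopolymer_runs(chunk)
    # an insertion before position i adjoins runs at i-1 and i
    run_at <- function(pos, edit) {
      if (startsWith(edit, "ins")) {
        max(runs[max(pos - 1, 1)], runs[pos])
      } else runs[pos]
    }
    hp <- mapply(run_at, candidates$pos, candidates$edit)
    keep <- keep & hp < homopolymer_min
  }
  if (both_strands_present && nrow(candidates) > 0 &&
      any(candidates$support_plus + candidates$support_minus > 0)) {
    pv <- mapply(function(sp, sm) {
      n <- sp + sm
      if (n == 0) return(1)
      stats::binom.test(sp, n, 0.5)$p.value
    }, candidates$support_plus, candidates$support_minus)
    keep <- keep & pv >= strand_alpha
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_set", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
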