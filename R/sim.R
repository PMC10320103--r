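#' Random DNA sequence
#' @param n Length in bp.
#' @return A character scalar over A/C/G/T.
#' @export
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement
#' @param seq DNA string.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca", vapply(seq, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Structural variant specification
#'
#' @param hap Haplotype carrying the variant, "A" or "B".
#' @param kind "insertion" or "deletion".
#' @param length Length in bp.
#' @param pos Optional 1-based position on the ancestral sequence
#'   (insertion point, or deletion start). Placed uniformly at random when
#'   NULL.
#' @return A list describing the SV.
#' @export
sv_spec <- function(hap, kind = c("insertion", "deletion"), length, pos = NULL) {
  kind <- match.arg(kind)
  stopifnot(hap %in% c("A", "B"), length >= 1)
  list(hap = hap, kind = kind, length = as.integer(length),
       pos = if (is.null(pos)) NA_integer_ else as.integer(pos))
}

#' Simulate a diploid genome with known truth
#'
#' Generates a random ancestral sequence and derives two haplotypes from it:
#' heterozygous SNVs are placed uniformly at the stated per-base divergence
#' (each assigned to one haplotype at random) and large insertions/deletions
#' are placed at the stated or random non-overlapping positions. The
#' returned ledgers fully determine each haplotype from the ancestral
#' sequence.
#'
#' @param ancestral_length Ancestral sequence length in bp.
#' @param divergence Heterozygous SNV rate per base, in [0, 0.05].
#' @param svs List of [sv_spec()] entries.
#' @param seed Integer seed.
#' @param end_margin SVs are rejected closer than this to a sequence end so
#'   that reads can span them; capped at a fifth of the ancestral length.
#' @return An object of class `diploid_truth`: list with `hapA`, `hapB`,
#'   `ancestral`, `snv_ledger` (hap, pos, ref, alt), `sv_ledger`
#'   (hap, pos, kind, length, seq), `seed`.
#' @export
make_diploid <- function(ancestral_length, divergence = 0.001, svs = list(),
                         seed = 1L, end_margin = 40000L) {
  if (divergence < 0 || divergence > 0.05) stop("divergence must be in [0, 0.05]")
  stopifnot(ancestral_length >= 1000)
  set.seed(seed)
  anc <- random_seq(ancestral_length)
  margin <- min(end_margin, ancestral_length %/% 5L)
  # ---- place SVs (ancestral footprint must not overlap) ----
  footprint <- function(sv) {
    if (sv$kind == "deletion") c(sv$pos, sv$pos + sv$length - 1L) else c(sv$pos, sv$pos)
  }
  placed <- list()
  taken <- matrix(numeric(0), ncol = 2)
  for (sv in svs) {
    if (!is.na(sv$pos)) {
      fp <- footprint(sv)
      if (fp[2] > ancestral_length) stop("SV extends past the ancestral sequence")
      if (nrow(taken) > 0 && any(fp[1] <= taken[, 2] & fp[2] >= taken[, 1]))
        stop(sprintf("overlapping SVs: %s at %d (length %d) collides with a placed SV",
                     sv$kind, sv$pos, sv$length))
      placed <- c(placed, list(sv))
      taken <- rbind(taken, fp)
      next
    }
    span <- if (sv$kind == "deletion") sv$length else 1L
    lo <- margin + 1L
    hi <- ancestral_length - margin - span + 1L
    if (hi < lo) stop("ancestral sequence too short to place SV away from the ends")
    ok <- FALSE
    for (try in 1:1000) {
      sv$pos <- sample(lo:hi, 1L)
      fp <- footprint(sv)
      if (nrow(taken) == 0 || !any(fp[1] <= taken[, 2] & fp[2] >= taken[, 1])) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place SVs without overlap; reduce sizes or count")
    placed <- c(placed, list(sv))
    taken <- rbind(taken, fp)
  }
  sv_ledger <- data.frame(
    hap = vapply(placed, `[[`, character(1), "hap"),
    pos = vapply(placed, `[[`, integer(1), "pos"),
    kind = vapply(placed, `[[`, character(1), "kind"),
    length = vapply(placed, `[[`, integer(1), "length"),
    seq = vapply(placed, function(sv)
      if (sv$kind == "insertion") random_seq(sv$length) else "", character(1)),
    stringsAsFactors = FALSE)
  # ---- place heterozygous SNVs (outside deletion footprints) ----
  n_snv <- rbinom(1, ancestral_length, divergence)
  avoid <- rep(FALSE, ancestral_length)
  del <- sv_ledger[sv_ledger$kind == "deletion", , drop = FALSE]
  for (i in seq_len(nrow(del))) avoid[del$pos[i]:(del$pos[i] + del$length[i] - 1L)] <- TRUE
  free_pos <- which(!avoid)
  n_snv <- min(n_snv, length(free_pos))
  pos <- sort(sample(free_pos, n_snv))
  anc_b <- strsplit(anc, "")[[1]]
  ref <- anc_b[pos]
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1), USE.NAMES = FALSE)
  hap_of <- sample(c("A", "B"), n_snv, replace = TRUE)
  snv_ledger <- data.frame(hap = hap_of, pos = pos, ref = ref, alt = alt,
                           stringsAsFactors = FALSE)
  build_hap <- function(h) {
    b <- anc_b
    sel <- snv_ledger$hap == h
    b[snv_ledger$pos[sel]] <- snv_ledger$alt[sel]
    s <- paste(b, collapse = "")
    svh <- sv_ledger[sv_ledger$hap == h, , drop = FALSE]
    svh <- svh[order(-svh$pos), , drop = FALSE]
    for (i in seq_len(nrow(svh))) {
      p <- svh$pos[i]
      if (svh$kind[i] == "insertion") {
        s <- paste0(substr(s, 1, p - 1L), svh$seq[i], substr(s, p, nchar(s)))
      } else {
        s <- paste0(substr(s, 1, p - 1L), substr(s, p + svh$length[i], nchar(s)))
      }
    }
    s
  }
  structure(list(hapA = build_hap("A"), hapB = build_hap("B"), ancestral = anc,
                 snv_ledger = snv_ledger, sv_ledger = sv_ledger, seed = seed),
            class = "diploid_truth")
}

#' Replay a haplotype from its ledgers
#'
#' Reconstructs a haplotype from the ancestral sequence by applying the SNV
#' and SV ledgers; the result must equal the stored haplotype.
#' @param truth A `diploid_truth`.
#' @param hap "A" or "B".
#' @return The reconstructed haplotype string.
#' @export
replay_haplotype <- function(truth, hap) {
  b <- strsplit(truth$ancestral, "")[[1]]
  sel <- truth$snv_ledger$hap == hap
  b[truth$snv_ledger$pos[sel]] <- truth$snv_ledger$alt[sel]
  s <- paste(b, collapse = "")
  svh <- truth$sv_ledger[truth$sv_ledger$hap == hap, , drop = FALSE]
  svh <- svh[order(-svh$pos), , drop = FALSE]
  for (i in seq_len(nrow(svh))) {
    p <- svh$pos[i]
    if (svh$kind[i] == "insertion") {
      s <- paste0(substr(s, 1, p - 1L), svh$seq[i], substr(s, p, nchar(s)))
    } else {
      s <- paste0(substr(s, 1, p - 1L), substr(s, p + svh$length[i], nchar(s)))
    }
  }
  s
}

#' @export
print.diploid_truth <- function(x, ...) {
  cat(sprintf("diploid truth: hapA %d bp, hapB %d bp, %d het SNVs, %d SVs (seed %d)\n",
              nchar(x$hapA), nchar(x$hapB), nrow(x$snv_ledger), nrow(x$sv_ledger),
              x$seed))
  invisible(x)
}

#' Copies of a template differing by a fixed number of edits
#'
#' Copy 1 is the random template; each subsequent copy differs from it by
#' exactly `edits_per_copy` randomly chosen single-base edits, and all
#' copies are pairwise distinct.
#'
#' @param template_length Template length in bp.
#' @param n_copies Number of copies (>= 2).
#' @param edits_per_copy Edits distinguishing each non-template copy (>= 1).
#' @param seed Integer seed.
#' @return List with `copies` (character vector) and `ledger`
#'   (data.frame copy, pos, edit).
#' @export
make_copies <- function(template_length, n_copies, edits_per_copy, seed = 1L) {
  if (n_copies < 2) stop("n_copies must be >= 2")
  if (edits_per_copy < 1) stop("edits_per_copy must be >= 1")
  if (template_length < 10 * edits_per_copy)
    stop("template too short to host the requested distinct edits")
  set.seed(seed)
  template <- random_seq(template_length)
  copies <- template
  ledger <- data.frame(copy = integer(0), pos = integer(0), edit = character(0),
                       stringsAsFactors = FALSE)
  for (cp in 2:n_copies) {
    for (try in 1:100) {
      s <- template
      rows <- list()
      for (k in seq_len(edits_per_copy)) {
        repeat {
          i <- sample(nchar(template), 1L)
          e <- sample(9L, 1L)
          if (apply_edit(template, i, e) != template) break
        }
        rows[[k]] <- data.frame(copy = cp, pos = i, edit = edit_names()[e],
                                stringsAsFactors = FALSE)
        s <- apply_edit(s, i, e)
      }
      if (!s %in% copies) break
    }
    if (s %in% copies) stop("could not generate pairwise distinct copies")
    copies <- c(copies, s)
    ledger <- rbind(ledger, do.call(rbind, rows))
  }
  list(copies = copies, ledger = ledger)
}

#' Read simulation model
#'
#' A self-contained i.i.d. error model: each emitted base mismatches,
#' gains a following insertion, or is deleted independently at the stated
#' per-base rates. Read lengths follow a log-normal by default, truncated
#' at `max_length` (a hard maximum) and at the source length; a "fixed"
#' family yields degenerate lengths. Reads are taken from either strand
#' with probability 1/2.
#'
#' @param mismatch_rate,insertion_rate,deletion_rate Per-base error rates.
#' @param length_distribution List: `family` ("lognormal" or "fixed") plus
#'   parameters (`meanlog`, `sdlog`, or `length`).
#' @param max_length Hard maximum read length in bp.
#' @param min_length Minimum read length in bp.
#' @param coverage Fold coverage per haplotype.
#' @return An object of class `sim_read_model`.
#' @export
sim_read_model <- function(mismatch_rate = 0.04, insertion_rate = 0.03,
                           deletion_rate = 0.03,
                           length_distribution = list(family = "lognormal",
                                                      meanlog = log(12000),
                                                      sdlog = 0.6),
                           max_length = 50000L, min_length = 500L,
                           coverage = 30) {
  rates <- c(mismatch_rate, insertion_rate, deletion_rate)
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 0.5)
    stop("error rates must be in [0, 1) and sum below 0.5")
  if (coverage <= 0) stop("coverage must be positive")
  structure(list(mismatch_rate = mismatch_rate, insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 length_distribution = length_distribution,
                 max_length = as.integer(max_length),
                 min_length = as.integer(min_length), coverage = coverage),
            class = "sim_read_model")
}

draw_length <- function(model, source_len) {
  ld <- model$length_distribution
  len <- switch(ld$family,
    lognormal = as.integer(round(rlnorm(1, ld$meanlog, ld$sdlog))),
    fixed = as.integer(ld$length),
    stop("unknown length distribution family: ", ld$family))
  max(model$min_length, min(len, model$max_length, source_len))
}

noisy_copy <- function(seq, model) {
  b <- utf8ToInt(seq)  # bytes of ACGT
  n <- length(b)
  bases <- utf8ToInt("ACGT")
  u <- runif(n)
  del <- u < model$deletion_rate
  mis <- !del & u < model$deletion_rate + model$mismatch_rate
  if (any(mis)) {
    # shift each mismatched base to one of the three others
    cur <- match(b[mis], bases)
    b[mis] <- bases[((cur - 1L + sample(3L, sum(mis), replace = TRUE)) %% 4L) + 1L]
  }
  ins <- runif(n) < model$insertion_rate
  if (any(ins) || any(del)) {
    keep <- !del
    pieces <- character(2)
    out <- b[keep]
    if (any(ins)) {
      # insert a random base after each flagged position (surviving or not)
      ipos <- which(ins)
      ibase <- bases[sample(4L, length(ipos), replace = TRUE)]
      # positions in the deletion-filtered sequence
      cum <- cumsum(keep)
      at <- cum[ipos]
      ord <- order(at)
      out <- insert_at(out, at[ord], ibase[ord])
    }
    b <- out
  }
  intToUtf8(b)
}

insert_at <- function(x, at, vals) {
  # insert vals[i] after position at[i] (0 allowed); at must be sorted
  res <- integer(length(x) + length(vals))
  idx <- seq_along(x) + findInterval(seq_along(x) - 0.5, at)
  res[idx] <- x
  res[setdiff(seq_along(res), idx)] <- vals
  res
}

#' Simulate noisy long reads with truth labels
#'
#' Emits reads per source sequence until the per-source base count reaches
#' `coverage * source length`. Each read records its source haplotype,
#' half-open truth interval on the source, and strand.
#'
#' @param truth A `diploid_truth`, or a named character vector of source
#'   sequences.
#' @param model A [sim_read_model()].
#' @param seed Integer seed.
#' @return A `sim_reads` data.frame: id, sequence, haplotype, start, end,
#'   strand.
#' @export
simulate_reads <- function(truth, model = sim_read_model(), seed = 1L) {
  sources <- if (inherits(truth, "diploid_truth")) {
    c(A = truth$hapA, B = truth$hapB)
  } else {
    if (is.null(names(truth))) names(truth) <- paste0("S", seq_along(truth))
    truth
  }
  if (length(sources) == 0 || any(nchar(sources) == 0)) stop("empty source sequence")
  set.seed(seed)
  out <- list()
  ctr <- 0L
  for (h in names(sources)) {
    src <- sources[[h]]
    slen <- nchar(src)
    target <- model$coverage * slen
    emitted <- 0
    while (emitted < target) {
      len <- draw_length(model, slen)
      start <- sample.int(slen - len + 1L, 1L) - 1L  # 0-based
      frag <- substr(src, start + 1L, start + len)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") frag <- revcomp(frag)
      sq <- noisy_copy(frag, model)
      ctr <- ctr + 1L
      out[[ctr]] <- data.frame(id = sprintf("r%05d_%s", ctr, h), sequence = sq,
                               haplotype = h, start = start, end = start + len,
                               strand = strand, stringsAsFactors = FALSE)
      emitted <- emitted + len
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("sim_reads", "data.frame")
  res
}
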