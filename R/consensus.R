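#' Polish a sequence against spanning read segments
#'
#' Iteratively computes the summed perturbation `Ps[i, e]` of the current
#' sequence over the segments, applies every positively supported edit in
#' order of decreasing gain while keeping applied edits at least `min_sep`
#' bases apart (interacting edits would invalidate each other's deltas),
#' and stops when no entry exceeds `tol` or after `max_rounds`.
#'
#' All segments must span the whole sequence (oriented the same way); this
#' is the consensus step for a chunk copy or a single polishing window.
#'
#' @param seq Sequence to polish.
#' @param segs Character vector of spanning, oriented read segments.
#' @param params A [pairhmm_params()].
#' @param band Band half-width for the pair-HMM.
#' @param max_rounds Maximum polishing rounds.
#' @param tol Positive-gain tolerance (nats).
#' @param min_sep Minimum distance between edits applied in one round.
#' @return List: `sequence`, `n_edits`, `rounds`, `converged`,
#'   `loglik_trace` (summed read log-likelihood before each round).
#' @export
polish_sequence <- function(seq, segs, params = pairhmm_params(), band = NULL,
                            max_rounds = 30L, tol = 0.5, min_sep = 8L) {
  n_edits <- 0L
  trace <- numeric(0)
  converged <- FALSE
  rounds <- 0L
  for (round in seq_len(max_rounds)) {
    rounds <- round
    sp <- summed_perturbation(seq, segs, params, band = band)
    trace <- c(trace, sum(sp$loglik))
    sel <- select_edits(sp$Ps, tol, min_sep)
    if (nrow(sel) == 0) {
      converged <- TRUE
      break
    }
    seq <- apply_edits(seq, sel)
    n_edits <- n_edits + nrow(sel)
  }
  if (!converged) {
    sp <- summed_perturbation(seq, segs, params, band = band)
    trace <- c(trace, sum(sp$loglik))
    converged <- nrow(select_edits(sp$Ps, tol, min_sep)) == 0
    if (!converged) warning("polishing did not converge within max_rounds")
  }
  list(sequence = seq, n_edits = n_edits, rounds = rounds, converged = converged,
       loglik_trace = trace)
}

# pick positive edits, best first, spaced >= min_sep apart; at most one per
# position
select_edits <- function(Ps, tol, min_sep) {
  pos_best <- apply(Ps, 1, which.max)
  val_best <- Ps[cbind(seq_len(nrow(Ps)), pos_best)]
  cand <- which(val_best > tol)
  if (length(cand) == 0)
    return(data.frame(pos = integer(0), edit = integer(0), gain = numeric(0)))
  cand <- cand[order(-val_best[cand])]
  kept <- integer(0)
  for (p in cand) {
    if (length(kept) == 0 || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  }
  data.frame(pos = kept, edit = pos_best[kept], gain = val_best[kept])
}

# apply edits right-to-left so earlier positions stay valid
apply_edits <- function(seq, sel) {
  sel <- sel[order(-sel$pos), , drop = FALSE]
  for (i in seq_len(nrow(sel))) seq <- apply_edit(seq, sel$pos[i], sel$edit[i])
  seq
}

#' Consensus of a chunk copy
#'
#' Polishes the raw chunk sequence against the read segments assigned to
#' one copy cluster, producing the copy's consensus (chunk self-errors are
#' corrected and copy-specific alleles introduced).
#'
#' @param chunk_seq Raw chunk sequence.
#' @param segs Oriented read segments of the copy's reads.
#' @param params A [pairhmm_params()].
#' @param band Pair-HMM band half-width.
#' @param max_rounds Maximum polishing rounds.
#' @return The consensus sequence.
#' @export
copy_consensus <- function(chunk_seq, segs, params = pairhmm_params(),
                           band = NULL, max_rounds = 10L) {
  if (length(segs) < 3) return(chunk_seq)
  polish_sequence(chunk_seq, segs, params, band = band,
                  max_rounds = max_rounds)$sequence
}

#' Assemble a draft sequence along a haplotype path
#'
#' Concatenates the (consensus) sequences of the path's nodes. The joint
#' between consecutive nodes is estimated from the reads supporting the
#' connecting edge: the median gap between the two chunk alignments on a
#' read. Negative gaps (overlaps) are trimmed from the next node; positive
#' gaps are filled with the spanning subsequence of the read whose gap is
#' closest to the median.
#'
#' @param path A `haplotype_path`.
#' @param graph The `copy_graph` (for edge read evidence).
#' @param node_seqs Named character vector/list of per-node sequences.
#' @param reads Read sequences (named) for anchor bookkeeping.
#' @return A `draft` list: `sequence`, `nodes` (node_id, orientation,
#'   start, end; 0-based half-open on the draft), `read_anchors`
#'   (read_id, draft_start, draft_end, read_start, read_end, rev),
#'   `label`.
#' @export
make_draft <- function(path, graph, node_seqs, reads = NULL) {
  rseq <- if (!is.null(reads)) read_seqs(reads) else NULL
  seqs <- character(nrow(path))
  starts <- integer(nrow(path))
  pieces <- character(0)
  cur_len <- 0L
  anchors <- list()
  for (t in seq_len(nrow(path))) {
    nid <- path$node_id[t]
    o <- path$orientation[t]
    ns <- node_seqs[[nid]]
    if (is.null(ns)) stop("missing node sequence for ", nid)
    if (o == "-") ns <- revcomp(ns)
    trim <- 0L
    if (t > 1) {
      # edge from previous node's exit side to this node's entry side
      prev <- path$node_id[t - 1]
      po <- path$orientation[t - 1]
      exit <- if (po == "+") "R" else "L"
      enter <- if (o == "+") "L" else "R"
      ek <- edge_key(prev, exit, nid, enter)
      ed <- graph$edge_data[[ek]]
      if (is.null(ed)) stop("consecutive path nodes share no edge: ", prev, " -> ", nid)
      g <- as.integer(round(median(ed$gaps)))
      if (g > 0) {
        pick <- which.min(abs(ed$gaps - g))
        fill <- ed$fills[pick]
        if (is.na(fill) || nchar(fill) == 0) {
          fill <- strrep("N", g)  # no sequence retained; placeholder
        }
        # orient the stored fill (canonical node1->node2 frame) to the path
        fwd_in_path <- side_key(prev, exit) <= side_key(nid, enter)
        if (!fwd_in_path) fill <- revcomp(fill)
        pieces <- c(pieces, fill)
        cur_len <- cur_len + nchar(fill)
      } else if (g < 0) {
        trim <- min(-g, nchar(ns) - 1L)
        ns <- substr(ns, trim + 1L, nchar(ns))
      }
    }
    starts[t] <- cur_len
    pieces <- c(pieces, ns)
    cur_len <- cur_len + nchar(ns)
    seqs[t] <- ns
    # read anchors for this node occurrence
    for (rid in unique(graph$node_reads[[nid]])) {
      al <- graph$aln_of[[paste0(nid, "|", rid)]]
      if (is.null(al)) next
      rl <- if (!is.null(rseq)) nchar(rseq[[rid]]) else NA_integer_
      rev <- (al$strand == "+") != (o == "+")
      if (rev && is.na(rl)) next
      rs <- if (rev) rl - al$read_end else al$read_start
      re <- if (rev) rl - al$read_start else al$read_end
      anchors[[length(anchors) + 1L]] <-
        data.frame(read_id = rid, draft_start = starts[t] - trim,
                   draft_end = cur_len, read_start = rs, read_end = re,
                   rev = rev, stringsAsFactors = FALSE)
    }
  }
  ra <- if (length(anchors)) do.call(rbind, anchors) else
    data.frame(read_id = character(0), draft_start = integer(0),
               draft_end = integer(0), read_start = integer(0),
               read_end = integer(0), rev = logical(0))
  # drop reads with inconsistent orientation across nodes (chimeric signal)
  if (nrow(ra)) {
    bad <- tapply(ra$rev, ra$read_id, function(v) length(unique(v)) > 1)
    ra <- ra[!(ra$read_id %in% names(bad)[bad]), , drop = FALSE]
  }
  structure(list(sequence = paste(pieces, collapse = ""),
                 nodes = data.frame(node_id = path$node_id,
                                    orientation = path$orientation,
                                    start = starts,
                                    end = starts + nchar(seqs),
                                    stringsAsFactors = FALSE),
                 read_anchors = ra,
                 label = attr(path, "label") %||% "haplotype_phased"),
            class = "draft")
}

# piecewise-linear draft -> oriented-read coordinate map for one read
anchor_map <- function(ra_read) {
  dx <- c(ra_read$draft_start, ra_read$draft_end)
  rx <- c(ra_read$read_start, ra_read$read_end)
  o <- order(dx)
  dx <- dx[o]
  rx <- rx[o]
  keep <- !duplicated(dx)
  list(dx = dx[keep], rx = rx[keep])
}

map_draft_to_read <- function(am, x) {
  # linear interpolation with slope-1 extrapolation
  if (length(am$dx) == 1) return(am$rx + (x - am$dx))
  i <- findInterval(x, am$dx)
  ifelse(i == 0, am$rx[1] + (x - am$dx[1]),
    ifelse(i >= length(am$dx), am$rx[length(am$rx)] + (x - am$dx[length(am$dx)]),
      {
        i2 <- pmax(pmin(i, length(am$dx) - 1L), 1L)
        f <- (x - am$dx[i2]) / pmax(am$dx[i2 + 1L] - am$dx[i2], 1)
        am$rx[i2] + f * (am$rx[i2 + 1L] - am$rx[i2])
      }))
}

#' Polish a draft into a contig
#'
#' Computes the summed perturbation of the draft over its reads in
#' overlapping windows (a stride-sized tile plus context on both sides;
#' reads are assigned to windows through the draft-to-read anchor map) and
#' applies every positively supported edit per tile and round, edits
#' spaced at least `min_sep` bases apart. Rounds continue until no edit is
#' applied or `max_rounds` is reached; tiles untouched in a round are not
#' recomputed in the next unless a neighbor changed.
#'
#' @param draft A `draft` from [make_draft()], or a bare sequence (then
#'   `reads` must all span it and no windowing is used).
#' @param reads Named character vector of read sequences (forward frame).
#' @param params A [pairhmm_params()].
#' @param window Window length in bp (tile `stride` + context).
#' @param stride Tile length in bp.
#' @param band Pair-HMM band half-width within windows.
#' @param max_rounds Maximum rounds.
#' @param tol Positive-gain tolerance (nats).
#' @param min_sep Minimum edit spacing within a round.
#' @param pad Extra read bases taken on each side of a mapped window.
#' @param reach How far (bp) beyond a read's anchored span its coordinate
#'   map may be extrapolated; lets reads polish gap fills adjacent to
#'   their last anchored chunk.
#' @param min_reads Minimum spanning reads to polish a tile.
#' @param max_reads Windows deeper than this use only the first `max_reads`
#'   spanning reads (consensus accuracy saturates well below typical
#'   depth).
#' @return A `contig` list: `sequence`, `label`, `n_edits`, `rounds`,
#'   `converged`.
#' @export
polish <- function(draft, reads, params = pairhmm_params(), window = 2000L,
                   stride = 1000L, band = 80L, max_rounds = 30L, tol = 0.5,
                   min_sep = 8L, pad = 40L, reach = 2500L, min_reads = 3L,
                   max_reads = 24L) {
  if (is.character(draft)) {
    res <- polish_sequence(draft, read_seqs(reads), params, band = band,
                           max_rounds = max_rounds, tol = tol, min_sep = min_sep)
    return(structure(list(sequence = res$sequence, label = "haplotype_phased",
                          n_edits = res$n_edits, rounds = res$rounds,
                          converged = res$converged), class = "contig"))
  }
  rseq <- read_seqs(reads)
  seq <- draft$sequence
  ra <- draft$read_anchors
  ra <- ra[ra$read_id %in% names(rseq), , drop = FALSE]
  # oriented read cache
  rids <- unique(ra$read_id)
  oriented <- setNames(vector("list", length(rids)), rids)
  for (rid in rids) {
    rv <- ra$rev[ra$read_id == rid][1]
    oriented[[rid]] <- if (rv) revcomp(rseq[[rid]]) else rseq[[rid]]
  }
  maps <- lapply(setNames(rids, rids), function(rid)
    anchor_map(ra[ra$read_id == rid, , drop = FALSE]))
  spans <- lapply(setNames(rids, rids), function(rid) {
    rr <- ra[ra$read_id == rid, ]
    c(min(rr$draft_start), max(rr$draft_end))
  })
  ctx <- max(0L, (window - stride) %/% 2L)
  n_edits <- 0L
  rounds <- 0L
  converged <- FALSE
  n_tiles <- max(1L, ceiling(nchar(seq) / stride))
  active <- rep(TRUE, n_tiles)
  for (round in seq_len(max_rounds)) {
    rounds <- round
    edited <- rep(FALSE, n_tiles)
    shift_total <- 0L
    len <- nchar(seq)
    tile_bounds <- pmin(0:n_tiles * stride, len)
    for (ti in seq_len(n_tiles)) {
      if (!active[ti]) next
      a <- tile_bounds[ti] + shift_total
      b <- min(tile_bounds[ti + 1] + shift_total, nchar(seq))
      if (b <= a) next
      ws <- max(0L, a - ctx)
      we <- min(nchar(seq), b + ctx)
      wseq <- substr(seq, ws + 1L, we)
      at_start <- ws == 0L
      at_end <- we == nchar(seq)
      segs <- character(0)
      for (rid in rids) {
        sp <- spans[[rid]]
        if (sp[1] > ws + reach || sp[2] < we - reach) next
        rl <- nchar(oriented[[rid]])
        # no pad at the draft's own ends: overhanging read bases there
        # would masquerade as insertions at the window edge
        rs <- floor(map_draft_to_read(maps[[rid]], ws) - if (at_start) 0L else pad)
        re <- ceiling(map_draft_to_read(maps[[rid]], we) + if (at_end) 0L else pad)
        # the read must extend past the window on both sides (except at
        # the draft's own ends), or its global alignment would misfit
        if (rs < 0 && !at_start) next
        if (re > rl && !at_end) next
        rs <- max(0L, rs)
        re <- min(rl, re)
        if (re - rs < 0.5 * (we - ws)) next
        segs <- c(segs, substr(oriented[[rid]], rs + 1L, re))
        if (length(segs) >= max_reads) break
      }
      if (length(segs) < min_reads) next
      sp <- summed_perturbation(wseq, segs, params, band = band)
      sel <- select_edits(sp$Ps, tol, min_sep)
      # only apply edits inside the tile (window positions are 1-based),
      # guarding a few bases at exposed window edges
      lo_ok <- max(a - ws, if (a == ws) min_sep else 0)
      hi_ok <- (b - ws) - (if (b == we) min_sep else 0)
      sel <- sel[sel$pos > lo_ok & sel$pos <= hi_ok, , drop = FALSE]
      if (nrow(sel) == 0) next
      sel$pos <- sel$pos + ws  # absolute draft positions (1-based)
      seq <- apply_edits(seq, sel)
      delta <- sum(sel$edit >= 5 & sel$edit <= 8) - sum(sel$edit == 9)
      n_edits <- n_edits + nrow(sel)
      edited[ti] <- TRUE
      if (delta != 0) {
        # shift anchors and spans beyond this tile
        thr <- b
        for (rid in rids) {
          mv <- maps[[rid]]$dx >= thr
          maps[[rid]]$dx[mv] <- maps[[rid]]$dx[mv] + delta
          if (spans[[rid]][1] >= thr) spans[[rid]][1] <- spans[[rid]][1] + delta
          if (spans[[rid]][2] >= thr) spans[[rid]][2] <- spans[[rid]][2] + delta
        }
        shift_total <- shift_total + delta
      }
    }
    if (!any(edited)) {
      converged <- TRUE
      break
    }
    active <- edited | c(edited[-1], FALSE) | c(FALSE, edited[-n_tiles])
  }
  structure(list(sequence = seq, label = draft$label, n_edits = n_edits,
                 rounds = rounds, converged = converged), class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("contig (%s): %d bp, %d edits in %d polishing rounds%s\n",
              x$label, nchar(x$sequence), x$n_edits, x$rounds,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
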