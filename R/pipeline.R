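#' Deterministic sub-seed from a master seed and a stage tag
#'
#' @param master Integer master seed.
#' @param tag Stage name.
#' @return An integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, tag) {
  h <- as.numeric(master) %% 2147483647
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

#' Pipeline configuration
#'
#' Defaults follow the method's stated operating point: 2000-bp chunks,
#' chunk-to-read alignment at up to 20% error, sampler length `2000 * n`
#' moves, and polishing by positively supported perturbation edits.
#'
#' @param chunk_length Chunk length L in bp.
#' @param haploid_coverage Genome-wide haploid coverage; estimated from the
#'   alignments when NULL.
#' @param max_align_error Chunk-to-read alignment error ceiling.
#' @param params Pair-HMM parameters ([pairhmm_params()]).
#' @param band Pair-HMM band half-width used on chunks and windows.
#' @param t_multiplier Sampler iterations per read (T = t_multiplier * n).
#' @param restarts Sampler restarts.
#' @param min_edge_support Minimum reads per graph edge.
#' @param resolve_ratio Straight-to-crossing ratio for homozygous
#'   resolution.
#' @param polish_max_rounds Maximum polishing rounds.
#' @param window,stride Polishing window and tile sizes in bp.
#' @param target_span Haploid target span in bp; estimated from total read
#'   bases / (2 * haploid coverage) when NULL.
#' @param min_chunk_reads Chunks with fewer aligned reads are dropped.
#' @param min_contig_length Phased paths yielding contigs shorter than this
#'   are labeled "fragment" (assembly debris at region ends).
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(chunk_length = 2000L, haploid_coverage = NULL,
                            max_align_error = 0.20, params = pairhmm_params(),
                            band = 64L, t_multiplier = 2000L, restarts = 4L,
                            min_edge_support = 2L, resolve_ratio = 3,
                            polish_max_rounds = 30L, window = 2000L,
                            stride = 1000L, target_span = NULL,
                            min_chunk_reads = 4L,
                            min_contig_length = 3L * chunk_length, seed = 1L) {
  structure(list(chunk_length = as.integer(chunk_length),
                 haploid_coverage = haploid_coverage,
                 max_align_error = max_align_error, params = params,
                 band = as.integer(band), t_multiplier = t_multiplier,
                 restarts = as.integer(restarts),
                 min_edge_support = as.integer(min_edge_support),
                 resolve_ratio = resolve_ratio,
                 polish_max_rounds = as.integer(polish_max_rounds),
                 window = as.integer(window), stride = as.integer(stride),
                 target_span = target_span,
                 min_chunk_reads = as.integer(min_chunk_reads),
                 min_contig_length = as.integer(min_contig_length),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Oriented read segment of a chunk alignment
#'
#' @param rseq Named read sequences.
#' @param al One row (or rows) of a `chunk_alignments` data.frame.
#' @return Character vector of segments in chunk-forward orientation.
#' @export
aligned_segments <- function(rseq, al) {
  seg <- substr(rseq[al$read_id], al$read_start + 1L, al$read_end)
  flip <- al$strand == "-"
  seg[flip] <- revcomp(seg[flip])
  seg
}

#' Run the full assembly pipeline
#'
#' Chunk sampling, chunk-to-read alignment, copy-number estimation and
#' refinement, perturbation-matrix variant discovery, stochastic read
#' clustering with neighbor correction, copy-graph construction,
#' homozygous-region resolution, per-copy consensus, drafting, and
#' polishing. Fully deterministic given the master seed.
#'
#' @param reads A `sim_reads` data.frame, named character vector, or path
#'   to a FASTA/FASTQ file.
#' @param config A [pipeline_config()].
#' @return A list: `contigs` (data.frame id, sequence, label, length),
#'   `paths`, `graph`, `clusterings`, `copy_numbers`, `alignments`,
#'   `chunks`, `config`.
#' @export
run_pipeline <- function(reads, config = pipeline_config()) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_sequences(reads)
  rseq <- read_seqs(reads)
  total_bases <- sum(nchar(rseq))
  hc <- config$haploid_coverage
  span <- config$target_span
  if (is.null(span)) {
    if (is.null(hc)) stop("either haploid_coverage or target_span is required")
    span <- round(total_bases / (2 * hc))
  }
  log_stage("input", "%d reads, %.1f Mb, target span %.0f kb", length(rseq),
            total_bases / 1e6, span / 1000)
  ## 1. chunks
  chunks <- sample_chunks(reads, L = config$chunk_length, target_span = span,
                          seed = derive_seed(config$seed, "chunks"))
  log_stage("chunks", "%d chunks of %d bp", nrow(chunks), config$chunk_length)
  ## 2. alignment
  aligns <- align_chunks_to_reads(chunks, reads, max_error = config$max_align_error)
  log_stage("align", "%d chunk-read alignments", nrow(aligns))
  if (is.null(hc)) {
    hc <- estimate_haploid_coverage(aligns)
    log_stage("align", "estimated haploid coverage %.1f", hc)
  }
  ## 3. copy numbers
  cnt <- table(aligns$chunk_id)
  counts <- setNames(as.integer(cnt[chunks$chunk_id]), chunks$chunk_id)
  counts[is.na(counts)] <- 0L
  raw <- setNames(estimate_copy_number_raw(counts, hc), chunks$chunk_id)
  adj <- chunk_adjacency(aligns)
  cn <- refine_copy_numbers(raw, adj)
  keep <- names(cn)[cn >= 1 & counts[names(cn)] >= config$min_chunk_reads]
  log_stage("copy-number", "%d chunks kept; copy numbers: %s", length(keep),
            paste(names(table(cn[keep])), table(cn[keep]), sep = "x",
                  collapse = ", "))
  aligns <- aligns[aligns$chunk_id %in% keep, , drop = FALSE]
  chunk_seq <- setNames(chunks$sequence, chunks$chunk_id)
  ## 4. perturbation + clustering per chunk; the perturbation matrix also
  ## warm-starts the per-copy consensus (its column sums over a copy's
  ## reads are that copy's first polishing round)
  clusterings <- list()
  chunk_segs <- list()
  warm <- list()
  for (cid in keep) {
    al <- aligns[aligns$chunk_id == cid, , drop = FALSE]
    al <- al[!duplicated(al$read_id), , drop = FALSE]  # one segment per read
    segs <- aligned_segments(rseq, al)
    names(segs) <- al$read_id
    ## the chunk is a raw read subsequence (~read error rate); polish it
    ## over all its reads first so variant calling sees a clean reference
    cons <- suppressWarnings(
      copy_consensus(chunk_seq[[cid]], head(segs, 30L), config$params,
                     band = config$band, max_rounds = 6L))
    chunk_seq[[cid]] <- cons
    P <- suppressWarnings(
      perturbation_matrix(cons, segs, config$params, band = config$band))
    U <- if (dim(P)[1] >= 4) {
      collect_variants(P, strand = al$strand[match(rownames(P), al$read_id)])
    } else empty_variant_set()
    K <- min(cn[[cid]], dim(P)[1])
    cl <- cluster_reads(P, U, K = max(K, 1L),
                        clustering_config(restarts = config$restarts,
                                          seed = derive_seed(config$seed,
                                                             paste0("cl_", cid))))
    cl$chunk_id <- cid
    cl$n_variants <- nrow(U)
    clusterings[[cid]] <- cl
    chunk_segs[[cid]] <- segs
    for (k in sort(unique(cl$assignment))) {
      mem <- names(cl$assignment)[cl$assignment == k]
      mem <- intersect(mem, rownames(P))
      s <- chunk_seq[[cid]]
      if (length(mem) >= 3) {
        Ps <- matrix(colSums(P[mem, , , drop = FALSE]), dim(P)[2], 9)
        sel <- select_edits(Ps, 1e-6, 8L)
        if (nrow(sel)) s <- apply_edits(s, sel)
      }
      warm[[node_name(cid, k)]] <- s
    }
  }
  nvar <- vapply(clusterings, function(x) x$n_variants, numeric(1))
  log_stage("cluster", "%d/%d chunks separated (median %d variants)",
            sum(vapply(clusterings, function(x) x$K > 1 && x$n_variants > 0,
                       logical(1))), length(keep), as.integer(median(nvar)))
  ## 5. neighbor correction
  clusterings <- correct_with_neighbors(clusterings, aligns)
  ## 6. copy consensus (continues from the warm-started sequences)
  node_seqs <- list()
  for (cid in keep) {
    cl <- clusterings[[cid]]
    segs <- chunk_segs[[cid]]
    for (k in sort(unique(cl$assignment))) {
      mem <- names(cl$assignment)[cl$assignment == k]
      nid <- node_name(cid, k)
      start <- warm[[nid]] %||% chunk_seq[[cid]]
      node_seqs[[nid]] <-
        copy_consensus(start, segs[intersect(mem, names(segs))],
                       config$params, band = config$band)
    }
  }
  log_stage("consensus", "%d copy consensus sequences", length(node_seqs))
  ## 7. graph
  graph <- build_graph(clusterings, aligns,
                       min_edge_support = config$min_edge_support,
                       reads = reads, copy_numbers = cn)
  graph <- simplify_graph(graph)
  log_stage("graph", "%d nodes, %d edges", nrow(graph$nodes), nrow(graph$edges))
  graph <- resolve_homozygous(graph, resolve_ratio = config$resolve_ratio,
                              min_span = config$min_edge_support)
  ## duplicated homozygous nodes reuse their chunk's consensus
  for (nid in graph$nodes$node_id) {
    if (is.null(node_seqs[[nid]])) {
      base <- sub("[ab]$", "", nid)
      node_seqs[[nid]] <- node_seqs[[base]]
    }
  }
  ## 8. paths, drafts, polish
  paths <- extract_paths(graph)
  log_stage("paths", "%d paths (%d multicopy)", length(paths),
            sum(vapply(paths, function(p) attr(p, "label") == "multicopy",
                       logical(1))))
  contigs <- list()
  drafts <- list()
  for (pi in seq_along(paths)) {
    draft <- make_draft(paths[[pi]], graph, node_seqs, reads = reads)
    drafts[[pi]] <- draft
    ctg <- polish(draft, reads, config$params, window = config$window,
                  stride = config$stride, band = max(config$band, 80L),
                  max_rounds = config$polish_max_rounds)
    log_stage("polish", "path %d: %d bp, %d edits, %d rounds", pi,
              nchar(ctg$sequence), ctg$n_edits, ctg$rounds)
    lab <- ctg$label
    if (lab == "haplotype_phased" && nchar(ctg$sequence) < config$min_contig_length)
      lab <- "fragment"
    contigs[[pi]] <- data.frame(id = sprintf("ctg%03d", pi),
                                sequence = ctg$sequence, label = lab,
                                length = nchar(ctg$sequence),
                                n_nodes = nrow(paths[[pi]]),
                                stringsAsFactors = FALSE)
  }
  cdf <- if (length(contigs)) do.call(rbind, contigs) else
    data.frame(id = character(0), sequence = character(0), label = character(0),
               length = integer(0), n_nodes = integer(0))
  ## order by size, phased first
  cdf <- cdf[order(cdf$label != "haplotype_phased", -cdf$length), , drop = FALSE]
  rownames(cdf) <- NULL
  log_stage("done", "%d phased contigs, %d multicopy",
            sum(cdf$label == "haplotype_phased"),
            sum(cdf$label == "multicopy"))
  list(contigs = cdf, paths = paths, graph = graph, clusterings = clusterings,
       copy_numbers = cn, alignments = aligns, chunks = chunks,
       node_seqs = node_seqs, drafts = drafts, config = config)
}
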