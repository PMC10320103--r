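#' Read sequences from FASTA or FASTQ
#'
#' @param path File path (.fa/.fasta/.fq/.fastq, optionally gzipped).
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  fq <- grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE)
  x <- if (fq) Biostrings::readDNAStringSet(path, format = "fastq")
       else Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector, or a contigs data.frame (columns
#'   id, sequence, and optionally label, n_nodes appended to headers).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "data.frame")) {
    nm <- seqs$id
    if (!is.null(seqs$label)) nm <- paste0(nm, " label=", seqs$label)
    seqs <- setNames(seqs$sequence, nm)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write reads as FASTQ with uniform placeholder qualities
#'
#' @param reads A `sim_reads` data.frame or named character vector.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  seqs <- read_seqs(reads)
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write the read truth ledger as TSV
#'
#' Columns: read_id, haplotype, start, end, strand (0-based half-open).
#' @param reads A `sim_reads` data.frame.
#' @param path Output path.
#' @export
write_truth_tsv <- function(reads, path) {
  write.table(reads[, c("id", "haplotype", "start", "end", "strand")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("read_id", "haplotype", "start", "end", "strand"))
  invisible(path)
}

#' Write chunk alignments as PAF
#'
#' Standard 12 mandatory columns with the edit distance as an NM:i tag;
#' the chunk is the query.
#'
#' @param alignments A `chunk_alignments` data.frame.
#' @param chunks A `chunk_set` (for query lengths).
#' @param reads Read sequences (for target lengths).
#' @param path Output path.
#' @export
write_paf <- function(alignments, chunks, reads, path) {
  cl <- setNames(nchar(chunks$sequence), chunks$chunk_id)
  rseq <- read_seqs(reads)
  rl <- nchar(rseq)
  alen <- alignments$read_end - alignments$read_start
  matches <- pmax(alen - alignments$edit_distance, 0L)
  lines <- paste(alignments$chunk_id, cl[alignments$chunk_id], 0L,
                 cl[alignments$chunk_id], alignments$strand,
                 alignments$read_id, rl[alignments$read_id],
                 alignments$read_start, alignments$read_end,
                 matches, alen, 255L,
                 paste0("NM:i:", alignments$edit_distance), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a clustering as TSV (chunk_id, read_id, cluster_index)
#' @param clusterings Named list of `read_clustering`.
#' @param path Output path.
#' @export
write_clusters_tsv <- function(clusterings, path) {
  rows <- do.call(rbind, lapply(clusterings, function(cl)
    data.frame(chunk_id = cl$chunk_id %||% NA_character_,
               read_id = names(cl$assignment),
               cluster_index = unname(cl$assignment),
               stringsAsFactors = FALSE)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the assembly as GFA 1.0
#'
#' S-lines carry node (or contig) sequences, L-lines the copy-graph edges
#' with orientations, and P-lines the haplotype paths.
#'
#' @param result A [run_pipeline()] result.
#' @param path Output path.
#' @param node_seqs Optional named node sequences for S-lines; contig
#'   records are written as P-lines over node ids.
#' @export
write_gfa <- function(result, path, node_seqs = NULL) {
  g <- result$graph
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (nid in g$nodes$node_id) {
    s <- if (!is.null(node_seqs)) node_seqs[[nid]] else NULL
    writeLines(sprintf("S\t%s\t%s", nid, s %||% "*"), con)
  }
  if (nrow(g$edges)) {
    for (i in seq_len(nrow(g$edges))) {
      e <- g$edges[i, ]
      # L-line orientation: leaving node1 via end1 ('R' means forward)
      o1 <- if (e$end1 == "R") "+" else "-"
      o2 <- if (e$end2 == "L") "+" else "-"
      writeLines(sprintf("L\t%s\t%s\t%s\t%s\t0M\tRC:i:%d", e$node1, o1,
                         e$node2, o2, e$support), con)
    }
  }
  for (pi in seq_along(result$paths)) {
    p <- result$paths[[pi]]
    writeLines(sprintf("P\tctg%03d\t%s\t*", pi,
                       paste0(p$node_id, ifelse(p$orientation == "+", "+", "-"),
                              collapse = ",")), con)
  }
  invisible(path)
}

#' Write pipeline outputs to a directory
#'
#' Contigs as FASTA (label and path length in headers), the copy graph as
#' GFA, chunk alignments as PAF, clusterings as TSV, and a JSON run
#' manifest (config and seed).
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if missing).
#' @param reads The reads used (for PAF target lengths); optional.
#' @return `out_dir`, invisibly.
#' @export
save_assembly <- function(result, out_dir, reads = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(result$contigs, file.path(out_dir, "contigs.fasta"))
  write_gfa(result, file.path(out_dir, "assembly.gfa"))
  write_clusters_tsv(result$clusterings, file.path(out_dir, "clusters.tsv"))
  if (!is.null(reads))
    write_paf(result$alignments, result$chunks, reads,
              file.path(out_dir, "chunk_alignments.paf"))
  cfg <- result$config
  cfg$params <- unclass(cfg$params)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(out_dir)
}

#' Write a perturbation matrix as a tabular sidecar
#'
#' Long-format TSV (read_id, pos, edit, delta) of all non-zero entries;
#' intended for debugging chunk separation.
#'
#' @param P A [perturbation_matrix()].
#' @param path Output path (".gz" gives a compressed file).
#' @export
write_perturbation_tsv <- function(P, path) {
  N <- dim(P)[1]
  L <- dim(P)[2]
  df <- data.frame(read_id = rep(dimnames(P)[[1]], L * 9),
                   pos = rep(rep(seq_len(L), each = N), 9),
                   edit = rep(edit_names(), each = N * L),
                   delta = as.vector(P), stringsAsFactors = FALSE)
  df <- df[df$delta != 0, , drop = FALSE]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a variant set as TSV
#' @param U A `variant_set`.
#' @param path Output path.
#' @export
write_variants_tsv <- function(U, path) {
  write.table(U, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
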