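#' Assemble reads into contigs with tandem-repeat restoration
#'
#' Runs the full pipeline: k-mer counting, graph construction, error cleaning
#' (low-weight edges, tips, bubbles), coverage normalization of edge weights
#' into per-genome copy numbers, tandem-loop balancing, and weight-consuming
#' traversal.
#'
#' Normalization multiplies each weight by p and rounds half-up. In the
#' error-free model p = G/(N(L-k+1)); here p is computed as
#' (strands x G) / (total cleaned edge weight), which equals the model value
#' on error-free input (the cleaned total weight is then exactly N(L-k+1)
#' per strand) and stays correct when substitution errors have removed a
#' fraction of the read k-mers. In double-strand mode the graph carries both
#' genome strands, hence the factor 2.
#'
#' @param reads a [read_set()] or character vector of read sequences.
#' @param reads2 optional second read collection (mates); unitig mode uses
#'   pairing for nothing except pooling the sequences.
#' @param k graph dimension (default 55 for 100-bp reads).
#' @param genome_size known genome length G; `NULL` to estimate from the
#'   distinct k-mer count (biased low for repeat-dense references).
#' @param low_weight_cutoff error-edge cutoff; `NULL` chooses
#'   `max(2, round(0.1 * single-copy modal weight))` from the weight spectrum.
#' @param single_strand if `TRUE`, do not add reverse-complement k-mers.
#' @param normalize run coverage normalization (default `TRUE`).
#' @param resolve_repeats run tandem-loop balancing (default `TRUE`).
#' @param tip_length,tip_ratio,bubble_length cleaning parameters, see
#'   [remove_tips()] and [remove_bubbles()].
#' @param min_coverage coverage below which normalization warns that the
#'   repeat model is outside its regime (default 100).
#' @param clean run tip/bubble/low-weight cleaning (default `TRUE`; the
#'   worked examples switch it off).
#' @param max_return_depth bound on return-path / loop-branch length in
#'   edges, see [simple_return_path()].
#' @return an [assembly_result()] with extra elements: `graph` (final graph),
#'   `genome_size`, `p`, `cutoff`, `coverage`, `loop_report`.
#' @export
assemble <- function(reads, reads2 = NULL, k = 55L, genome_size = NULL,
                     low_weight_cutoff = NULL, single_strand = FALSE,
                     normalize = TRUE, resolve_repeats = TRUE,
                     tip_length = NULL, tip_ratio = 0.2,
                     bubble_length = NULL, min_coverage = 100,
                     clean = TRUE, max_return_depth = 1000L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  if (!is.null(reads2)) {
    seqs <- c(seqs, if (is.data.frame(reads2)) reads2$sequence else as.character(reads2))
  }
  total_bases <- sum(nchar(seqs))
  tab <- count_kmers(seqs, k, single_strand = single_strand)
  cutoff <- low_weight_cutoff
  if (clean) {
    if (is.null(cutoff)) {
      cutoff <- max(2, round_half_up(0.1 * weight_spectrum_mode(tab$counts)))
    }
    # pre-filter the table: identical to remove_low_weight_edges on the full
    # graph, but avoids materializing millions of weight-1 error edges
    tab$counts <- tab$counts[tab$counts >= cutoff]
    if (length(tab$counts) == 0) stop("no k-mer reaches the weight cutoff")
    g <- build_graph(tab)
    g <- remove_low_weight_edges(g, cutoff)
    g <- remove_tips(g, tip_length, tip_ratio)
    g <- remove_bubbles(g, bubble_length)
  } else {
    g <- build_graph(tab)
    if (is.null(cutoff)) cutoff <- 0
  }
  if (n_edges(g) == 0) stop("graph empty after cleaning; cutoff too high?")

  G <- if (!is.null(genome_size)) genome_size
       else estimate_genome_size(g, single_strand)
  coverage <- total_bases / G
  p <- NA_real_
  if (normalize) {
    if (coverage < min_coverage) {
      warning(sprintf(paste0("observed coverage %.1fx is below %gx; the ",
                             "repeat copy-number model needs high coverage - ",
                             "normalizing anyway"), coverage, min_coverage))
    }
    strands <- if (single_strand) 1 else 2
    p <- strands * G / total_weight(g)
    g <- normalize_graph(g, p)
    if (n_edges(g) == 0) stop("graph empty after normalization")
  }
  loop_report <- NULL
  if (resolve_repeats) {
    g <- resolve_all(g)
    loop_report <- attr(g, "loop_report")
  }
  res <- generate_contigs(g, max_return_depth)
  if (!single_strand) res$contigs <- drop_rc_duplicates(res$contigs)
  res <- assembly_result(res$contigs)
  res$graph <- g
  res$genome_size <- G
  res$p <- p
  res$cutoff <- cutoff
  res$coverage <- coverage
  res$loop_report <- loop_report
  res
}

# drop contigs equal to the reverse complement (or duplicate) of an earlier one
drop_rc_duplicates <- function(contigs) {
  keep <- logical(length(contigs))
  seen <- character(0)
  for (i in seq_along(contigs)) {
    if (!(contigs[i] %in% seen)) {
      keep[i] <- TRUE
      seen <- c(seen, contigs[i], revcomp(contigs[i]))
    }
  }
  contigs[keep]
}

#' Assembly summary line
#'
#' Contig count, N50 and longest length, counting only contigs of at least
#' `min_contig_length` bases (a reporting filter: the contig set itself is
#' never trimmed).
#'
#' @param result an [assembly_result()].
#' @param min_contig_length reporting threshold in bases (default 0).
#' @return named list with `n_contigs`, `n50`, `longest`.
#' @export
assembly_summary <- function(result, min_contig_length = 0) {
  longs <- result$contigs[nchar(result$contigs) >= min_contig_length]
  s <- assembly_result(longs)
  list(n_contigs = s$n_contigs, n50 = s$n50, longest = s$longest)
}
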