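#' Extract overlapping k-mers from a read
#'
#' A read of length L yields the L - k + 1 overlapping substrings of length k,
#' left to right; reads shorter than k yield none.
#'
#' @param read a single DNA string.
#' @param k k-mer length (>= 2).
#' @return character vector of k-mers in order.
#' @export
extract_kmers <- function(read, k) {
  if (k < 2) stop("k must be >= 2")
  L <- nchar(read)
  if (L < k) return(character())
  substring(read, 1:(L - k + 1), k:L)
}

# Split sequences at N into N-free fragments (fragments < k are useless and
# dropped by extraction anyway).
split_at_n <- function(seqs) {
  has_n <- grepl("N", seqs, fixed = TRUE)
  if (!any(has_n)) return(seqs)
  c(seqs[!has_n], unlist(strsplit(seqs[has_n], "N+"), use.names = FALSE))
}

#' Count k-mers over a read set
#'
#' In double-strand mode (`single_strand = FALSE`) each read contributes the
#' k-mers of its sequence and of its reverse complement, so the resulting
#' graph represents both genome strands. Reads containing N are split at the
#' N positions first.
#'
#' @param reads a [read_set()] or a character vector of sequences.
#' @param k k-mer length.
#' @param single_strand if `TRUE`, count only the given orientation.
#' @return object of class `kmer_table`: list with `k` and `counts`
#'   (named integer vector, names are k-mers, sorted).
#' @export
count_kmers <- function(reads, k, single_strand = FALSE) {
  if (k < 2) stop("k must be >= 2")
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  if (length(seqs) == 0) stop("empty read set")
  seqs <- split_at_n(seqs)
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0) {
    stop("no read (or N-free read fragment) of length >= k = ", k,
         "; cannot build a k-mer table")
  }
  if (!single_strand) seqs <- c(seqs, revcomp(seqs))
  # vectorize over offsets: reads mostly share one length, so group by length
  lens <- nchar(seqs)
  pieces <- vector("list", 0L)
  for (L in sort(unique(lens))) {
    s <- seqs[lens == L]
    off <- lapply(1:(L - k + 1), function(i) substr(s, i, i + k - 1L))
    pieces[[length(pieces) + 1L]] <- unlist(off, use.names = FALSE)
  }
  km <- unlist(pieces, use.names = FALSE)
  dt <- data.table::data.table(kmer = km)
  cnt <- dt[, .N, by = "kmer"]
  data.table::setorderv(cnt, "kmer")
  structure(list(k = as.integer(k),
                 counts = setNames(cnt$N, cnt$kmer)),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("k-mer table: k = %d, %d distinct k-mers, %d total\n",
              x$k, length(x$counts), sum(x$counts)))
  invisible(x)
}
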