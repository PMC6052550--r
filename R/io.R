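#' @import data.table
#' @importFrom stats median qnorm rbinom rnorm runif setNames
#' @importFrom utils head tail
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Timestamped log message to standard error
#'
#' All pipeline logging goes to stderr so that results on stdout stay clean.
#' @param ... passed to [sprintf()] (first element is the format string).
#' @keywords internal
log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

#' Construct a read set
#'
#' A read set is a plain `data.frame` with columns `id`, `sequence`,
#' `quality` (may be `NA`) and `mate_id` (may be `NA`). Sequences are
#' uppercase strings over A/C/G/T/N.
#'
#' @param id character vector of read labels.
#' @param sequence character vector of DNA sequences.
#' @param quality optional character vector of per-base qualities (same
#'   lengths as `sequence`).
#' @param mate_id optional character vector linking paired reads.
#' @return a `data.frame` of class `read_set`.
#' @export
read_set <- function(id, sequence, quality = NA_character_,
                     mate_id = NA_character_) {
  if (length(sequence) == 0) {
    out <- data.frame(id = character(), sequence = character(),
                      quality = character(), mate_id = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("read_set", "data.frame")
    return(out)
  }
  sequence <- toupper(sequence)
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("invalid characters in sequence(s): ", paste(head(id[bad], 3), collapse = ", "))
  }
  if (any(nchar(sequence) < 1)) stop("zero-length sequence in read set")
  ql <- !is.na(quality)
  if (any(ql & nchar(quality) != nchar(sequence))) {
    stop("quality length differs from sequence length")
  }
  out <- data.frame(id = as.character(id), sequence = sequence,
                    quality = as.character(quality),
                    mate_id = as.character(mate_id),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

open_maybe_gz <- function(path) {
  # gzfile() reads plain files transparently as well
  gzfile(path, open = "rt")
}

#' Read sequences from FASTA or FASTQ
#'
#' Lowercase bases are uppercased; characters outside A/C/G/T/N are rejected.
#' gzip-compressed files are handled transparently. Parse errors report the
#' offending line number.
#'
#' @param path path to a (optionally gzipped) FASTA or FASTQ file.
#' @param format one of `"auto"`, `"fasta"`, `"fastq"`. `"auto"` sniffs the
#'   first non-empty character (`>` vs `@`).
#' @return a [read_set()] `data.frame` in file order; empty file gives an
#'   empty read set.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0) return(read_set(character(), character())[0, ])
  if (format == "auto") {
    first <- substr(trimws(lines[which(nzchar(trimws(lines)))[1]]), 1, 1)
    format <- switch(first, ">" = "fasta", "@" = "fastq",
                     stop("cannot determine format of ", path,
                          " (first record char '", first, "')"))
  }
  if (format == "fasta") parse_fasta(lines, path) else parse_fastq(lines, path)
}

parse_fasta <- function(lines, path) {
  keep <- nzchar(lines)
  hdr <- grepl("^>", lines)
  if (any(keep) && !hdr[which(keep)[1]]) {
    stop("malformed FASTA in ", path, ": line ", which(keep)[1],
         " does not start a record")
  }
  rec <- cumsum(hdr)
  stray <- keep & rec == 0
  if (any(stray)) stop("malformed FASTA in ", path, ": line ", which(stray)[1])
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seq_lines <- lines[!hdr & keep]
  seqs <- vapply(split(seq_lines, rec[!hdr & keep]), paste, "", collapse = "")
  # headers with no sequence lines give empty strings
  full <- character(sum(hdr))
  full[as.integer(names(seqs))] <- seqs
  empty <- !nzchar(full)
  if (any(empty)) {
    stop("malformed FASTA in ", path, ": record '", ids[which(empty)[1]],
         "' (line ", which(hdr)[which(empty)[1]], ") has no sequence")
  }
  up <- toupper(full)
  bad <- regexpr("[^ACGTN]", up)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("invalid base '", substr(up[i], bad[i], bad[i]), "' in record '",
         ids[i], "' of ", path)
  }
  read_set(ids, up)
}

parse_fastq <- function(lines, path) {
  lines <- lines[nzchar(lines) | seq_along(lines) < length(lines)]
  n <- length(lines)
  if (n %% 4 != 0) {
    stop("malformed FASTQ in ", path, ": truncated record near line ", n)
  }
  idx <- seq(1, n, by = 4)
  bad_hdr <- !startsWith(lines[idx], "@")
  if (any(bad_hdr)) {
    stop("malformed FASTQ in ", path, ": line ", idx[which(bad_hdr)[1]],
         " does not start with '@'")
  }
  bad_sep <- !startsWith(lines[idx + 2], "+")
  if (any(bad_sep)) {
    stop("malformed FASTQ in ", path, ": line ", idx[which(bad_sep)[1]] + 2,
         " does not start with '+'")
  }
  ids <- sub("\\s.*$", "", sub("^@", "", lines[idx]))
  seqs <- toupper(lines[idx + 1])
  quals <- lines[idx + 3]
  mism <- nchar(seqs) != nchar(quals)
  if (any(mism)) {
    stop("malformed FASTQ in ", path, ": quality length differs from ",
         "sequence length at line ", idx[which(mism)[1]] + 3)
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("invalid base in record '", ids[i], "' at line ", idx[i] + 1,
         " of ", path)
  }
  read_set(ids, seqs, quality = quals)
}

#' Write contigs to FASTA
#'
#' Records are named `contig_<index>_len_<length>` and wrapped at 80 columns.
#'
#' @param contigs character vector of DNA strings (may be empty).
#' @param path output path.
#' @export
write_contigs <- function(contigs, path) {
  stopifnot(!is.null(contigs))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(contigs)) {
    s <- contigs[[i]]
    writeLines(sprintf(">contig_%d_len_%d", i, nchar(s)), con)
    starts <- seq(1, nchar(s), by = 80)
    writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
  }
  invisible(NULL)
}

#' Write paired reads to FASTQ files
#'
#' @param reads a [read_set()].
#' @param path output FASTQ path (plain text).
#' @export
write_fastq <- function(reads, path) {
  qual <- ifelse(is.na(reads$quality),
                 strrep("I", nchar(reads$sequence)), reads$quality)
  out <- as.vector(rbind(paste0("@", reads$id), reads$sequence, "+", qual))
  writeLines(out, path)
  invisible(NULL)
}

#' Load a key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Keys mirror the CLI
#' flag names with `-` replaced by `_`. CLI flags override config values.
#'
#' @param path path to config file.
#' @return named list of character values.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: '", lines[which(bad)[1]], "'")
  setNames(lapply(kv, function(m) trimws(m[3])),
           vapply(kv, function(m) gsub("-", "_", m[2]), ""))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Assembly configuration
#'
#' Bundles the tunable parameters of the pipeline with their invariants
#' (1 < k, 0 <= confidence_q <= 1).
#'
#' @param k de Bruijn graph dimension (k-mer length). Default 55, consistent
#'   with 100-bp reads; worked examples use small k (e.g. 4).
#' @param low_weight_cutoff integer cutoff for error-edge removal; `NULL`
#'   means choose from the k-mer weight spectrum at run time.
#' @param tip_length_factor tip length limit in edges as a multiple of k.
#' @param genome_size_override optional known genome length G in bases.
#' @param confidence_q confidence level used by the coverage planner.
#' @param single_strand_mode if `TRUE`, reads are not reverse-complemented
#'   before k-mer counting.
#' @param random_seed integer seed for any stochastic component.
#' @return list of class `assembly_config`.
#' @export
assembly_config <- function(k = 55L, low_weight_cutoff = NULL,
                            tip_length_factor = 2L,
                            genome_size_override = NULL,
                            confidence_q = 0.95,
                            single_strand_mode = FALSE,
                            random_seed = 1L) {
  k <- as.integer(k)
  if (k <= 1L) stop("k must be > 1")
  if (confidence_q < 0 || confidence_q > 1) stop("confidence_q must be in [0,1]")
  if (!is.null(genome_size_override) && genome_size_override <= 0) {
    stop("genome_size_override must be positive")
  }
  structure(list(k = k, low_weight_cutoff = low_weight_cutoff,
                 tip_length_factor = as.integer(tip_length_factor),
                 genome_size_override = genome_size_override,
                 confidence_q = confidence_q,
                 single_strand_mode = isTRUE(single_strand_mode),
                 random_seed = as.integer(random_seed)),
            class = "assembly_config")
}
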