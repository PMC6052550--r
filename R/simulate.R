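#' Tandem repeat specification
#'
#' Declarative description of one tandem array: a motif of `motif_length`
#' bases repeated `repeat_count` times back to back.
#'
#' @param motif_length motif length d in bases.
#' @param repeat_count number of copies m (>= 2).
#' @param motif optional explicit motif (length must equal `motif_length`);
#'   random when `NULL`.
#' @return list of class `repeat_spec`.
#' @export
repeat_spec <- function(motif_length, repeat_count, motif = NULL) {
  if (repeat_count < 2) stop("repeat_count must be >= 2")
  if (motif_length < 1) stop("motif_length must be >= 1")
  if (!is.null(motif) && nchar(motif) != motif_length) {
    stop("motif length does not equal motif_length")
  }
  structure(list(motif_length = as.integer(motif_length),
                 repeat_count = as.integer(repeat_count),
                 motif = motif),
            class = "repeat_spec")
}

#' The standard 20-array reference design
#'
#' Motifs of length 100, 200, 300, 400 and 500 bp, each repeated 2, 3, 4 and
#' 5 times, ordered by motif length then repeat count. With 1000-bp spacers
#' this yields a 42,000-bp reference (21,000 bp of arrays + 21 spacers).
#'
#' @return list of 20 [repeat_spec()] objects.
#' @export
default_reference_specs <- function() {
  specs <- list()
  for (d in c(100L, 200L, 300L, 400L, 500L)) {
    for (m in 2:5) specs[[length(specs) + 1L]] <- repeat_spec(d, m)
  }
  specs
}

#' Random DNA sequence
#'
#' @param n length in bases.
#' @return a single DNA string, i.i.d. uniform over A/C/G/T.
#' @export
random_dna <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a reference genome with planted tandem arrays
#'
#' The sequence is spacer1 + array1 + spacer2 + array2 + ... + spacerM+1,
#' with spacers of i.i.d. random bases. Motifs are random unless given
#' explicitly. The ground truth records every array as a 0-based half-open
#' interval.
#'
#' @param specs ordered list of [repeat_spec()] (a single spec may be passed
#'   bare).
#' @param spacer_length spacer length(s) in bases; recycled to
#'   `length(specs) + 1` values (the last is the trailing spacer).
#' @param circular is the genome circular?
#' @param seed integer seed (same seed, same sequence).
#' @return list of class `simulated_reference` with `sequence`, `truth`
#'   (`data.frame`: start, end, motif, motif_length, count), `circular`,
#'   `seed`.
#' @export
make_reference <- function(specs, spacer_length = 1000L, circular = FALSE,
                           seed = 1L) {
  if (inherits(specs, "repeat_spec")) specs <- list(specs)
  if (length(specs) == 0) stop("specs must be non-empty")
  if (any(spacer_length < 0)) stop("spacer_length must be >= 0")
  set.seed(seed)
  spacers <- rep_len(as.integer(spacer_length), length(specs) + 1L)
  parts <- character(0)
  truth <- list()
  pos <- 0L
  for (i in seq_along(specs)) {
    sp <- random_dna(spacers[i])
    parts <- c(parts, sp)
    pos <- pos + spacers[i]
    spec <- specs[[i]]
    motif <- if (is.null(spec$motif)) random_dna(spec$motif_length) else spec$motif
    array <- strrep(motif, spec$repeat_count)
    parts <- c(parts, array)
    truth[[i]] <- data.frame(start = pos, end = pos + nchar(array),
                             motif = motif, motif_length = spec$motif_length,
                             count = spec$repeat_count,
                             stringsAsFactors = FALSE)
    pos <- pos + nchar(array)
  }
  parts <- c(parts, random_dna(spacers[length(spacers)]))
  structure(list(sequence = paste(parts, collapse = ""),
                 truth = do.call(rbind, truth),
                 circular = isTRUE(circular), seed = as.integer(seed)),
            class = "simulated_reference")
}

#' @export
print.simulated_reference <- function(x, ...) {
  cat(sprintf("simulated reference: %d bp (%s), %d tandem array(s)\n",
              nchar(x$sequence), if (x$circular) "circular" else "linear",
              nrow(x$truth)))
  invisible(x)
}

#' Read simulation parameters
#'
#' Defaults mirror a typical Illumina paired-end run on a small genome:
#' 100-bp reads, 150x depth, 250 +/- 25 bp inserts, 1% substitutions, indels
#' on at 1e-4 per base.
#'
#' @param read_length read length L in bases.
#' @param coverage total fold coverage (both mates).
#' @param insert_mean,insert_std fragment length distribution (normal,
#'   rounded; truncated below at 2L - 1).
#' @param substitution_rate per-base substitution probability.
#' @param simulate_indels apply a 1e-4 per-base insertion/deletion rate.
#' @param seed integer seed.
#' @param forward_only emit mate 2 from the forward strand (error-free
#'   oracle mode together with `substitution_rate = 0`).
#' @return list of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 100L, coverage = 150,
                            insert_mean = 250, insert_std = 25,
                            substitution_rate = 0.01, simulate_indels = TRUE,
                            seed = 1L, forward_only = FALSE) {
  if (insert_mean < read_length) stop("insert_mean must be >= read_length")
  if (substitution_rate < 0 || substitution_rate > 1) {
    stop("substitution_rate must be in [0, 1]")
  }
  structure(list(read_length = as.integer(read_length), coverage = coverage,
                 insert_mean = insert_mean, insert_std = insert_std,
                 substitution_rate = substitution_rate,
                 simulate_indels = isTRUE(simulate_indels),
                 seed = as.integer(seed), forward_only = isTRUE(forward_only)),
            class = "read_sim_params")
}

INDEL_RATE <- 1e-4

apply_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1)
  n <- length(seqs)
  mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE), nrow = L)
  idx <- which(runif(L * n) < rate)
  if (length(idx) > 0) {
    bases <- c("A", "C", "G", "T")
    code <- match(mat[idx], bases)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    mat[idx] <- bases[((code - 1L + shift) %% 4L) + 1L]
  }
  do.call(paste0, as.data.frame(t(mat), stringsAsFactors = FALSE))
}

apply_indels <- function(seqs, rate = INDEL_RATE) {
  if (rate <= 0) return(seqs)
  L <- nchar(seqs)
  nind <- rbinom(length(seqs), L, rate)
  for (i in which(nind > 0)) {
    s <- seqs[i]
    for (j in seq_len(nind[i])) {
      p <- sample.int(nchar(s), 1)
      if (runif(1) < 0.5) {  # deletion
        s <- paste0(substr(s, 1, p - 1), substr(s, p + 1, nchar(s)))
      } else {               # insertion
        s <- paste0(substr(s, 1, p), sample(c("A", "C", "G", "T"), 1),
                    substr(s, p + 1, nchar(s)))
      }
    }
    seqs[i] <- s
  }
  seqs
}

#' Simulate paired-end reads from a reference
#'
#' Fragment starts are uniform over the genome (wrapping when circular);
#' fragment lengths are normal(insert_mean, insert_std), rounded and
#' truncated to at least 2 x read_length - 1. Mate 1 is the fragment's
#' 5' end; mate 2 is the reverse complement of its 3' end (forward when
#' `forward_only`). The number of pairs is
#' `ceiling(coverage * G / (2 * read_length))`. Deterministic under `seed`.
#'
#' @param reference a [make_reference()] result (or a plain DNA string).
#' @param params a [read_sim_params()].
#' @return list with elements `mate1` and `mate2` ([read_set()]s).
#' @export
simulate_reads <- function(reference, params = read_sim_params()) {
  seq0 <- if (inherits(reference, "simulated_reference")) reference$sequence
          else as.character(reference)
  circular <- if (inherits(reference, "simulated_reference")) reference$circular
              else FALSE
  G <- nchar(seq0)
  L <- params$read_length
  if (G <= params$insert_mean) stop("reference shorter than insert size")
  set.seed(params$seed)
  n_pairs <- ceiling(params$coverage * G / (2 * L))
  flen <- pmax(2L * L - 1L,
               as.integer(round(rnorm(n_pairs, params$insert_mean,
                                      params$insert_std))))
  flen <- pmin(flen, G)
  if (circular) {
    starts <- sample.int(G, n_pairs, replace = TRUE)
    genome <- paste0(seq0, substr(seq0, 1L, max(flen)))
  } else {
    starts <- floor(runif(n_pairs) * (G - flen + 1)) + 1L
    genome <- seq0
  }
  frag_start <- starts
  frag_end <- starts + flen - 1L
  m1 <- substr(substring(genome, frag_start, frag_end), 1L, L)
  m2 <- substring(genome, frag_end - L + 1L, frag_end)
  if (!params$forward_only) m2 <- revcomp(m2)
  m1 <- apply_substitutions(m1, params$substitution_rate)
  m2 <- apply_substitutions(m2, params$substitution_rate)
  if (params$simulate_indels) {
    m1 <- apply_indels(m1)
    m2 <- apply_indels(m2)
  }
  ids <- sprintf("sim_%d", seq_len(n_pairs))
  list(mate1 = read_set(paste0(ids, "/1"), m1,
                        quality = strrep("I", nchar(m1)), mate_id = ids),
       mate2 = read_set(paste0(ids, "/2"), m2,
                        quality = strrep("I", nchar(m2)), mate_id = ids))
}

#' Write the reference and its truth table to disk
#'
#' FASTA for the sequence, TSV (0-based half-open start/end, motif, count)
#' for the truth.
#'
#' @param reference a [make_reference()] result.
#' @param fasta_path,truth_path output paths.
#' @export
write_reference <- function(reference, fasta_path, truth_path) {
  con <- file(fasta_path, "wt")
  writeLines(sprintf(">reference_len_%d%s", nchar(reference$sequence),
                     if (reference$circular) "_circular" else ""), con)
  s <- reference$sequence
  starts <- seq(1, nchar(s), by = 80)
  writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
  close(con)
  utils::write.table(reference$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
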