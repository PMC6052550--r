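cyclic_rotations <- function(motif) {
  d <- nchar(motif)
  unique(vapply(0:(d - 1), function(i) {
    paste0(substr(motif, i + 1, d), substr(motif, 1, i))
  }, ""))
}

#' Count tandem repetitions of a motif in a contig
#'
#' Returns the maximum, over all cyclic rotations of the motif and all
#' positions, of (maximal tandem run length / motif length). Fractional
#' counts arise when a run ends in a partial copy (repetitive length divided
#' by motif length). Rotations are considered because an assembly may enter
#' an array at any phase. Returns 0 when the motif is absent.
#'
#' @param contig a DNA string.
#' @param motif the repeat motif (non-empty).
#' @return rational repeat count.
#' @export
count_motif_repeats <- function(contig, motif) {
  d <- nchar(motif)
  if (d == 0) stop("motif must be non-empty")
  Lc <- nchar(contig)
  if (Lc < d) return(0)
  best <- 0
  for (rot in cyclic_rotations(motif)) {
    hits <- gregexpr(rot, contig, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    for (s in hits) {
      q <- s
      while (q + 2 * d - 1 <= Lc &&
             substr(contig, q + d, q + 2 * d - 1) == rot) {
        q <- q + d
      }
      full <- (q - s) / d + 1
      # partial tail: longest prefix of the rotation continuing the run
      t <- 0
      while (t < d && q + d + t <= Lc &&
             substr(contig, q + d + t, q + d + t) == substr(rot, t + 1, t + 1)) {
        t <- t + 1
      }
      best <- max(best, full + t / d)
    }
  }
  best
}

#' Find exact tandem arrays in a sequence
#'
#' Exact-match detection (no alignment): positions i with
#' `s[i] == s[i + d]` are found for every candidate motif length d, and
#' maximal runs of at least d such positions form arrays of repeat count
#' (run + d) / d. Overlapping calls are reduced to the longest array, ties
#' to the smallest motif.
#'
#' @param sequence DNA string.
#' @param min_motif,max_motif motif length range in bases.
#' @param min_repeats minimum repeat count to report (default 2).
#' @return `data.frame` with columns `start` (0-based), `motif`,
#'   `motif_length`, `repeat_count`, `array_length`.
#' @export
find_tandem_arrays <- function(sequence, min_motif, max_motif,
                               min_repeats = 2) {
  if (min_motif < 1 || min_motif > max_motif) {
    stop("need 1 <= min_motif <= max_motif")
  }
  L <- nchar(sequence)
  r <- charToRaw(sequence)
  calls <- list()
  for (d in min_motif:max_motif) {
    if (2 * d > L) break
    eq <- r[1:(L - d)] == r[(d + 1):L]
    rl <- rle(eq)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    ok <- rl$values & rl$lengths >= d * (min_repeats - 1)
    for (j in which(ok)) {
      i <- starts[j]
      alen <- rl$lengths[j] + d
      calls[[length(calls) + 1L]] <- data.frame(
        start = i - 1L,
        motif = substr(sequence, i, i + d - 1L),
        motif_length = d,
        repeat_count = alen / d,
        array_length = alen,
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0) {
    return(data.frame(start = integer(), motif = character(),
                      motif_length = integer(), repeat_count = numeric(),
                      array_length = integer(), stringsAsFactors = FALSE))
  }
  calls <- do.call(rbind, calls)
  calls <- calls[order(-calls$array_length, calls$motif_length, calls$start), ]
  keep <- rep(FALSE, nrow(calls))
  taken_s <- integer(0); taken_e <- integer(0)
  for (i in seq_len(nrow(calls))) {
    s <- calls$start[i]; e <- s + calls$array_length[i]
    if (!any(s < taken_e & e > taken_s)) {
      keep[i] <- TRUE
      taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
    }
  }
  out <- calls[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score an assembly against the simulation truth
#'
#' For each planted array, reports the repeat count recovered in the
#' best-matching contig (the motif and its reverse complement are both
#' tried; 0 when the motif is absent), alongside the usual contig summary
#' statistics.
#'
#' @param result an [assembly_result()] (or plain character vector of
#'   contigs).
#' @param truth a `simulated_reference` or its `truth` `data.frame`.
#' @return list of class `assembly_score` with `per_array` (`data.frame`:
#'   motif_length, expected, recovered) and `summary`.
#' @export
score_assembly <- function(result, truth) {
  contigs <- if (inherits(result, "assembly_result")) result$contigs
             else as.character(result)
  tr <- if (inherits(truth, "simulated_reference")) truth$truth else truth
  recovered <- vapply(seq_len(nrow(tr)), function(i) {
    motif <- tr$motif[i]
    rc <- revcomp(motif)
    if (length(contigs) == 0) return(0)
    max(vapply(contigs, function(ctg) {
      max(count_motif_repeats(ctg, motif), count_motif_repeats(ctg, rc))
    }, 0))
  }, 0)
  res <- if (inherits(result, "assembly_result")) result
         else assembly_result(contigs)
  structure(list(
    per_array = data.frame(motif_length = tr$motif_length,
                           expected = tr$count, recovered = recovered),
    summary = list(n_contigs = res$n_contigs, n50 = res$n50,
                   longest = res$longest)),
    class = "assembly_score")
}

#' @export
print.assembly_score <- function(x, ...) {
  print(x$per_array)
  ok <- sum(abs(x$per_array$recovered - x$per_array$expected) < 0.5)
  cat(sprintf("%d/%d arrays recovered; %d contig(s), N50 = %d, longest = %d\n",
              ok, nrow(x$per_array), x$summary$n_contigs, x$summary$n50,
              x$summary$longest))
  invisible(x)
}
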