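#' Coverage model parameters
#'
#' Bundles the quantities of the k-mer coverage model: N reads of identical
#' length L, graph dimension k, genome length G, a tandem repeat of total
#' length n whose motif has length d, and a confidence level q. The k-mer
#' span of the repeat, Delta = n - k + 1, is always derived, never stored.
#'
#' @param N number of reads.
#' @param L read length (bases).
#' @param k graph dimension.
#' @param G genome length (bases).
#' @param n tandem repeat total length (bases); must exceed k.
#' @param d motif length (bases); at most n.
#' @param q confidence level in \[0, 1\].
#' @return list of class `coverage_params`.
#' @export
coverage_params <- function(N, L, k, G, n = k + 1, d = n, q = 0.95) {
  if (any(c(N, L, k, G, n, d) <= 0)) stop("all parameters must be positive")
  if (n <= k) stop("tandem repeat length n must exceed k")
  if (d > n) stop("motif length d cannot exceed repeat length n")
  if (L <= k) stop("read length L must exceed k")
  if (q < 0 || q > 1) stop("q must be in [0, 1]")
  structure(list(N = N, L = L, k = k, G = G, n = n, d = d, q = q),
            class = "coverage_params")
}

delta_of <- function(params) params$n - params$k + 1

#' Expected edge weight under the ideal (error-free) model
#'
#' Non-repetitive k-mers have expected weight N(L-k+1)/G; k-mers inside a
#' tandem repeat of length n and motif length d are inflated by Delta/d with
#' Delta = n - k + 1.
#'
#' @param params a [coverage_params()].
#' @param repetitive is the k-mer inside the tandem repeat?
#' @return expected weight (rational number).
#' @export
expected_edge_weight <- function(params, repetitive = FALSE) {
  stopifnot(inherits(params, "coverage_params"))
  base <- params$N * (params$L - params$k + 1) / params$G
  if (repetitive) delta_of(params) / params$d * base else base
}

#' Poisson rate of the edge-weight distribution
#'
#' The edge weight of a repeat k-mer is Poisson with rate
#' lambda = N L (L-k+1) Delta / (G k d). This is the printed model rate (it
#' carries an extra L/k factor relative to the plain expectation) and is
#' exposed as a diagnostic; normalization uses [normalization_factor()].
#'
#' @param params a [coverage_params()].
#' @return positive rate.
#' @export
poisson_lambda <- function(params) {
  stopifnot(inherits(params, "coverage_params"))
  with(params, N * L * (L - k + 1) * delta_of(params) / (G * k * d))
}

#' Normalization factor p = G / (N (L - k + 1))
#'
#' Multiplying a read-space k-mer count by p converts it into a per-genome
#' copy number (expected value 1 for unique k-mers).
#'
#' @param G genome length.
#' @param N number of reads.
#' @param L read length.
#' @param k graph dimension.
#' @return positive factor.
#' @export
normalization_factor <- function(G, N, L, k) {
  if (L <= k) stop("read length L must exceed k")
  if (N * (L - k + 1) <= 0) stop("N(L-k+1) must be positive")
  G / (N * (L - k + 1))
}

#' Round half up
#'
#' floor(x + 0.5): the model's rounding rule, which differs from R's
#' banker's rounding at exact halves (2.5 rounds to 3 here).
#'
#' @param x numeric.
#' @return numeric of same length.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Normalize one edge weight
#'
#' w' = floor(p * w + 0.5).
#'
#' @param w non-negative weight(s).
#' @param p normalization factor.
#' @return non-negative integer-valued weight(s).
#' @export
normalize_weight <- function(w, p) {
  if (any(w < 0)) stop("weights must be >= 0")
  round_half_up(p * w)
}

#' Normalize all edge weights of a graph
#'
#' Each weight becomes its per-genome copy number estimate
#' floor(p * w + 0.5); edges whose normalized weight is 0 are deleted.
#'
#' @param g a cleaned `dbg` graph.
#' @param p normalization factor (see [normalization_factor()]).
#' @return normalized graph.
#' @export
normalize_graph <- function(g, p) {
  g <- dbg_set_weights(g, normalize_weight(g$weight, p))
  dbg_drop_edges(g, which(g$weight == 0))
}

#' Normal approximation of the normalized repeat-edge weight
#'
#' For coverage >= 10 the normalized weight of a repeat edge is
#' approximately Normal with mean Delta/d and sd sqrt(Delta/d).
#'
#' @param n tandem repeat length (> k).
#' @param d motif length.
#' @param k graph dimension.
#' @return named numeric vector `c(mean, sd)`.
#' @export
weight_distribution_normal <- function(n, d, k) {
  if (n <= k) stop("n must exceed k")
  mu <- (n - k + 1) / d
  c(mean = mu, sd = sqrt(mu))
}

#' Required coverage for reliable repeat-count recovery
#'
#' Returns c = k/(L-k+1) * (2 * Phi^-1((1+q)/2))^2 * Delta/d, the read depth
#' at which the normalized weight of a repeat edge resolves the copy number
#' with confidence q.
#'
#' @param q confidence level in (0, 1).
#' @param k graph dimension.
#' @param L read length (> k).
#' @param n tandem repeat length (> k).
#' @param d motif length.
#' @return required fold coverage.
#' @export
required_coverage <- function(q, k, L, n, d) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (n <= k) stop("n must exceed k")
  if (L <= k) stop("L must exceed k")
  k / (L - k + 1) * (2 * qnorm((1 + q) / 2))^2 * (n - k + 1) / d
}

#' Required-coverage table over a grid of repeat geometries
#'
#' @param q confidence level.
#' @param k graph dimension.
#' @param L read length.
#' @param n_values vector of repeat lengths.
#' @param d_values vector of motif lengths.
#' @return `data.frame` with columns `n`, `d`, `coverage` (rows where
#'   d > n or n <= k are dropped).
#' @export
required_coverage_table <- function(q, k, L, n_values, d_values) {
  grid <- expand.grid(n = n_values, d = d_values)
  grid <- grid[grid$d <= grid$n & grid$n > k, , drop = FALSE]
  grid$coverage <- mapply(function(n, d) required_coverage(q, k, L, n, d),
                          grid$n, grid$d)
  rownames(grid) <- NULL
  grid
}

#' Estimate genome length from the graph
#'
#' Uses the number of distinct edges (distinct k-mers), halved when the
#' graph was built in double-strand mode. A user-supplied genome size always
#' takes precedence in the pipeline. Note: for references dominated by
#' repeats this estimate is biased low, since repeat copies collapse onto
#' single edges.
#'
#' @param g a cleaned `dbg` graph.
#' @param single_strand was the graph built in single-strand mode?
#' @return estimated genome length in bases.
#' @export
estimate_genome_size <- function(g, single_strand = TRUE) {
  if (n_edges(g) == 0) stop("empty graph: cannot estimate genome size")
  ne <- n_edges(g)
  if (single_strand) ne else max(1, round(ne / 2))
}

#' Pick the single-copy coverage peak from the edge-weight spectrum
#'
#' Classic k-mer spectrum heuristic: skip the error peak at weight 1 by
#' finding the first valley (first weight where the histogram turns upward),
#' then return the modal weight above it.
#'
#' @param g a `dbg` graph (pre-cleaning) or a bare numeric vector of
#'   k-mer counts / edge weights.
#' @return modal single-copy edge weight (integer >= 1).
#' @export
weight_spectrum_mode <- function(g) {
  w <- if (inherits(g, "dbg")) g$weight else as.numeric(g)
  w <- as.integer(round(w))
  if (length(w) == 0) stop("empty graph")
  h <- tabulate(w, nbins = max(w))
  valley <- 1L
  while (valley < length(h) && h[valley + 1] <= h[valley]) valley <- valley + 1L
  if (valley >= length(h)) return(max(1L, as.integer(round(median(w)))))
  which.max(h[(valley + 1):length(h)]) + valley
}
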