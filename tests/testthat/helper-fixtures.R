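# Weighted 4-mer multiset of the worked traversal example: spells the reads
# CCATGGGAG / CATTAACCC / TTTCCCGACGACGACT with the GAC loop carrying
# weights 3/2/2.
worked_example_kmers <- function() {
  c("CCAT", "CATG", "ATGG", "TGGG", "GGGA", "GGAG",
    "CATT", "ATTA", "TTAA", "TAAC", "AACC", "ACCC",
    "TTTC", "TTCC", "TCCC", "CCCG", "CCGA",
    rep("CGAC", 3), rep("GACG", 2), rep("ACGA", 2), "GACT")
}

worked_example_graph <- function() {
  build_graph(count_kmers(worked_example_kmers(), 4, single_strand = TRUE))
}

# graph from the exact k-spectrum of a sequence: edge weights are true
# per-genome copy numbers
graph_from_sequence <- function(seq, k) {
  build_graph(count_kmers(seq, k, single_strand = TRUE))
}

# hand-built graph from labelled weighted edges
graph_from_edges <- function(k, from, to, weight) {
  tandemasm:::dbg_create(k, from, to, weight)
}

# spacer + motif^m + spacer toy genome; spacers fixed to be repeat-free
# flanks chosen so no (k-1)-mer recurs outside the array (no spurious cycles)
toy_tandem_genome <- function(motif = "ACGTG", m = 3, k = 4,
                              left = "TATCCAG", right = "CCCTCTA") {
  paste0(left, strrep(motif, m), right)
}
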