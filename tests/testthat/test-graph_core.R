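test_that("extract_kmers returns the L-k+1 substrings in order", {
  expect_equal(extract_kmers("ACGTA", 4), c("ACGT", "CGTA"))
  expect_equal(extract_kmers("ACG", 4), character())
  expect_length(extract_kmers(strrep("A", 100), 55), 46)
  expect_error(extract_kmers("ACGT", 1), "k must be >= 2")
})

test_that("count_kmers aggregates, handles strands and splits at N", {
  expect_equal(count_kmers("AAAA", 3, single_strand = TRUE)$counts,
               c(AAA = 2L))
  # palindrome counted once per strand
  expect_equal(count_kmers("ACGT", 4, single_strand = FALSE)$counts,
               c(ACGT = 2L))
  expect_equal(count_kmers(c("ACG", "ACG"), 3, single_strand = TRUE)$counts,
               c(ACG = 2L))
  # N splits the read; fragments shorter than k are dropped
  expect_equal(count_kmers("ACGNGT", 3, single_strand = TRUE)$counts,
               c(ACG = 1L))
  expect_error(count_kmers(c("AC", "GT"), 3, single_strand = TRUE),
               "cannot build")
})

test_that("k-mer conservation: counts sum to sum over reads of L-k+1", {
  set.seed(11)
  for (k in c(3, 7, 15)) {
    reads <- vapply(sample(k:40, 25, replace = TRUE), random_dna, "")
    tab <- count_kmers(reads, k, single_strand = TRUE)
    expect_equal(sum(tab$counts), sum(pmax(0, nchar(reads) - k + 1)))
  }
})

test_that("build_graph creates one weighted edge per distinct k-mer", {
  g <- build_graph(count_kmers(rep("ACGT", 3), 4, single_strand = TRUE))
  e <- graph_edges(g)
  expect_equal(e, data.frame(from = "ACG", to = "CGT", weight = 3))
  expect_error(build_graph(structure(list(k = 4L, counts = integer()),
                                     class = "kmer_table")),
               "empty")
})

test_that("worked-example graph has the expected branch structure", {
  g <- worked_example_graph()
  od <- tandemasm:::out_deg(g)
  id <- tandemasm:::in_deg(g)
  expect_equal(sort(g$labels[od == 2]), c("CAT", "GAC"))
  expect_equal(sort(g$labels[id == 2]), c("CCC", "CGA"))
  # k-mer conservation through graph construction
  expect_equal(tandemasm:::total_weight(g), length(worked_example_kmers()))
})

test_that("remove_low_weight_edges deletes below cutoff, identity at 0", {
  g <- graph_from_edges(4, c("AAA", "CCC"), c("AAC", "CCA"), c(1, 10))
  g2 <- remove_low_weight_edges(g, 2)
  expect_equal(graph_edges(g2),
               data.frame(from = "CCC", to = "CCA", weight = 10))
  expect_equal(graph_edges(remove_low_weight_edges(g, 0)), graph_edges(g))
  expect_error(remove_low_weight_edges(g, -1))
})

test_that("remove_tips deletes weak dead-ends and keeps chains", {
  # linear chain: no tips
  chain <- graph_from_sequence("ACGTGGTACC", 4)
  expect_equal(graph_edges(remove_tips(chain)), graph_edges(chain))

  # main path weight 50 with a 2-edge dead-end of weight 1 at branch point CGT
  g <- graph_from_edges(
    4,
    from = c("ACG", "CGT", "GTA", "TAC", "CGT", "GTT"),
    to   = c("CGT", "GTA", "TAC", "ACC", "GTT", "TTT"),
    weight = c(50, 50, 50, 50, 1, 1))
  g2 <- remove_tips(g, max_tip_length = 4, weight_ratio = 0.2)
  expect_equal(nrow(graph_edges(g2)), 4)
  expect_false("TTT" %in% g2$labels)

  # two qualifying dead-ends: both removed
  g3 <- graph_from_edges(
    4,
    from = c("ACG", "CGT", "GTA", "TAC", "CGT", "GTA"),
    to   = c("CGT", "GTA", "TAC", "ACC", "GTT", "TAA"),
    weight = c(50, 50, 50, 50, 1, 1))
  g3c <- remove_tips(g3, max_tip_length = 4, weight_ratio = 0.2)
  expect_equal(sort(graph_edges(g3c)$to), c("ACC", "CGT", "GTA", "TAC"))
})

test_that("remove_bubbles merges parallel paths, lower path absorbed", {
  # parallel paths AC->CG->GT->TT (weights 40) and AC->CT->TT (weights 2):
  # the weaker path is deleted and its minimum weight added to the survivor
  g <- graph_from_edges(
    3,
    from = c("AC", "CG", "GT", "AC", "CT"),
    to   = c("CG", "GT", "TT", "CT", "TT"),
    weight = c(40, 40, 40, 2, 2))
  g2 <- remove_bubbles(g, 5)
  e <- graph_edges(g2)
  expect_equal(nrow(e), 3)
  expect_true(all(e$weight == 42))
  expect_equal(e$from, c("AC", "CG", "GT"))

  # no parallel paths: unchanged
  chain <- graph_from_sequence("ACGTGGT", 3)
  expect_equal(graph_edges(remove_bubbles(chain)), graph_edges(chain))

  # tie in total weight (6 vs 6): the lexicographically smaller path
  # spelling (AC>CG>GT>TT < AC>CT>TT) survives
  gt <- graph_from_edges(
    3,
    from = c("AC", "CG", "GT", "AC", "CT"),
    to   = c("CG", "GT", "TT", "CT", "TT"),
    weight = c(2, 2, 2, 3, 3))
  gt2 <- remove_bubbles(gt, 5)
  e <- graph_edges(gt2)
  expect_equal(e$from, c("AC", "CG", "GT"))
  expect_true(all(e$weight == 5))  # 2 + min(3, 3)
})

test_that("cleaning never creates edges", {
  set.seed(5)
  ref <- random_dna(400)
  reads <- substring(ref, 1:(400 - 30), 30:399)
  tab <- count_kmers(reads, 9, single_strand = TRUE)
  g <- build_graph(tab)
  for (op in list(function(x) remove_low_weight_edges(x, 3),
                  function(x) remove_tips(x),
                  function(x) remove_bubbles(x))) {
    expect_lte(tandemasm:::n_edges(op(g)), tandemasm:::n_edges(g))
  }
})

test_that("error-free simulated reads leave no true edge below cutoff 3 at 50x", {
  # circular so that coverage is uniform (no under-covered linear ends)
  ref <- make_reference(repeat_spec(50, 2, motif = NULL), spacer_length = 300,
                        circular = TRUE, seed = 21)
  reads <- simulate_reads(ref, read_sim_params(
    read_length = 60, coverage = 50, insert_mean = 150, insert_std = 10,
    substitution_rate = 0, simulate_indels = FALSE, seed = 21,
    forward_only = TRUE))
  tab <- count_kmers(c(reads$mate1$sequence, reads$mate2$sequence), 21,
                     single_strand = TRUE)
  g <- remove_low_weight_edges(build_graph(tab), 3)
  wrapped <- paste0(ref$sequence, substr(ref$sequence, 1, 20))
  ref_kmers <- names(count_kmers(wrapped, 21, single_strand = TRUE)$counts)
  left <- paste0(g$labels[g$from], substr(g$labels[g$to], 20, 20))
  expect_true(all(left %in% ref_kmers))
  expect_setequal(left, ref_kmers)
})

test_that("graph dumps: edge list and GFA", {
  g <- worked_example_graph()
  f <- withr::local_tempfile()
  write_edge_list(g, f)
  expect_equal(length(readLines(f)), 21)
  expect_match(readLines(f)[1], "^[ACGT]{3}\t[ACGT]{3}\t\\d+$")
  write_gfa(g, f)
  expect_equal(readLines(f)[1], "H\tVN:Z:1.0")
  expect_equal(sum(startsWith(readLines(f), "L\t")), 21)
})
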