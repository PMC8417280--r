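# Graph construction is exercised with k = 15 toys (random sequences are
# collision-free at that length) and error-free tiling reads.

toy_table <- function(reads, k = 15L) {
  filter_errors(build_kmer_table(reads, k, stranded = TRUE))
}

test_that("seed selection honours entropy, frequency and lexicographic ties", {
  mk <- function(counts) denovotx:::new_kmer_table(counts, nchar(names(counts)[1]), TRUE)
  # poly-A k-mer has H = 0 and is never seeded, however frequent
  tab <- mk(c(AAAAAAAA = 500L, ACGTACGT = 40L))
  expect_equal(select_seed(tab), "ACGTACGT")
  # frequency must exceed 1
  tab <- mk(c(ACGTACGT = 1L, CGTACGTA = 1L))
  expect_null(select_seed(tab))
  # equal counts: lexicographically smaller k-mer wins
  tab <- mk(c(CGTACGTA = 7L, ACGTACGT = 7L))
  expect_equal(select_seed(tab), "ACGTACGT")
  # used k-mers are not reselected
  expect_equal(select_seed(tab, used = "ACGTACGT"), "CGTACGTA")
})

test_that("greedy extension recovers a unique-path transcript exactly", {
  set.seed(101)
  tx <- rand_seq(400)
  reads <- tiling_pairs(tx, frag_len = 80, read_len = 40, step = 3)
  tab <- toy_table(reads)
  seed <- select_seed(tab)
  ctg <- extend_contig(seed, tab)
  expect_s3_class(ctg, "contig")
  expect_equal(ctg$sequence, tx)  # unique Eulerian walk spells the input
  expect_true(all(ctg$kmer_coverage >= 1L))
})

test_that("extension stalls on an isolated seed and follows the majority fork", {
  mk <- function(counts, k) denovotx:::new_kmer_table(counts, k, TRUE)
  tab <- mk(c(ACGTACGT = 5L), 8L)
  ctg <- extend_contig("ACGTACGT", tab)
  expect_equal(ctg$sequence, "ACGTACGT")
  # fork: after seed GTAC, right extensions TACA (count 30) vs TACC (5)
  tab <- mk(c(GTAC = 10L, TACA = 30L, TACC = 5L), 4L)
  ctg <- extend_contig("GTAC", tab)
  expect_equal(substr(ctg$sequence, 1, 5), "GTACA")
})

test_that("paired-end information bridges a coverage dip spelled by a mate", {
  set.seed(102)
  tx <- rand_seq(500)
  k <- 15L
  reads <- tiling_pairs(tx, frag_len = 120, read_len = 50, step = 4)
  tab <- toy_table(reads, k)
  # drop the k-mers spanning positions 250..252 (a 3-base dip)
  dip <- substring(tx, (250 - k + 1):252, (250 - k + 1):252 + k - 1)
  counts <- tab$counts[!(names(tab$counts) %in% dip)]
  tab2 <- denovotx:::new_kmer_table(counts, k, TRUE)
  seed <- select_seed(tab2)
  ctg <- extend_contig(seed, tab2)
  expect_lt(nchar(ctg$sequence), nchar(tx))  # stalls at the dip
  ext <- paired_end_extend(ctg, reads, tab2)
  expect_equal(ext$sequence, tx)  # mate sequence spells the gap
  # with no anchored fragments the contig is unchanged
  other <- tiling_pairs(rand_seq(300), frag_len = 120, read_len = 50,
                        step = 4, prefix = "o")
  expect_equal(paired_end_extend(ctg, other, tab2)$sequence, ctg$sequence)
})

test_that("skipped-exon toy yields a graph whose paths are exactly the isoforms", {
  set.seed(103)
  toy <- skipped_exon_toy()
  reads <- tiling_pairs(toy$iso, frag_len = 80, read_len = 40, step = 1)
  tab <- toy_table(reads)
  graphs <- build_all_graphs(tab, reads)
  expect_length(graphs, 1L)
  g <- graphs[[1]]
  expect_gt(nrow(g$edges), 0L)
  spelled <- sort(oracle_graph_sequences(g))
  expect_equal(spelled, sort(unname(toy$iso)))
})

test_that("an alternative k-mer with no read support opens no branch", {
  set.seed(104)
  tx <- rand_seq(300)
  k <- 15L
  reads <- tiling_pairs(tx, frag_len = 80, read_len = 40, step = 1)
  # chimeric artifact: a k-mer overlapping position 150 by k-1 bases with a
  # different final base, embedded mid-read in an unrelated context so the
  # junction (k+1)-mer never occurs and the k-mer is not read-initial
  anchor <- substr(tx, 150 - k + 2, 150)
  tb <- substr(tx, 151, 151)
  alt_base <- setdiff(c("A", "C", "G", "T"), tb)[1]
  chimera <- paste0(anchor, alt_base)
  # the base preceding the anchor in the host differs from the one on the
  # transcript, so no read witnesses the junction (k+1)-mer at the locus
  ctx <- substr(tx, 150 - k + 1, 150 - k + 1)
  host_prefix <- paste0(rand_seq(19), setdiff(c("A", "C", "G", "T"), ctx)[1])
  host <- paste0(host_prefix, chimera, rand_seq(20))
  reads2 <- read_pairs(c(reads$fragment_id, "chim1", "chim2"),
                       c(reads$mate1, host, host),
                       c(reads$mate2, revcomp(host), revcomp(host)), TRUE)
  tab <- toy_table(reads2, k)
  expect_true(chimera %in% names(tab$counts))
  graphs <- build_all_graphs(tab, reads2)
  main <- graphs[[which.max(vapply(graphs, function(g) max(nchar(g$nodes)),
                                   integer(1)))]]
  # the chimeric branch is absent: the transcript's graph spells only tx
  expect_equal(oracle_graph_sequences(main), tx)
})

test_that("loci with disjoint k-mers give one graph each, empty table none", {
  set.seed(105)
  tx1 <- rand_seq(400)
  tx2 <- rand_seq(400)
  reads <- tiling_pairs(c(tx1, tx2), frag_len = 80, read_len = 40, step = 2)
  tab <- toy_table(reads)
  graphs <- build_all_graphs(tab, reads)
  expect_length(graphs, 2L)
  seqs <- sort(vapply(graphs, function(g) oracle_graph_sequences(g)[1],
                      character(1)))
  expect_equal(seqs, sort(c(tx1, tx2)))
  # k-mer usage is disjoint across graphs
  all_kmers <- unlist(lapply(graphs, `[[`, "kmers"))
  expect_false(anyDuplicated(all_kmers) > 0)
  # empty table
  empty <- denovotx:::new_kmer_table(structure(integer(0), names = character(0)),
                                     15L, TRUE)
  expect_length(build_all_graphs(empty, reads), 0L)
})

test_that("every edge of every graph is witnessed by a read", {
  set.seed(106)
  genes <- simulate_transcriptome(n_genes = 3,
                                  isoform_dist = c("2" = 0.5, "3" = 0.5),
                                  exon_len_range = c(300L, 500L),
                                  fpkm_range = c(30, 80))
  sim <- simulate_reads(genes, depth = 25)
  tab <- filter_errors(build_kmer_table(sim$reads, 25L))
  graphs <- build_all_graphs(tab, sim$reads)
  for (g in graphs) {
    chk <- verify_read_support(g, sim$reads)
    expect_true(all(chk$supported))
  }
})

test_that("adding an isoform's reads never removes existing junctions", {
  set.seed(107)
  toy <- skipped_exon_toy()
  reads1 <- tiling_pairs(toy$iso["inclusion"], frag_len = 80, read_len = 40,
                         step = 1)
  tab1 <- toy_table(reads1)
  g1 <- build_all_graphs(tab1, reads1)[[1]]
  reads2 <- tiling_pairs(toy$iso, frag_len = 80, read_len = 40, step = 1)
  tab2 <- toy_table(reads2)
  g2 <- build_all_graphs(tab2, reads2)[[1]]
  # every junction (k+1)-mer present before is still present after
  expect_true(all(g1$edges$junction %in%
                    c(g2$edges$junction,
                      unlist(lapply(g2$nodes, function(s) {
                        denovotx:::kmer_windows(s, g2$k + 1L)
                      })))))
  expect_true(all(oracle_graph_sequences(g1) %in% oracle_graph_sequences(g2)))
})

test_that("splicing graphs serialise to GFA", {
  set.seed(108)
  toy <- skipped_exon_toy()
  reads <- tiling_pairs(toy$iso, frag_len = 80, read_len = 40, step = 1)
  g <- build_all_graphs(toy_table(reads), reads)[[1]]
  d <- withr::local_tempdir()
  p <- write_gfa(g, file.path(d, "g.gfa"))
  lines <- readLines(p)
  expect_equal(sum(startsWith(lines, "S")), length(g$nodes))
  expect_equal(sum(startsWith(lines, "L")), nrow(g$edges))
})
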