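# The expression model is tested against direct formula evaluation and a
# brute-force posterior enumeration oracle.

mk_candidate <- function(seq, eff = NULL, frag_mu = 250) {
  list(path = "n001", sequence = seq,
       effective_length = eff %||% max(nchar(seq) - frag_mu + 1, 1))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# synthetic likelihood matrix for a two-candidate mixture: n_unique1 /
# n_unique2 uniquely-compatible fragments and n_shared ambiguous ones
# with equal likelihood under both.
mixture_L <- function(n_unique1, n_unique2, n_shared, l1 = 1e-3, l2 = 1e-3) {
  rbind(cbind(rep(l1, n_unique1), 0),
        cbind(0, rep(l2, n_unique2)),
        cbind(rep(l1, n_shared), rep(l2, n_shared)))
}

test_that("fragment likelihood follows the placement formula", {
  set.seed(301)
  flen <- list(mu = 250, sd = 25)
  tx <- rand_seq(1249)
  cand <- mk_candidate(tx)  # effective length 1000
  # a fragment of exactly modal length placed at position 101
  frag <- list(mate1 = substr(tx, 101, 200),
               mate2 = revcomp(substr(tx, 251, 350)))
  expect_equal(fragment_likelihood(frag, cand, flen),
               dnorm(250, 250, 25) / 1000)
  # an incompatible fragment scores zero
  alien <- list(mate1 = rand_seq(100), mate2 = rand_seq(100))
  expect_equal(fragment_likelihood(alien, cand, flen), 0)
  # same placement probability, effective lengths 500 vs 1000: ratio 2:1
  c500 <- mk_candidate(tx, eff = 500)
  c1000 <- mk_candidate(tx, eff = 1000)
  expect_equal(fragment_likelihood(frag, c500, flen) /
                 fragment_likelihood(frag, c1000, flen), 2)
  # a custom density function is honoured
  expect_equal(fragment_likelihood(frag, c1000, function(x) 1 * (x == 250)),
               1 / 1000)
})

test_that("likelihood matrix marks path-incompatible fragments with zero", {
  set.seed(302)
  toy <- skipped_exon_toy()
  cands <- list(mk_candidate(toy$iso[["inclusion"]], frag_mu = 80),
                mk_candidate(toy$iso[["skip"]], frag_mu = 80))
  # a fragment spanning the skip junction is incompatible with inclusion
  skip_tx <- toy$iso[["skip"]]
  jpos <- nchar(toy$L)
  frag <- read_pairs("j1", substr(skip_tx, jpos - 30, jpos + 29),
                     revcomp(substr(skip_tx, jpos + 10, jpos + 69)))
  L <- likelihood_matrix(frag, cands, list(mu = 100, sd = 15), k = 15L)
  expect_equal(L[1, 1], 0)
  expect_gt(L[1, 2], 0)
})

test_that("degenerate single-candidate state is fixed by the sweep", {
  set.seed(303)
  L <- matrix(1e-3, nrow = 10, ncol = 1)
  state <- list(c = 1L, e = 1, z = rep(1L, 10))
  for (i in 1:20) {
    state <- gibbs_sweep(state, L)
    expect_identical(state$c, 1L)
    expect_identical(state$e, 1)
    expect_identical(state$z, rep(1L, 10))
  }
})

test_that("the sampler recovers a 70/30 mixture with ambiguous fragments", {
  errs <- vapply(1:3, function(s) {
    set.seed(s)
    # 300 fragments, 20% ambiguous, true mixture (0.7, 0.3)
    L <- mixture_L(round(0.7 * 240), round(0.3 * 240), 60)
    fit <- gibbs_fit(L, sweeps = 800L, burnin = 200L)
    max(abs(fit$mean_abundance - c(0.7, 0.3)))
  }, numeric(1))
  expect_lt(max(errs), 0.08)
})

test_that("a decoy candidate without unique support is rarely called", {
  called <- vapply(1:10, function(s) {
    set.seed(s)
    L <- cbind(rep(1e-3, 60), c(rep(1e-3, 20), rep(0, 40)))
    fit <- gibbs_fit(L, sweeps = 500L, burnin = 100L)
    fit$posterior_prob[2] >= 0.5
  }, logical(1))
  expect_lte(sum(called), 2L)
})

test_that("Gibbs state frequencies match brute-force posterior enumeration", {
  set.seed(305)
  # 2 candidates, 6 fragments: 2 unique to each, 2 ambiguous
  L <- mixture_L(2, 2, 2, l1 = 2e-3, l2 = 1e-3)
  oracle <- oracle_posterior(L)
  p_both_on <- sum(oracle$probs[vapply(oracle$states, function(s) {
    all(s$c == 1)
  }, logical(1))])
  fit <- gibbs_fit(L, sweeps = 20000L, burnin = 1000L, keep_states = TRUE)
  both_on <- rowSums(fit$trace$c) == 2
  est <- mean(both_on)
  # batch-means Monte-Carlo standard error (autocorrelation-aware)
  nb <- 50L
  bm <- tapply(both_on, rep(seq_len(nb), each = length(both_on) / nb), mean)
  se <- sd(bm) / sqrt(nb)
  expect_lt(abs(est - p_both_on), 3 * se + 1e-6)
  # assignment-count distribution of candidate 1, same comparison
  for (j in 0:4) {
    p_oracle <- sum(oracle$probs[vapply(oracle$states, function(s) {
      sum(s$z == 1) == j
    }, logical(1))])
    ind <- fit$trace$n[, 1] == j
    bm <- tapply(ind, rep(seq_len(nb), each = length(ind) / nb), mean)
    expect_lt(abs(mean(ind) - p_oracle), 3 * sd(bm) / sqrt(nb) + 5e-3)
  }
})

test_that("a minor isoform with unique support survives a 95/5 mixture", {
  called <- vapply(1:10, function(s) {
    set.seed(s)
    L <- mixture_L(570, 30, 0)  # 95% / 5%, 30 unique minor fragments
    fit <- gibbs_fit(L, sweeps = 500L, burnin = 100L)
    fit$posterior_prob[2] >= 0.5
  }, logical(1))
  expect_gte(mean(called), 0.9)
})

test_that("permuting candidate order permutes call_transcripts output", {
  set.seed(306)
  toy <- skipped_exon_toy()
  reads <- tiling_pairs(toy$iso, frag_len = 80, read_len = 40, step = 2)
  tab <- filter_errors(build_kmer_table(reads, 15L))
  g <- build_all_graphs(tab, reads)[[1]]
  cs <- enumerate_candidates(g, frag_mu = 80)
  cs_rev <- cs
  cs_rev$candidates <- rev(cs$candidates)
  cfg <- list(sweeps = 300L, burnin = 50L)
  set.seed(99)
  a <- call_transcripts(g, cs, reads, flen = list(mu = 80, sd = 8),
                        config = cfg)
  set.seed(99)
  b <- call_transcripts(g, cs_rev, reads, flen = list(mu = 80, sd = 8),
                        config = cfg)
  perm <- rev(seq_along(cs$candidates))
  expect_equal(b$summary$posterior_prob, a$summary$posterior_prob[perm])
  expect_equal(b$summary$mean_abundance, a$summary$mean_abundance[perm])
  expect_setequal(b$transcripts$sequence, a$transcripts$sequence)
})

test_that("call_transcripts on the skipped-exon toy calls both isoforms", {
  set.seed(307)
  toy <- skipped_exon_toy()
  reads <- tiling_pairs(toy$iso, frag_len = 80, read_len = 40, step = 2)
  tab <- filter_errors(build_kmer_table(reads, 15L))
  g <- build_all_graphs(tab, reads)[[1]]
  cs <- enumerate_candidates(g, frag_mu = 80)
  res <- call_transcripts(g, cs, reads, flen = list(mu = 80, sd = 8),
                          config = list(sweeps = 500L, burnin = 100L,
                                        min_transcript_length = 100L))
  expect_setequal(res$transcripts$sequence, unname(toy$iso))
  expect_equal(sum(res$transcripts$abundance), 1, tolerance = 1e-9)
  # reads supporting only the skip isoform call only the skip isoform
  skip_reads <- tiling_pairs(toy$iso["skip"], frag_len = 80, read_len = 40,
                             step = 2)
  tab2 <- filter_errors(build_kmer_table(skip_reads, 15L))
  g2 <- build_all_graphs(tab2, skip_reads)[[1]]
  cs2 <- enumerate_candidates(g2, frag_mu = 80)
  res2 <- call_transcripts(g2, cs2, skip_reads,
                           flen = list(mu = 80, sd = 8),
                           config = list(sweeps = 500L, burnin = 100L,
                                         min_transcript_length = 100L))
  expect_equal(res2$transcripts$sequence, unname(toy$iso["skip"]))
})

test_that("zero mapped fragments yield an empty call list with a warning", {
  set.seed(308)
  tx <- rand_seq(400)
  reads <- tiling_pairs(tx, frag_len = 80, read_len = 40, step = 2)
  tab <- filter_errors(build_kmer_table(reads, 15L))
  g <- build_all_graphs(tab, reads)[[1]]
  cs <- enumerate_candidates(g, frag_mu = 80)
  alien <- read_pairs("x1", rand_seq(60), rand_seq(60))
  expect_warning(
    res <- call_transcripts(g, cs, alien, flen = list(mu = 80, sd = 8)),
    "no fragment")
  expect_equal(nrow(res$transcripts), 0L)
})

test_that("fragment-length estimation falls back when data are scarce", {
  est <- estimate_flen(rep(240L, 50), fallback = list(mu = 250, sd = 25))
  expect_equal(est$mu, 250)
  expect_equal(est$n, 0L)
  set.seed(309)
  lens <- round(rnorm(500, 240, 20))
  est2 <- estimate_flen(lens)
  expect_equal(est2$mu, mean(lens))
  expect_equal(est2$sd, sd(lens))
})
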