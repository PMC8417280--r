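# Shared fixtures and independent oracles for the test suite. All toy
# data are built in code; oracles are deliberately naive (enumeration,
# direct formulas) and independent of the package's implementation paths.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Error-free paired-end fragments tiling the given transcripts at every
# `step` positions: full junction coverage by construction.
tiling_pairs <- function(seqs, frag_len = 80L, read_len = 40L, step = 1L,
                         stranded = TRUE, prefix = "f") {
  m1 <- character(0); m2 <- character(0)
  for (s in seqs) {
    L <- nchar(s)
    fl <- min(frag_len, L)
    starts <- unique(c(seq(1L, L - fl + 1L, by = step), L - fl + 1L))
    rl <- min(read_len, fl)
    m1 <- c(m1, substr(rep(s, length(starts)), starts, starts + rl - 1L))
    ends <- starts + fl - 1L
    m2 <- c(m2, denovotx::revcomp(substr(rep(s, length(starts)),
                                         ends - rl + 1L, ends)))
  }
  denovotx::read_pairs(sprintf("%s%05d", prefix, seq_along(m1)), m1, m2,
                       stranded)
}

# A two-isoform skipped-exon gene: isoform 1 = L + C + R, isoform 2 = L + R.
skipped_exon_toy <- function(l = 150L, c = 60L, r = 150L) {
  L <- rand_seq(l); C <- rand_seq(c); R <- rand_seq(r)
  list(L = L, C = C, R = R,
       iso = c(inclusion = paste0(L, C, R), skip = paste0(L, R)))
}

# Independent brute-force source-to-sink path enumerator over an edge
# list (recursion over successors; no sharing with the package's DFS).
oracle_paths <- function(nodes, edges, sources = NULL) {
  succ <- function(v) sort(edges$to[edges$from == v])
  if (is.null(sources)) sources <- sort(setdiff(nodes, edges$to))
  out <- list()
  grow <- function(path) {
    s <- succ(path[length(path)])
    if (!length(s)) {
      out[[length(out) + 1L]] <<- path
    } else {
      for (w in s) grow(c(path, w))
    }
  }
  for (s in sources) grow(s)
  out
}

# Spell all source-to-sink sequences of a splicing graph via the oracle
# enumerator.
oracle_graph_sequences <- function(graph) {
  paths <- oracle_paths(names(graph$nodes), graph$edges)
  vapply(paths, function(p) {
    seqs <- graph$nodes[p]
    if (length(seqs) == 1L) return(unname(seqs))
    paste0(seqs[1], paste(substring(seqs[-1], graph$k), collapse = ""))
  }, character(1))
}

# Exhaustive k-mer counting oracle (direct window enumeration).
oracle_kmer_counts <- function(seqs, k) {
  wins <- unlist(lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  }))
  wins <- wins[!grepl("N", wins)]
  table(wins)
}

# Brute-force posterior enumeration of the expression model for small
# candidate sets: returns the exact joint distribution over (c, z) with
# the abundances integrated out.
oracle_posterior <- function(L, pi_prior = 0.5, alpha = 1) {
  T_ <- ncol(L); N <- nrow(L)
  states <- list(); probs <- numeric(0)
  cvecs <- as.matrix(expand.grid(rep(list(0:1), T_)))
  for (ci in seq_len(nrow(cvecs))) {
    cc <- cvecs[ci, ]
    on <- which(cc == 1)
    if (N > 0 && !length(on)) next
    compat <- lapply(seq_len(N), function(r) on[L[r, on] > 0])
    if (any(lengths(compat) == 0)) next
    zz <- as.matrix(expand.grid(compat))
    for (zi in seq_len(nrow(zz))) {
      z <- as.integer(zz[zi, ])
      n_t <- tabulate(z, T_)
      A <- length(on)
      logp <- sum(cc) * log(pi_prior) + (T_ - sum(cc)) * log(1 - pi_prior) +
        lgamma(A * alpha) - lgamma(A * alpha + N) +
        sum(lgamma(alpha + n_t[on]) - lgamma(alpha)) +
        sum(log(vapply(seq_len(N), function(r) L[r, z[r]], numeric(1))))
      states[[length(states) + 1L]] <- list(c = cc, z = z)
      probs <- c(probs, logp)
    }
  }
  probs <- exp(probs - max(probs))
  list(states = states, probs = probs / sum(probs))
}

# Small simulated study used by several tests (cached per session).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(20240915)
      genes <- denovotx::simulate_transcriptome(
        n_genes = 4, isoform_dist = c("1" = 0.4, "2" = 0.6),
        exon_len_range = c(300L, 500L), fpkm_range = c(20, 100))
      sim <- denovotx::simulate_reads(genes, depth = 25)
      cache <<- list(genes = genes, sim = sim)
    }
    cache
  }
})
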