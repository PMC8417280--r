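# Bayesian transcript calling.
#
# Generative model, per splicing graph with T candidate transcripts and
# N fragments:
#   c_t ~ Bernoulli(pi) i.i.d.          (hidden expression indicators)
#   e | c ~ Dirichlet(alpha) on the expressed support, e_t = 0 elsewhere
#   z_r | e ~ Categorical(e)            (fragment-to-transcript assignment)
#   r  | z_r ~ L(r, z_r)                (placement likelihood below)
#
# L(r, t) sums, over admissible placements of fragment r on candidate t,
# the fragment-length density of the implied length divided by the
# candidate's effective length. The sampler is partially collapsed: the
# expression indicators are updated with the abundances integrated out
# analytically (Dirichlet-multinomial), then abundances are redrawn given
# the assignments, then assignments given the abundances. A transcript
# with fragments assigned cannot switch off, so transcripts with unique
# read support are never lost, however low their abundance — expression
# is decided by explanatory power, not by relative expression level.

#' Placement-based likelihood of a fragment on a candidate transcript
#'
#' Mates are placed on the candidate sequence by exact-k-mer voting
#' (several k-mers per mate are looked up in the candidate; each hit
#' votes for a placement offset). For every admissible placement pair
#' (second mate not before the first, implied length between the read
#' length and the candidate length), the fragment-length density of the
#' implied length is accumulated and divided by the candidate's
#' effective length. Returns 0 for incompatible fragments.
#'
#' @param fragment A list with `mate1`, `mate2` (single fragment), or a
#'   `read_pairs` of length 1.
#' @param candidate A candidate (list with `sequence` and
#'   `effective_length`), e.g. one element of
#'   [enumerate_candidates()]`$candidates`.
#' @param flen_dist Fragment-length distribution: either a function of
#'   the implied length or a list with `mu` and `sd` (Gaussian).
#' @param k K-mer length for placement seeding (default 25).
#' @param stranded Strand-specific library (default TRUE).
#' @return Non-negative likelihood value.
#' @export
fragment_likelihood <- function(fragment, candidate, flen_dist,
                                k = 25L, stranded = TRUE) {
  dens <- as_flen_density(flen_dist)
  s1 <- fragment$mate1[1]
  s2 <- if (stranded) revcomp(fragment$mate2[1]) else fragment$mate2[1]
  pidx <- candidate_kmer_index(candidate$sequence, k)
  p1 <- place_mate(s1, pidx, k)
  p2 <- place_mate(s2, pidx, k)
  placement_likelihood(p1, p2, nchar(s1), nchar(s2),
                       nchar(candidate$sequence),
                       candidate$effective_length, dens)
}

as_flen_density <- function(flen_dist) {
  if (is.function(flen_dist)) return(flen_dist)
  function(x) stats::dnorm(x, mean = flen_dist$mu, sd = flen_dist$sd)
}

candidate_kmer_index <- function(seq, k) {
  if (nchar(seq) < k) return(new.env(parent = emptyenv()))
  wins <- kmer_windows(seq, k, drop_n = FALSE)
  sp <- split(seq_along(wins), wins)
  list2env(sp, envir = new.env(hash = TRUE, parent = emptyenv(),
                               size = max(29L, length(sp))))
}

# Sampled k-mer offsets along a mate (about one every 12 bases).
mate_offsets <- function(len, k) {
  if (len < k) return(integer(0))
  unique(c(seq(1L, len - k + 1L, by = 12L), len - k + 1L))
}

# Candidate placement offsets (1-based start of the mate on the
# transcript). Every sampled k-mer that matches anywhere must vote for
# the same offset: a mate spanning a junction absent from the candidate
# splits its votes and is rejected as incompatible. (Errors make k-mers
# miss entirely, which is tolerated; they do not mis-vote.)
place_mate <- function(s, pidx, k) {
  place_kmers(mate_kmers(s, k), pidx)
}

placement_likelihood <- function(p1, p2, n1, n2, tlen, eff_len, dens) {
  if (!length(p1) || !length(p2)) return(0)
  total <- 0
  for (a in p1) {
    for (b in p2) {
      if (b < a) next
      ilen <- b + n2 - a
      if (ilen > tlen || ilen < max(n1, n2)) next
      total <- total + dens(ilen)
    }
  }
  total / max(eff_len, 1)
}

#' Likelihood matrix of fragments against a candidate set
#'
#' @param reads A `read_pairs` object (the fragments of one graph).
#' @param candidates A `candidate_set` (or plain list of candidates).
#' @param flen_dist Fragment-length distribution (see
#'   [fragment_likelihood()]).
#' @param k Placement k-mer length.
#' @return Numeric matrix (fragments x candidates); rows that are all
#'   zero correspond to fragments incompatible with every candidate.
#' @export
likelihood_matrix <- function(reads, candidates, flen_dist, k = 25L) {
  cands <- if (inherits(candidates, "candidate_set")) {
    candidates$candidates
  } else {
    candidates
  }
  dens <- as_flen_density(flen_dist)
  n <- length(reads)
  T_ <- length(cands)
  L <- matrix(0, nrow = n, ncol = T_)
  s1v <- reads$mate1
  s2v <- if (reads$stranded) revcomp(reads$mate2) else reads$mate2
  # sampled k-mers per mate, extracted once and reused for every candidate
  km1 <- lapply(s1v, mate_kmers, k = k)
  km2 <- lapply(s2v, mate_kmers, k = k)
  for (j in seq_len(T_)) {
    seq <- cands[[j]]$sequence
    pidx <- candidate_kmer_index(seq, k)
    tlen <- nchar(seq)
    eff <- cands[[j]]$effective_length
    for (i in seq_len(n)) {
      p1 <- place_kmers(km1[[i]], pidx)
      if (!length(p1)) next
      p2 <- place_kmers(km2[[i]], pidx)
      if (!length(p2)) next
      L[i, j] <- placement_likelihood(p1, p2, nchar(s1v[i]), nchar(s2v[i]),
                                      tlen, eff, dens)
    }
  }
  L
}

# pre-extracted sampled k-mers of one mate, with their offsets
mate_kmers <- function(s, k) {
  offs <- mate_offsets(nchar(s), k)
  list(w = substring(s, offs, offs + k - 1L), offs = offs)
}

place_kmers <- function(km, pidx) {
  votes <- integer(0)
  n_hit <- 0L
  for (i in seq_along(km$offs)) {
    hit <- get0(km$w[i], envir = pidx, inherits = FALSE)
    if (!is.null(hit)) {
      n_hit <- n_hit + 1L
      votes <- c(votes, hit - km$offs[i] + 1L)
    }
  }
  if (!n_hit) return(integer(0))
  u <- unique(votes)
  if (length(u) == 1L) {
    if (length(votes) == n_hit) return(u) else return(integer(0))
  }
  u[tabulate(match(votes, u)) == n_hit]
}

#' Estimate the fragment-length distribution from unique placements
#'
#' Fragments placed uniquely on single-candidate graphs give implied
#' lengths; their mean and standard deviation parameterise the Gaussian
#' fragment-length model. With fewer than `min_n` unique placements the
#' configured fallback is returned.
#'
#' @param lengths Integer vector of implied fragment lengths.
#' @param fallback List with `mu`, `sd` used when data are insufficient.
#' @param min_n Minimum number of placements to trust (default 100).
#' @return List with `mu`, `sd`, and `n` (placements used; 0 = fallback).
#' @export
estimate_flen <- function(lengths, fallback = list(mu = 250, sd = 25),
                          min_n = 100L) {
  lengths <- lengths[is.finite(lengths)]
  if (length(lengths) < min_n) {
    return(list(mu = fallback$mu, sd = fallback$sd, n = 0L))
  }
  list(mu = mean(lengths), sd = max(stats::sd(lengths), 1), n = length(lengths))
}

# Implied fragment lengths of uniquely-placed fragments on a single
# candidate sequence.
implied_lengths <- function(reads, candidate, k = 25L) {
  pidx <- candidate_kmer_index(candidate$sequence, k)
  s1v <- reads$mate1
  s2v <- if (reads$stranded) revcomp(reads$mate2) else reads$mate2
  out <- integer(0)
  for (i in seq_along(s1v)) {
    p1 <- place_mate(s1v[i], pidx, k)
    p2 <- place_mate(s2v[i], pidx, k)
    if (length(p1) == 1L && length(p2) == 1L && p2 >= p1) {
      il <- p2 + nchar(s2v[i]) - p1
      if (il <= nchar(candidate$sequence)) out <- c(out, il)
    }
  }
  out
}

#' One sweep of the partially collapsed Gibbs sampler
#'
#' Updates, in order: each expression indicator `c_t` from its full
#' conditional given the assignments with the abundances integrated out
#' (a transcript with assigned fragments stays on — fragments whose only
#' compatible transcripts are off force those transcripts on through
#' their assignments); the abundance vector `e` from
#' Dirichlet(alpha + counts) on the expressed support; and all
#' assignments `z_r` proportional to `e_t L(r, t)` over expressed
#' candidates. All conditionals are computed in log space where needed;
#' no NaN is ever produced.
#'
#' @param state List with `c` (0/1 vector), `e` (abundances), `z`
#'   (assignment indices).
#' @param L Likelihood matrix (fragments x candidates).
#' @param hyper List with `pi` (prior expression probability) and
#'   `alpha` (Dirichlet concentration).
#' @return Updated state.
#' @export
gibbs_sweep <- function(state, L, hyper = list(pi = 0.5, alpha = 1)) {
  T_ <- ncol(L)
  N <- nrow(L)
  cc <- state$c
  z <- state$z
  pi_ <- hyper$pi
  alpha <- hyper$alpha
  n_t <- tabulate(z, T_)
  log_prior_odds <- log(pi_) - log1p(-pi_)
  for (t in seq_len(T_)) {
    if (n_t[t] > 0L) {
      cc[t] <- 1L
      next
    }
    A_off <- sum(cc) - cc[t]
    if (A_off == 0L && N > 0L) {
      cc[t] <- 1L  # at least one transcript must explain the fragments
      next
    }
    # Dirichlet-multinomial marginal ratio for adding an empty component
    lr <- if (N == 0L) 0 else {
      (lgamma((A_off + 1) * alpha) - lgamma((A_off + 1) * alpha + N)) -
        (lgamma(A_off * alpha) - lgamma(A_off * alpha + N))
    }
    p_on <- stats::plogis(log_prior_odds + lr)
    cc[t] <- as.integer(stats::runif(1) < p_on)
  }
  on <- which(cc == 1L)
  e <- numeric(T_)
  if (length(on)) {
    g <- stats::rgamma(length(on), shape = alpha + n_t[on])
    g[g == 0] <- .Machine$double.xmin
    e[on] <- g / sum(g)
  }
  if (N > 0L && length(on)) {
    W <- L[, on, drop = FALSE] * rep(e[on], each = N)
    cs <- W
    if (ncol(cs) > 1L) {
      for (j in 2:ncol(cs)) cs[, j] <- cs[, j - 1L] + cs[, j]
    }
    tot <- cs[, ncol(cs)]
    u <- stats::runif(N) * tot
    pick <- max.col(cs >= u, ties.method = "first")
    z <- on[pick]
  }
  list(c = cc, e = e, z = z)
}

#' Fit the expression model to a likelihood matrix by Gibbs sampling
#'
#' Runs burn-in plus sampling sweeps of [gibbs_sweep()] and accumulates
#' posterior means of the expression indicators and abundances.
#' Candidates are processed in a canonical internal order (sorted by
#' sequence when available), so permuting the input order permutes the
#' outputs identically.
#'
#' @param L Likelihood matrix (fragments x candidates). Rows that are
#'   entirely zero are dropped (with a message) before fitting.
#' @param pi_prior Prior expression probability (default 0.5).
#' @param alpha Dirichlet concentration (default 1).
#' @param sweeps Kept sweeps (default 2000).
#' @param burnin Discarded initial sweeps (default 500).
#' @param keep_states Retain per-sweep `c` and assignment counts (for
#'   diagnostics; default FALSE).
#' @return List of class `gibbs_fit`: `posterior_prob`,
#'   `mean_abundance`, `sweeps`, `burnin`, `n_fragments`,
#'   `n_dropped`, and optionally `trace`.
#' @export
gibbs_fit <- function(L, pi_prior = 0.5, alpha = 1, sweeps = 2000L,
                      burnin = 500L, keep_states = FALSE) {
  stopifnot(ncol(L) >= 1L)
  ok <- rowSums(L) > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message(n_dropped, " fragment(s) incompatible with every candidate; dropped")
  }
  L <- L[ok, , drop = FALSE]
  T_ <- ncol(L)
  N <- nrow(L)
  hyper <- list(pi = pi_prior, alpha = alpha)
  state <- init_state(L)
  acc_c <- numeric(T_)
  acc_e <- numeric(T_)
  trace_c <- if (keep_states) matrix(0L, nrow = sweeps, ncol = T_)
  trace_n <- if (keep_states) matrix(0L, nrow = sweeps, ncol = T_)
  total <- burnin + sweeps
  for (s in seq_len(total)) {
    state <- gibbs_sweep(state, L, hyper)
    if (s > burnin) {
      acc_c <- acc_c + state$c
      acc_e <- acc_e + state$e
      if (keep_states) {
        trace_c[s - burnin, ] <- state$c
        trace_n[s - burnin, ] <- tabulate(state$z, T_)
      }
    }
  }
  out <- list(posterior_prob = acc_c / sweeps,
              mean_abundance = acc_e / sweeps,
              sweeps = sweeps, burnin = burnin,
              n_fragments = N, n_dropped = n_dropped)
  if (keep_states) out$trace <- list(c = trace_c, n = trace_n)
  structure(out, class = "gibbs_fit")
}

init_state <- function(L) {
  T_ <- ncol(L)
  N <- nrow(L)
  z <- integer(N)
  if (N > 0L) {
    for (i in seq_len(N)) {
      w <- L[i, ]
      z[i] <- sample.int(T_, 1L, prob = w)
    }
  }
  list(c = rep(1L, T_), e = rep(1 / T_, T_), z = z)
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat("gibbs_fit:", length(x$posterior_prob), "candidates |",
      x$n_fragments, "fragments |", x$sweeps, "sweeps after",
      x$burnin, "burn-in\n")
  invisible(x)
}

#' Call expressed transcripts for one splicing graph
#'
#' Computes the likelihood matrix of the graph's fragments against its
#' candidates, fits the expression model by Gibbs sampling, and calls a
#' transcript expressed when its posterior expression probability reaches
#' `call_threshold`. Abundances of called transcripts are renormalised to
#' sum to one within the graph.
#'
#' @param graph A `splicing_graph`.
#' @param candidates A `candidate_set` for the graph.
#' @param fragments A `read_pairs` with the fragments assigned to the
#'   graph.
#' @param flen Fragment-length distribution (list with `mu`, `sd`).
#' @param config List of model settings: `pi_prior`, `alpha`, `sweeps`,
#'   `burnin`, `call_threshold`, `min_transcript_length`.
#' @return List with `transcripts` (data frame: transcript_id, sequence,
#'   graph_id, abundance, posterior_expression) and `summary` (per-
#'   candidate posterior table).
#' @export
call_transcripts <- function(graph, candidates, fragments,
                             flen = list(mu = 250, sd = 25),
                             config = list()) {
  cfg <- utils::modifyList(
    list(pi_prior = 0.5, alpha = 1, sweeps = 2000L, burnin = 500L,
         call_threshold = 0.5, min_transcript_length = 200L), config)
  cands <- candidates$candidates
  stopifnot(length(cands) >= 1L)
  seqs <- vapply(cands, `[[`, character(1), "sequence")
  ord <- lex_order(seqs)  # canonical order: label-invariant inference
  L <- likelihood_matrix(fragments, cands[ord], flen, k = graph$k)
  empty <- data.frame(transcript_id = character(0), sequence = character(0),
                      graph_id = character(0), abundance = numeric(0),
                      posterior_expression = numeric(0))
  if (nrow(L) == 0L || all(L == 0)) {
    warning("graph ", graph$graph_id,
            ": no fragment compatible with any candidate; nothing called")
    summ <- data.frame(candidate_id = candidate_ids(graph, seq_along(cands)),
                       posterior_prob = NA_real_, mean_abundance = NA_real_)
    return(list(transcripts = empty, summary = summ))
  }
  fit <- gibbs_fit(L, pi_prior = cfg$pi_prior, alpha = cfg$alpha,
                   sweeps = cfg$sweeps, burnin = cfg$burnin)
  post <- numeric(length(cands))
  abun <- numeric(length(cands))
  post[ord] <- fit$posterior_prob
  abun[ord] <- fit$mean_abundance
  called <- which(post >= cfg$call_threshold &
                    nchar(seqs) >= cfg$min_transcript_length)
  rel <- if (length(called) && sum(abun[called]) > 0) {
    abun[called] / sum(abun[called])
  } else {
    rep_len(0, length(called))
  }
  ids <- candidate_ids(graph, seq_along(cands))
  transcripts <- data.frame(
    transcript_id = ids[called],
    sequence = seqs[called],
    graph_id = graph$graph_id,
    abundance = rel,
    posterior_expression = post[called],
    row.names = NULL)
  summary <- data.frame(candidate_id = ids, posterior_prob = post,
                        mean_abundance = abun, row.names = NULL)
  list(transcripts = transcripts, summary = summary)
}

candidate_ids <- function(graph, idx) {
  sprintf("%s.t%02d", graph$graph_id, idx)
}
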