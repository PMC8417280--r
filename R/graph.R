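# Splicing-graph construction.
#
# Strategy: (1) pick the most frequent high-entropy k-mer as a seed;
# (2) extend it greedily in both directions through the k-mer table;
# (3) when overlap extension stalls, bridge coverage dips with the mate
# sequences of fragments anchored on the contig end; (4) open branches at
# positions with alternative extensions, but only where a read witnesses
# the alternative junction; (5) condense the used k-mer set into a
# unitig graph whose adjacencies are gated on read support, so that every
# surviving edge is spanned by at least one read.

BASES <- c("A", "C", "G", "T")

rc1 <- function(x) {
  # scalar reverse complement without DNAStringSet overhead
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Mutable assembly state shared by the extension routines.
asm_state <- function(table, reads = NULL, used = character(0),
                      branch_cap = 20L) {
  st <- new.env(parent = emptyenv())
  st$k <- table$k
  st$stranded <- table$stranded
  st$counts <- table$counts
  st$cenv <- new.env(hash = TRUE, parent = emptyenv(),
                     size = max(29L, length(table$counts)))
  nm <- names(table$counts)
  for (i in seq_along(nm)) assign(nm[i], table$counts[[i]], envir = st$cenv)
  st$used <- new.env(hash = TRUE, parent = emptyenv())
  for (u in used) assign(kkey(st, u), TRUE, envir = st$used)
  st$extra <- new.env(hash = TRUE, parent = emptyenv())
  st$branch_cap <- branch_cap
  st$pe_min_overlap <- table$k - 1L
  if (!is.null(reads)) attach_read_index(st, reads)
  st
}

kkey <- function(st, kmer) {
  if (st$stranded) kmer else {
    r <- rc1(kmer)
    if (r < kmer) r else kmer
  }
}

# Junction tables and anchor indices derived from the reads.
attach_read_index <- function(st, reads) {
  k <- st$k
  st$seq1 <- reads$mate1
  st$seq2 <- if (reads$stranded) revcomp(reads$mate2) else reads$mate2
  jw <- kmer_windows(c(st$seq1, st$seq2), k + 1L)
  if (!st$stranded) jw <- pmin(jw, revcomp(jw))
  jc <- count_strings(jw)
  st$jenv <- new.env(hash = TRUE, parent = emptyenv(),
                     size = max(29L, length(jc)))
  nm <- names(jc)
  for (i in seq_along(nm)) assign(nm[i], jc[[i]], envir = st$jenv)
  # k-mers at which a read begins / ends (branch-opening fallback)
  both <- c(st$seq1, st$seq2)
  both <- both[nchar(both) >= k]
  ini <- substr(both, 1L, k)
  fin <- substr(both, nchar(both) - k + 1L, nchar(both))
  ini <- ini[!grepl("N", ini, fixed = TRUE)]
  fin <- fin[!grepl("N", fin, fixed = TRUE)]
  st$init_env <- list_to_count_env(ini)
  st$fin_env <- list_to_count_env(fin)
  # anchor index: k-mer -> fragment indices, per mate
  st$idx1 <- anchor_env(st$seq1, k)
  st$idx2 <- anchor_env(st$seq2, k)
  invisible(st)
}

list_to_count_env <- function(x) {
  cc <- count_strings(x)
  e <- new.env(hash = TRUE, parent = emptyenv(), size = max(29L, length(cc)))
  nm <- names(cc)
  for (i in seq_along(nm)) assign(nm[i], cc[[i]], envir = e)
  e
}

anchor_env <- function(seqs, k) {
  keep <- which(nchar(seqs) >= k)
  if (!length(keep)) return(new.env(parent = emptyenv()))
  nw <- nchar(seqs[keep]) - k + 1L
  wins <- kmer_windows(seqs[keep], k, drop_n = FALSE)
  ids <- rep(keep, times = nw)
  ok <- !grepl("N", wins, fixed = TRUE)
  sp <- split(ids[ok], wins[ok])
  list2env(lapply(sp, unique), envir = new.env(hash = TRUE, parent = emptyenv(),
                                               size = max(29L, length(sp))))
}

kmer_free <- function(st, kmer) {
  key <- kkey(st, kmer)
  cnt <- get0(key, envir = st$cenv, inherits = FALSE)
  if (is.null(cnt) || !is.null(get0(key, envir = st$used, inherits = FALSE))) {
    return(0L)
  }
  cnt
}

mark_used <- function(st, kmer) {
  assign(kkey(st, kmer), TRUE, envir = st$used)
}

unmark_used <- function(st, kmer) {
  key <- kkey(st, kmer)
  if (!is.null(get0(key, envir = st$used, inherits = FALSE))) {
    rm(list = key, envir = st$used)
  }
}

junction_count <- function(st, jstr) {
  key <- if (st$stranded) jstr else {
    r <- rc1(jstr)
    if (r < jstr) r else jstr
  }
  cnt <- get0(key, envir = st$jenv, inherits = FALSE)
  if (is.null(cnt)) cnt <- get0(jstr, envir = st$extra, inherits = FALSE)
  if (is.null(cnt)) 0L else cnt
}

#' Select the next seed k-mer
#'
#' Returns the unused k-mer with the highest count among those with
#' Shannon entropy above `min_entropy` and count above `min_count`; ties
#' are broken lexicographically. `NULL` when no k-mer qualifies.
#'
#' @param table A filtered `kmer_table`.
#' @param used Character vector of already-consumed k-mers.
#' @param min_entropy Entropy gate in bits (default 1.5).
#' @param min_count Seeds must have count strictly above this (default 1).
#' @return A single k-mer, or `NULL`.
#' @export
select_seed <- function(table, used = character(0), min_entropy = 1.5,
                        min_count = 1L) {
  counts <- table$counts
  cand <- counts[counts > min_count]
  if (length(used)) cand <- cand[!(names(cand) %in% used)]
  if (!length(cand)) return(NULL)
  cand <- cand[shannon_entropy(names(cand)) > min_entropy]
  if (!length(cand)) return(NULL)
  o <- lex_order(-cand, names(cand))
  names(cand)[o[1]]
}

# Greedy rightward extension; returns list(ext = appended bases,
# coverage = counts of consumed k-mers).
core_extend_right <- function(st, seq) {
  k <- st$k
  n <- nchar(seq)
  suffix <- substr(seq, n - k + 2L, n)
  bases <- character(0)
  cov <- integer(0)
  repeat {
    best_b <- NULL
    best_c <- 0L
    for (b in BASES) {
      cnt <- kmer_free(st, paste0(suffix, b))
      if (cnt > best_c) {
        best_c <- cnt
        best_b <- b
      }
    }
    if (is.null(best_b)) break
    mark_used(st, paste0(suffix, best_b))
    bases <- c(bases, best_b)
    cov <- c(cov, best_c)
    suffix <- paste0(substr(suffix, 2L, k - 1L), best_b)
  }
  list(ext = paste(bases, collapse = ""), coverage = cov)
}

core_extend_left <- function(st, seq) {
  k <- st$k
  prefix <- substr(seq, 1L, k - 1L)
  bases <- character(0)
  cov <- integer(0)
  repeat {
    best_b <- NULL
    best_c <- 0L
    for (b in BASES) {
      cnt <- kmer_free(st, paste0(b, prefix))
      if (cnt > best_c) {
        best_c <- cnt
        best_b <- b
      }
    }
    if (is.null(best_b)) break
    mark_used(st, paste0(best_b, prefix))
    bases <- c(best_b, bases)
    cov <- c(best_c, cov)
    prefix <- paste0(best_b, substr(prefix, 1L, k - 2L))
  }
  list(ext = paste(bases, collapse = ""), coverage = cov)
}

#' Extend a seed k-mer into a contig by greedy overlap extension
#'
#' Starting from `seed`, repeatedly appends (and prepends) the base whose
#' implied k-mer has the highest unused count in the table, until no
#' unused overlapping k-mer remains in either direction. All consumed
#' k-mers are marked used.
#'
#' @param seed Seed k-mer (must be present in `table` and not in `used`).
#' @param table A filtered `kmer_table`.
#' @param used Character vector of k-mers consumed by earlier contigs.
#' @return An object of class `contig`: list with `sequence`,
#'   `kmer_coverage` (one count per constituent k-mer) and `kmers`.
#' @export
extend_contig <- function(seed, table, used = character(0)) {
  st <- asm_state(table, used = used)
  if (kmer_free(st, seed) == 0L) stop("seed k-mer absent from table or already used")
  ctg <- core_build_contig(st, seed)
  new_contig(ctg$sequence, st)
}

core_build_contig <- function(st, seed) {
  seed_cov <- kmer_free(st, seed)
  mark_used(st, seed)
  r <- core_extend_right(st, seed)
  l <- core_extend_left(st, seed)
  seq <- paste0(l$ext, seed, r$ext)
  # alternate paired-end bridging with further greedy extension
  if (!is.null(st$idx1)) {
    for (i in seq_len(50L)) {
      grew <- FALSE
      pr <- core_pe_right(st, seq)
      if (pr$grew) {
        seq <- pr$seq
        seq <- paste0(seq, core_extend_right(st, seq)$ext)
        grew <- TRUE
      }
      pl <- core_pe_left(st, seq)
      if (pl$grew) {
        seq <- pl$seq
        seq <- paste0(core_extend_left(st, seq)$ext, seq)
        grew <- TRUE
      }
      if (!grew) break
    }
  }
  list(sequence = seq, seed_cov = seed_cov)
}

new_contig <- function(seq, st) {
  wins <- kmer_windows(seq, st$k, drop_n = FALSE)
  cov <- vapply(wins, function(w) {
    cnt <- get0(kkey(st, w), envir = st$cenv, inherits = FALSE)
    if (is.null(cnt)) 0L else as.integer(cnt)
  }, integer(1), USE.NAMES = FALSE)
  structure(list(sequence = seq, kmer_coverage = cov, kmers = wins),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat("contig:", nchar(x$sequence), "bp | mean k-mer coverage",
      round(mean(x$kmer_coverage), 1), "\n")
  invisible(x)
}

# Paired-end bridging on the right end: a fragment whose first mate is
# anchored on the contig tail and whose second mate overlaps the contig
# suffix and extends beyond it spells the continuation across a coverage
# dip. Only mate sequence is used (no N filling); the bridge is rejected
# if it would run into k-mers already consumed elsewhere.
core_pe_right <- function(st, seq) {
  k <- st$k
  n <- nchar(seq)
  ov <- st$pe_min_overlap
  if (n < ov) return(list(grew = FALSE, seq = seq))
  tail_seq <- substr(seq, max(1L, n - 149L), n)
  frags <- anchored_fragments(st$idx1, tail_seq, k)
  if (!length(frags)) return(list(grew = FALSE, seq = seq))
  key <- substr(seq, n - ov + 1L, n)
  best <- NULL
  for (f in frags) {
    s2 <- st$seq2[f]
    p <- regexpr(key, s2, fixed = TRUE)[1]
    if (p < 0L) next
    ext <- substr(s2, p + ov, nchar(s2))
    if (nchar(ext) == 0L) next
    wins <- kmer_windows(paste0(key, ext), k, drop_n = FALSE)
    if (bridge_blocked(st, wins)) next
    if (is.null(best) || nchar(ext) > nchar(best) ||
        (nchar(ext) == nchar(best) && ext < best)) {
      best <- ext
    }
  }
  if (is.null(best)) return(list(grew = FALSE, seq = seq))
  consume_bridge(st, paste0(key, best))
  list(grew = TRUE, seq = paste0(seq, best))
}

core_pe_left <- function(st, seq) {
  k <- st$k
  ov <- st$pe_min_overlap
  if (nchar(seq) < ov) return(list(grew = FALSE, seq = seq))
  head_seq <- substr(seq, 1L, min(nchar(seq), 150L))
  frags <- anchored_fragments(st$idx2, head_seq, k)
  if (!length(frags)) return(list(grew = FALSE, seq = seq))
  key <- substr(seq, 1L, ov)
  best <- NULL
  for (f in frags) {
    s1 <- st$seq1[f]
    m <- gregexpr(key, s1, fixed = TRUE)[[1]]
    p <- m[length(m)]
    if (p <= 1L) next
    ext <- substr(s1, 1L, p - 1L)
    wins <- kmer_windows(paste0(ext, key), k, drop_n = FALSE)
    if (bridge_blocked(st, wins)) next
    if (is.null(best) || nchar(ext) > nchar(best) ||
        (nchar(ext) == nchar(best) && ext < best)) {
      best <- ext
    }
  }
  if (is.null(best)) return(list(grew = FALSE, seq = seq))
  consume_bridge(st, paste0(best, key))
  list(grew = TRUE, seq = paste0(best, seq))
}

anchored_fragments <- function(idx, region, k) {
  if (nchar(region) < k) return(integer(0))
  wins <- unique(kmer_windows(region, k))
  hits <- lapply(wins, function(w) get0(w, envir = idx, inherits = FALSE))
  ids <- unique(unlist(hits, use.names = FALSE))
  if (is.null(ids)) integer(0) else sort(ids)
}

bridge_blocked <- function(st, wins) {
  any_table <- FALSE
  for (w in wins) {
    key <- kkey(st, w)
    if (!is.null(get0(key, envir = st$used, inherits = FALSE))) return(TRUE)
    if (!is.null(get0(key, envir = st$cenv, inherits = FALSE))) any_table <- TRUE
  }
  !any_table  # require at least one unused table k-mer as continuation
}

consume_bridge <- function(st, spanning) {
  for (w in kmer_windows(spanning, st$k, drop_n = FALSE)) {
    key <- kkey(st, w)
    if (!is.null(get0(key, envir = st$cenv, inherits = FALSE))) mark_used(st, w)
  }
}

#' Resume contig extension with paired-end information
#'
#' When greedy overlap extension has stalled, fragments with one mate
#' anchored on the contig end (exact k-mer match) and the other mate
#' overlapping the contig terminus and extending beyond it are used to
#' spell the continuation. The contig is returned unchanged when no such
#' fragment exists, or when the far mate would run into already-used
#' k-mers (no circularisation).
#'
#' @param contig A `contig` object.
#' @param reads A `read_pairs` object.
#' @param table The filtered `kmer_table`.
#' @param used Character vector of consumed k-mers (should include the
#'   contig's own k-mers).
#' @return A `contig`, possibly extended on either side.
#' @export
paired_end_extend <- function(contig, reads, table, used = contig$kmers) {
  st <- asm_state(table, reads = reads, used = used)
  if (!table$stranded) {
    return(contig)  # orientation of mates is ambiguous without strand info
  }
  seq <- contig$sequence
  repeat {
    grew <- FALSE
    pr <- core_pe_right(st, seq)
    if (pr$grew) {
      seq <- paste0(pr$seq, core_extend_right(st, pr$seq)$ext)
      grew <- TRUE
    }
    pl <- core_pe_left(st, seq)
    if (pl$grew) {
      seq <- pl$seq
      seq <- paste0(core_extend_left(st, seq)$ext, seq)
      grew <- TRUE
    }
    if (!grew) break
  }
  new_contig(seq, st)
}

# Scan a contig for read-supported alternative extensions; returns a list
# of branch contig sequences (extension is performed immediately, marking
# k-mers used).
scan_branches <- function(st, seq, counter) {
  k <- st$k
  branches <- character(0)
  if (is.null(st$jenv)) return(branches)  # no reads, no read-guided branches
  wins <- kmer_windows(seq, k, drop_n = FALSE)
  nw <- length(wins)
  for (i in seq_len(nw)) {
    if (counter$opened >= st$branch_cap) break
    x <- wins[i]
    nxt <- if (i < nw) substr(seq, i + k, i + k) else ""
    sfx <- substr(x, 2L, k)
    for (b in BASES) {
      if (b == nxt) next
      cand <- paste0(sfx, b)
      if (kmer_free(st, cand) == 0L) next
      jstr <- paste0(x, b)
      supported <- junction_count(st, jstr) > 0L
      fb <- get0(cand, envir = st$init_env, inherits = FALSE)
      if (!supported && is.null(fb)) next
      if (!supported) assign(jstr, fb, envir = st$extra)
      mark_used(st, cand)
      ext <- core_extend_right(st, cand)
      bseq <- paste0(cand, ext$ext)
      pr <- core_pe_right(st, bseq)
      if (pr$grew) bseq <- paste0(pr$seq, core_extend_right(st, pr$seq)$ext)
      branches <- c(branches, bseq)
      counter$opened <- counter$opened + 1L
      if (counter$opened >= st$branch_cap) break
    }
    if (counter$opened >= st$branch_cap) break
    prv <- if (i > 1L) substr(seq, i - 1L, i - 1L) else ""
    pfx <- substr(x, 1L, k - 1L)
    for (b in BASES) {
      if (b == prv) next
      cand <- paste0(b, pfx)
      if (kmer_free(st, cand) == 0L) next
      jstr <- paste0(b, x)
      supported <- junction_count(st, jstr) > 0L
      fb <- get0(cand, envir = st$fin_env, inherits = FALSE)
      if (!supported && is.null(fb)) next
      if (!supported) assign(jstr, fb, envir = st$extra)
      mark_used(st, cand)
      ext <- core_extend_left(st, cand)
      bseq <- paste0(ext$ext, cand)
      pl <- core_pe_left(st, bseq)
      if (pl$grew) {
        bseq <- pl$seq
        bseq <- paste0(core_extend_left(st, bseq)$ext, bseq)
      }
      branches <- c(branches, bseq)
      counter$opened <- counter$opened + 1L
      if (counter$opened >= st$branch_cap) break
    }
  }
  branches
}

#' Build one splicing graph by branch extension around a main contig
#'
#' Every internal position of the main contig (and, recursively, of each
#' opened branch, up to the opening cap) is inspected for alternative
#' k-mer extensions. A branch is opened only when a read witnesses the
#' alternative junction — either a read overlapping the contig that
#' contains the junction (k+1)-mer, or, failing that, a read that begins
#' or ends exactly at the alternative k-mer. Branches are extended like
#' contigs and stop on reaching a k-mer already used in the current
#' graph, closing back into it as a junction edge. The used k-mer set is
#' then condensed into a unitig graph; shared sequence becomes shared
#' nodes.
#'
#' @param main A `contig` (the main contig of the locus).
#' @param table Filtered `kmer_table`.
#' @param reads A `read_pairs` object (read-guidance and paired-end
#'   bridging); may be `NULL` for toy k-mer-only graphs, in which case no
#'   branch can be read-supported and the graph has a single node.
#' @param used K-mers consumed so far (defaults to the main contig's).
#' @param branch_cap Maximum branch openings per graph (default 20).
#' @return A `splicing_graph`.
#' @export
branch_extend <- function(main, table, reads = NULL, used = main$kmers,
                          branch_cap = 20L) {
  st <- asm_state(table, reads = reads, used = used, branch_cap = branch_cap)
  core_branch_graph(st, main$sequence, graph_id = "g1")
}

core_branch_graph <- function(st, main_seq, graph_id) {
  counter <- new.env(parent = emptyenv())
  counter$opened <- 0L
  contigs <- main_seq
  qi <- 1L
  while (qi <= length(contigs) && counter$opened < st$branch_cap) {
    contigs <- c(contigs, scan_branches(st, contigs[qi], counter))
    qi <- qi + 1L
  }
  condense_graph(st, contigs, seed_seq = main_seq, graph_id = graph_id)
}

# Condense the k-mer set of a locus into a unitig (splicing) graph.
# Adjacency between k-mers is admitted only when the junction (k+1)-mer
# is witnessed by a read (or was opened through the read-end fallback).
condense_graph <- function(st, contig_seqs, seed_seq, graph_id) {
  k <- st$k
  kS <- unique(unlist(lapply(contig_seqs, kmer_windows, k = k,
                             drop_n = FALSE), use.names = FALSE))
  kS <- lex_sort(kS)
  m <- length(kS)
  senv <- index_env(kS)
  no_reads <- is.null(st$jenv)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    x <- kS[i]
    sfx <- substr(x, 2L, k)
    nb <- integer(0)
    for (b in BASES) {
      j <- get0(paste0(sfx, b), envir = senv, inherits = FALSE)
      if (is.null(j)) next
      if (no_reads) {
        # without reads only unambiguous chains are linked
        nb <- c(nb, j)
      } else if (junction_count(st, paste0(x, b)) > 0L) {
        nb <- c(nb, j)
      }
    }
    if (no_reads && length(nb) > 1L) nb <- integer(0)
    out[[i]] <- nb
  }
  indeg <- tabulate(unlist(out, use.names = FALSE), m)
  outdeg <- lengths(out)
  start <- indeg != 1L
  for (i in which(outdeg > 1L)) start[out[[i]]] <- TRUE
  visited <- logical(m)
  chains <- list()
  for (s in which(start)) {
    if (visited[s]) next
    chain <- s
    visited[s] <- TRUE
    cur <- s
    while (outdeg[cur] == 1L) {
      nxt <- out[[cur]][1]
      if (start[nxt] || visited[nxt]) break
      chain <- c(chain, nxt)
      visited[nxt] <- TRUE
      cur <- nxt
    }
    chains[[length(chains) + 1L]] <- chain
  }
  # pure cycles (no start k-mer): walk from the smallest unvisited k-mer
  while (any(!visited)) {
    s <- which(!visited)[1]
    chain <- s
    visited[s] <- TRUE
    cur <- s
    while (outdeg[cur] == 1L && !visited[out[[cur]][1]]) {
      cur <- out[[cur]][1]
      chain <- c(chain, cur)
      visited[cur] <- TRUE
    }
    chains[[length(chains) + 1L]] <- chain
  }
  spell <- vapply(chains, function(ch) {
    paste0(kS[ch[1]],
           paste(substr(kS[ch[-1]], k, k), collapse = ""))
  }, character(1))
  u_of <- integer(m)
  for (u in seq_along(chains)) u_of[chains[[u]]] <- u
  e_from <- integer(0); e_to <- integer(0); e_sup <- integer(0)
  e_junc <- character(0)
  for (u in seq_along(chains)) {
    endk <- chains[[u]][length(chains[[u]])]
    for (y in out[[endk]]) {
      jstr <- paste0(kS[endk], substr(kS[y], k, k))
      e_from <- c(e_from, u)
      e_to <- c(e_to, u_of[y])
      e_sup <- c(e_sup, if (no_reads) 1L else junction_count(st, jstr))
      e_junc <- c(e_junc, jstr)
    }
  }
  # keep the weakly-connected component containing the seed contig
  nseed <- u_of[get0(substr(seed_seq, 1L, k), envir = senv, inherits = FALSE)]
  comp <- component_of(length(chains), e_from, e_to, nseed)
  dropped <- setdiff(seq_along(chains), comp)
  for (u in dropped) {
    for (i in chains[[u]]) unmark_used(st, kS[i])
  }
  keep <- sort(comp)
  remap <- integer(length(chains))
  # deterministic node ids: ordered by node sequence
  o <- keep[lex_order(spell[keep])]
  remap[o] <- seq_along(o)
  node_ids <- sprintf("n%03d", seq_along(o))
  nodes <- structure(spell[o], names = node_ids)
  esel <- which(e_from %in% keep & e_to %in% keep)
  edges <- data.frame(
    from = node_ids[remap[e_from[esel]]],
    to = node_ids[remap[e_to[esel]]],
    support = e_sup[esel],
    junction = e_junc[esel],
    stringsAsFactors = FALSE)
  edges <- edges[lex_order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  kept_kmers <- lex_sort(unlist(lapply(chains[keep], function(ch) kS[ch]),
                                use.names = FALSE))
  structure(list(graph_id = graph_id, k = k, stranded = st$stranded,
                 nodes = nodes, edges = edges, kmers = kept_kmers,
                 seed = substr(seed_seq, 1L, k)),
            class = "splicing_graph")
}

component_of <- function(n, from, to, start) {
  adj <- vector("list", n)
  for (i in seq_along(from)) {
    adj[[from[i]]] <- c(adj[[from[i]]], to[i])
    adj[[to[i]]] <- c(adj[[to[i]]], from[i])
  }
  seen <- logical(n)
  queue <- start
  seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  which(seen)
}

#' @export
print.splicing_graph <- function(x, ...) {
  cat("splicing_graph", x$graph_id, ":", length(x$nodes), "nodes,",
      nrow(x$edges), "edges | k =", x$k, "\n")
  invisible(x)
}

#' Build all splicing graphs from a filtered k-mer table
#'
#' Repeats seed selection, bidirectional contig extension (with
#' paired-end bridging) and read-guided branch extension until no k-mer
#' qualifies as a seed. Each iteration yields one graph, corresponding to
#' one gene locus; graphs are disjoint in their k-mer usage and are
#' returned sorted by seed k-mer.
#'
#' @param table Filtered `kmer_table`.
#' @param reads A `read_pairs` object (may be `NULL` for k-mer-only toys).
#' @param branch_cap Branch openings allowed per graph (default 20).
#' @param min_entropy,min_seed_count Seed gates (defaults 1.5 bits, > 1).
#' @return List of `splicing_graph` objects, sorted by seed k-mer; the
#'   attribute `kmer_to_graph` holds an environment mapping each used
#'   k-mer to its graph id.
#' @export
build_all_graphs <- function(table, reads = NULL, branch_cap = 20L,
                             min_entropy = 1.5, min_seed_count = 1L) {
  st <- asm_state(table, reads = reads, branch_cap = branch_cap)
  counts <- table$counts
  kmers <- names(counts)
  qual <- which(counts > min_seed_count)
  if (length(qual)) {
    qual <- qual[shannon_entropy(kmers[qual]) > min_entropy]
  }
  ord <- qual[lex_order(-counts[qual], kmers[qual])]
  graphs <- list()
  ptr <- 1L
  while (ptr <= length(ord)) {
    seed <- kmers[ord[ptr]]
    ptr <- ptr + 1L
    if (kmer_free(st, seed) == 0L) next
    ctg <- core_build_contig(st, seed)
    g <- core_branch_graph(st, ctg$sequence, graph_id = seed)
    graphs[[length(graphs) + 1L]] <- g
  }
  if (length(graphs)) {
    seeds <- vapply(graphs, `[[`, character(1), "seed")
    graphs <- graphs[lex_order(seeds)]
    for (i in seq_along(graphs)) {
      graphs[[i]]$graph_id <- sprintf("g%04d", i)
    }
  }
  kenv <- new.env(hash = TRUE, parent = emptyenv())
  for (g in graphs) {
    for (km in g$kmers) assign(km, g$graph_id, envir = kenv)
  }
  attr(graphs, "kmer_to_graph") <- kenv
  graphs
}

#' Check that every graph edge is witnessed by a read
#'
#' Re-scans the reads and verifies, for every edge, that some read either
#' contains the junction (k+1)-mer or begins/ends exactly at the k-mer on
#' the far side of the junction (the branch-opening fallback, where the
#' read cannot show the preceding base).
#'
#' @param graph A `splicing_graph`.
#' @param reads The `read_pairs` the graph was built from.
#' @return Data frame of edges with a logical `supported` column.
#' @export
verify_read_support <- function(graph, reads) {
  k <- graph$k
  seqs <- transcript_strand_seqs(reads, graph$stranded)
  jw <- kmer_windows(seqs, k + 1L)
  if (!graph$stranded) jw <- pmin(jw, revcomp(jw))
  jset <- index_env(unique(jw))
  ini <- index_env(unique(substr(seqs, 1L, k)))
  fin <- index_env(unique(substr(seqs, nchar(seqs) - k + 1L, nchar(seqs))))
  ok <- vapply(graph$edges$junction, function(j) {
    key <- if (graph$stranded) j else {
      r <- rc1(j)
      if (r < j) r else j
    }
    if (!is.null(get0(key, envir = jset, inherits = FALSE))) return(TRUE)
    lead <- substr(j, 2L, k + 1L)
    lag <- substr(j, 1L, k)
    !is.null(get0(lead, envir = ini, inherits = FALSE)) ||
      !is.null(get0(lag, envir = fin, inherits = FALSE))
  }, logical(1), USE.NAMES = FALSE)
  cbind(graph$edges, supported = ok)
}

#' Write a splicing graph as GFA 1.0
#'
#' Segments are nodes, links are edges with a k-1 overlap.
#'
#' @param graph A `splicing_graph`.
#' @param path Output path.
#' @export
write_gfa <- function(graph, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (id in names(graph$nodes)) {
    writeLines(paste("S", id, graph$nodes[[id]], sep = "\t"), con)
  }
  ov <- paste0(graph$k - 1L, "M")
  for (i in seq_len(nrow(graph$edges))) {
    writeLines(paste("L", graph$edges$from[i], "+", graph$edges$to[i], "+",
                     ov, sep = "\t"), con)
  }
  invisible(path)
}
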