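#' Build a k-mer count table from paired-end reads
#'
#' Every length-`k` window of every mate contributes one count. In
#' strand-specific mode the second mate is reverse-complemented first, so
#' both mates are counted on the transcript strand. In unstranded mode
#' each window is replaced by its canonical form (the lexicographic
#' minimum of the window and its reverse complement). Windows containing
#' `N` are skipped.
#'
#' @param reads A `read_pairs` object (see [read_fastq()] or
#'   [simulate_reads()]).
#' @param k K-mer length (>= 15 for assembly; smaller values are allowed
#'   for toy examples).
#' @param stranded Logical; is the library strand-specific?
#' @return An object of class `kmer_table`: a list with elements `k`,
#'   `counts` (named integer vector), and `stranded`.
#' @export
build_kmer_table <- function(reads, k, stranded = TRUE) {
  stopifnot(k >= 1L)
  seqs <- transcript_strand_seqs(reads, stranded)
  if (length(seqs) && k > min(nchar(seqs))) {
    stop("k (", k, ") exceeds the shortest read length (", min(nchar(seqs)), ")")
  }
  w <- kmer_windows(seqs, k)
  if (!stranded) w <- pmin(w, revcomp(w))
  new_kmer_table(count_strings(w), k, stranded)
}

new_kmer_table <- function(counts, k, stranded) {
  structure(list(k = as.integer(k), counts = counts, stranded = stranded),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("kmer_table: k =", x$k, "|", length(x$counts), "distinct k-mers |",
      if (x$stranded) "stranded" else "canonical (unstranded)", "\n")
  invisible(x)
}

# Mate sequences on the transcript strand: mate1 as-is, mate2
# reverse-complemented when the library is strand-specific. For unstranded
# data both mates are returned as read (canonicalisation happens on the
# k-mer level).
transcript_strand_seqs <- function(reads, stranded) {
  if (stranded) c(reads$mate1, revcomp(reads$mate2)) else c(reads$mate1, reads$mate2)
}

#' Remove presumed sequencing-error k-mers
#'
#' A k-mer is removed when some single-substitution neighbour has a count
#' at least `min_dominance_ratio` times its own: such minority k-mers
#' hanging off a high-coverage neighbour overwhelmingly arise from
#' substitution errors in reads drawn from that position (at 20x
#' dominance a k-mer carries under ~5% of the local coverage, far below
#' what a real allele or paralogue would show). K-mers with counts below
#' `min_count` are also removed. The input table is not modified.
#'
#' @param table A `kmer_table`.
#' @param min_dominance_ratio Dominance ratio (default 20).
#' @param min_count Absolute minimum count (default 1, i.e. no absolute
#'   cutoff beyond the dominance rule).
#' @return A new, filtered `kmer_table`.
#' @export
filter_errors <- function(table, min_dominance_ratio = 20, min_count = 1L) {
  counts <- table$counts
  counts <- counts[counts >= min_count]
  kmers <- names(counts)
  # only k-mers this small relative to the global maximum can possibly be
  # dominated; restricting the neighbour scan to them keeps the pass cheap
  cand <- if (length(counts)) {
    which(counts * min_dominance_ratio <= max(counts))
  } else {
    integer(0)
  }
  if (length(cand)) {
    k <- table$k
    sk <- kmers[cand]
    max_neighbour <- integer(length(sk))
    for (pos in seq_len(k)) {
      left <- substr(sk, 1L, pos - 1L)
      right <- substr(sk, pos + 1L, k)
      at <- substr(sk, pos, pos)
      for (b in c("A", "C", "G", "T")) {
        nb <- paste0(left, b, right)
        nb[at == b] <- NA_character_
        hit <- counts[match(nb, kmers)]
        hit[is.na(hit)] <- 0L
        max_neighbour <- pmax(max_neighbour, hit)
      }
    }
    dominated <- max_neighbour >= min_dominance_ratio * counts[cand]
    if (any(dominated)) counts <- counts[-cand[dominated]]
  }
  new_kmer_table(counts, table$k, table$stranded)
}

#' Shannon entropy of DNA sequences
#'
#' Base-2 Shannon entropy of the base composition of each sequence, in
#' bits. Ranges over \[0, 2\] for DNA; equal base counts give exactly 2.
#' Low-complexity k-mers (e.g. poly-A runs) score near 0 and are excluded
#' from seeding by the `H > 1.5` rule.
#'
#' @param kmer Character vector of DNA sequences (no `N`).
#' @return Numeric vector of entropies in bits.
#' @export
shannon_entropy <- function(kmer) {
  if (length(kmer) == 0L) return(numeric(0))
  stopifnot(all(nchar(kmer) > 0L))
  p <- base_counts(kmer) / nchar(kmer)
  lp <- ifelse(p > 0, log2(p), 0)
  -rowSums(p * lp)
}

#' Write / read a k-mer table as two-column TSV
#'
#' Debugging aid: the table is serialised as `kmer<TAB>count`, sorted
#' lexicographically by k-mer.
#'
#' @param table A `kmer_table`.
#' @param path Output file path.
#' @export
write_kmer_table <- function(table, path) {
  o <- lex_order(names(table$counts))
  utils::write.table(
    data.frame(kmer = names(table$counts)[o], count = unname(table$counts[o])),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_table
#' @param k,stranded Metadata for the reconstructed table.
#' @export
read_kmer_table <- function(path, k, stranded = TRUE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("kmer", "count"),
                          colClasses = c("character", "integer"))
  new_kmer_table(structure(df$count, names = df$kmer), k, stranded)
}
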