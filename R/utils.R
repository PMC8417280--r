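# Internal helpers shared across modules. All lexicographic operations use
# radix sorting so behaviour is identical in every locale.

`%||%` <- function(x, y) if (is.null(x)) y else x

lex_sort <- function(x, decreasing = FALSE) {
  if (length(x) == 0L) return(character(0))
  sort(x, decreasing = decreasing, method = "radix")
}

lex_order <- function(...) {
  order(..., method = "radix")
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the 5-letter alphabet (N maps to N).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Count occurrences of each distinct string; returns a named integer vector
# sorted lexicographically by string.
count_strings <- function(x) {
  if (length(x) == 0L) return(structure(integer(0), names = character(0)))
  s <- sort(x, method = "radix")
  r <- rle(s)
  structure(r$lengths, names = r$values)
}

# Per-string counts of each DNA base, computed without splitting strings.
base_counts <- function(x) {
  n <- nchar(x)
  cbind(
    A = n - nchar(gsub("A", "", x, fixed = TRUE)),
    C = n - nchar(gsub("C", "", x, fixed = TRUE)),
    G = n - nchar(gsub("G", "", x, fixed = TRUE)),
    T = n - nchar(gsub("T", "", x, fixed = TRUE))
  )
}

# All length-k windows of a character vector of sequences, as one flat
# character vector. Windows containing N are dropped when drop_n is TRUE.
kmer_windows <- function(seqs, k, drop_n = TRUE) {
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) return(character(0))
  out <- vector("list", length(unique(nchar(seqs))))
  i <- 0L
  for (len in sort(unique(nchar(seqs)))) {
    i <- i + 1L
    grp <- seqs[nchar(seqs) == len]
    nw <- len - k + 1L
    wins <- vector("list", nw)
    for (j in seq_len(nw)) wins[[j]] <- substring(grp, j, j + k - 1L)
    out[[i]] <- unlist(wins, use.names = FALSE)
  }
  w <- unlist(out, use.names = FALSE)
  if (drop_n) w <- w[!grepl("N", w, fixed = TRUE)]
  w
}

# Fast hash map from string keys to integer indices (1..n).
index_env <- function(keys) {
  e <- new.env(hash = TRUE, parent = emptyenv(), size = max(29L, length(keys)))
  if (length(keys)) {
    idx <- seq_along(keys)
    for (i in idx) assign(keys[i], i, envir = e)
  }
  e
}

env_get <- function(e, key) {
  get0(key, envir = e, inherits = FALSE)
}
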