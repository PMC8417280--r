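# Assembly evaluation: sequence-overlap matching under the 90/80 rule,
# precision / recall / F-score, and stratification by isoform count and
# expression level. Overlap is computed by chained exact k-mer matching
# on both orientations; on synthetic (random, unique) sequences this is
# a lossless substitute for an external local aligner, and the 90/80
# decision rule is preserved verbatim.

#' Match assembled transcripts against an expressed reference set
#'
#' For each assembled transcript the best reference among `expressed_ids`
#' is found by shared-k-mer overlap on the forward and reverse-complement
#' orientations. The assembled coverage fraction is the fraction of the
#' assembled sequence covered by k-mers shared with the reference, and
#' vice versa for the reference coverage fraction. A match is declared
#' when the assembled fraction is at least 0.9 and the reference
#' fraction at least 0.8. Each assembly matches at most one reference
#' (ties broken by reference id); a reference may be matched by several
#' assemblies.
#'
#' @param assembled Named character vector of assembled sequences (or a
#'   FASTA path).
#' @param reference Named character vector of reference sequences (or a
#'   FASTA path).
#' @param expressed_ids Reference ids considered expressed.
#' @param k K-mer length for overlap computation (default 25).
#' @param min_assembled_frac,min_reference_frac Match thresholds
#'   (defaults 0.9 and 0.8).
#' @return Data frame with one row per assembled transcript:
#'   `assembled_id`, `matched_reference_id` (NA when unmatched),
#'   `assembled_coverage_fraction`, `reference_coverage_fraction`,
#'   `matched`.
#' @export
match_transcripts <- function(assembled, reference, expressed_ids,
                              k = 25L, min_assembled_frac = 0.9,
                              min_reference_frac = 0.8) {
  assembled <- as_named_seqs(assembled)
  reference <- as_named_seqs(reference)
  reference <- reference[names(reference) %in% expressed_ids]
  empty <- data.frame(
    assembled_id = names(assembled),
    matched_reference_id = NA_character_,
    assembled_coverage_fraction = 0,
    reference_coverage_fraction = 0,
    matched = FALSE,
    row.names = NULL)
  if (length(assembled) == 0L || length(reference) == 0L) return(empty)
  ref_ids <- lex_sort(names(reference))
  ref_idx <- lapply(reference[ref_ids], function(s) {
    index_env(unique(kmer_windows(s, k)))
  })
  ref_len <- nchar(reference[ref_ids])
  # prefilter: k-mer -> reference ids sharing it
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (r in ref_ids) {
    for (w in unique(kmer_windows(reference[[r]], k))) {
      assign(w, c(get0(w, envir = lookup, inherits = FALSE), r), envir = lookup)
    }
  }
  res <- empty
  for (i in seq_along(assembled)) {
    a_fw <- assembled[[i]]
    for (orient in c("fw", "rc")) {
      a <- if (orient == "fw") a_fw else revcomp(a_fw)
      wins <- kmer_windows(a, k)
      if (!length(wins)) next
      cand <- unique(unlist(lapply(
        unique(wins[seq(1L, length(wins), by = max(1L, k %/% 2L))]),
        function(w) get0(w, envir = lookup, inherits = FALSE)),
        use.names = FALSE))
      for (r in lex_sort(cand)) {
        af <- coverage_fraction(wins, nchar(a), ref_idx[[r]], k)
        rf <- coverage_fraction(kmer_windows(reference[[r]], k), ref_len[[r]],
                                index_env(unique(wins)), k)
        better <- af > res$assembled_coverage_fraction[i] ||
          (af == res$assembled_coverage_fraction[i] &&
             rf > res$reference_coverage_fraction[i])
        if (better) {
          res$assembled_coverage_fraction[i] <- af
          res$reference_coverage_fraction[i] <- rf
          res$matched_reference_id[i] <- r
        }
      }
    }
  }
  res$matched <- res$assembled_coverage_fraction >= min_assembled_frac &
    res$reference_coverage_fraction >= min_reference_frac
  res$matched_reference_id[!res$matched &
                             is.na(res$matched_reference_id)] <- NA_character_
  res
}

as_named_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      is.null(names(x))) {
    ss <- Biostrings::readDNAStringSet(x)
    return(stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
  }
  stopifnot(is.character(x))
  x
}

# Fraction of a sequence covered by windows whose k-mer occurs in the
# other sequence's k-mer index.
coverage_fraction <- function(wins, len, other_idx, k) {
  if (!length(wins) || len == 0L) return(0)
  hit <- vapply(wins, function(w) {
    !is.null(get0(w, envir = other_idx, inherits = FALSE))
  }, logical(1), USE.NAMES = FALSE)
  if (!any(hit)) return(0)
  covered <- logical(len)
  idx <- which(hit)
  for (i in idx) covered[i:(i + k - 1L)] <- TRUE
  mean(covered)
}

#' Precision, recall and F-score from match results
#'
#' Precision is the fraction of assembled transcripts that matched;
#' recall is the fraction of expressed reference transcripts matched by
#' at least one assembly; the F-score is their harmonic mean
#' (2 x precision x recall / (precision + recall)), defined as 0 when
#' precision + recall = 0.
#'
#' @param matches Output of [match_transcripts()].
#' @param n_assembled Number of assembled transcripts (precision
#'   denominator).
#' @param n_expressed_reference Number of expressed reference
#'   transcripts (recall denominator).
#' @return List with `precision`, `recall`, `fscore`,
#'   `n_matched_assembled`, `n_matched_reference`, and
#'   `zero_denominator` flag.
#' @export
compute_metrics <- function(matches, n_assembled, n_expressed_reference) {
  stopifnot(n_assembled >= 0, n_expressed_reference >= 0)
  n_ok <- sum(matches$matched)
  n_ref <- length(unique(matches$matched_reference_id[matches$matched]))
  zero <- FALSE
  precision <- if (n_assembled > 0) n_ok / n_assembled else { zero <- TRUE; 0 }
  recall <- if (n_expressed_reference > 0) {
    n_ref / n_expressed_reference
  } else {
    zero <- TRUE
    0
  }
  list(precision = precision, recall = recall,
       fscore = fscore(precision, recall),
       n_matched_assembled = n_ok, n_matched_reference = n_ref,
       zero_denominator = zero)
}

#' @rdname compute_metrics
#' @param precision,recall Metric values in \[0, 1\].
#' @export
fscore <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Stratified metrics by isoform count and expression level
#'
#' Recomputes precision/recall/F-score restricted to reference
#' transcripts in each gene-isoform-count bin (number of expressed
#' isoforms of the gene: 1, 2, 3, 4, >4) and in each FPKM bin
#' ((1,10], (10,50], (50,Inf), on realised FPKM). Assembled transcripts
#' enter a bin's precision when their best-matching reference lies in the
#' bin; unmatched assemblies without any best reference belong to no
#' bin. Empty bins are omitted.
#'
#' @param matches Output of [match_transcripts()].
#' @param truth Truth table from [simulate_reads()].
#' @param expressed_fpkm Expression threshold defining the expressed
#'   reference set (default 1).
#' @return List with `by_isoform_count` and `by_fpkm`, each a data frame
#'   of per-bin metrics.
#' @export
stratify <- function(matches, truth, expressed_fpkm = 1) {
  expressed <- truth[truth$fpkm_realized > expressed_fpkm, , drop = FALSE]
  iso_n <- table(expressed$gene_id)
  bin_of_gene <- ifelse(iso_n > 4, ">4", as.character(iso_n))
  expressed$iso_bin <- unname(bin_of_gene[expressed$gene_id])
  expressed$fpkm_bin <- cut(expressed$fpkm_realized,
                            c(expressed_fpkm, 10, 50, Inf),
                            labels = c("(1,10]", "(10,50]", "(50,Inf)"))
  strat_one <- function(bin_col, levels_) {
    rows <- lapply(levels_, function(bn) {
      ids <- expressed$isoform_id[expressed[[bin_col]] == bn]
      if (!length(ids)) return(NULL)
      sel <- matches[!is.na(matches$matched_reference_id) &
                       matches$matched_reference_id %in% ids, , drop = FALSE]
      m <- compute_metrics(sel, n_assembled = nrow(sel),
                           n_expressed_reference = length(ids))
      data.frame(bin = bn, n_reference = length(ids),
                 n_assembled = nrow(sel),
                 precision = m$precision, recall = m$recall,
                 fscore = m$fscore, row.names = NULL)
    })
    do.call(rbind, rows)
  }
  list(
    by_isoform_count = strat_one("iso_bin", c("1", "2", "3", "4", ">4")),
    by_fpkm = strat_one("fpkm_bin", c("(1,10]", "(10,50]", "(50,Inf)")))
}

#' Evaluate an assembly against a simulated reference
#'
#' Convenience wrapper: reads the assembled and reference FASTA (or
#' named vectors), derives the expressed reference set from the truth
#' table (realised FPKM above `expressed_fpkm`), matches under the 90/80
#' rule and reports overall plus stratified metrics.
#'
#' @param assembled,reference FASTA paths or named character vectors.
#' @param truth Truth table (data frame or TSV path).
#' @param expressed_fpkm Expression threshold (default 1).
#' @param report_path Optional JSON report output path.
#' @return List with `metrics`, `strata`, `matches`, `n_assembled`,
#'   `n_expressed_reference`.
#' @export
evaluate_assembly <- function(assembled, reference, truth,
                              expressed_fpkm = 1, report_path = NULL) {
  if (is.character(truth) && length(truth) == 1L) {
    truth <- utils::read.table(truth, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  }
  assembled <- as_named_seqs(assembled)
  reference <- as_named_seqs(reference)
  expressed_ids <- truth$isoform_id[truth$fpkm_realized > expressed_fpkm]
  matches <- match_transcripts(assembled, reference, expressed_ids)
  metrics <- compute_metrics(matches, n_assembled = length(assembled),
                             n_expressed_reference = length(expressed_ids))
  strata <- stratify(matches, truth, expressed_fpkm)
  out <- list(metrics = metrics, strata = strata, matches = matches,
              n_assembled = length(assembled),
              n_expressed_reference = length(expressed_ids))
  if (!is.null(report_path)) {
    jsonlite::write_json(
      list(metrics = metrics,
           strata = lapply(strata, function(d) d %||% list())),
      report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
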