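# Synthetic transcriptome and paired-end read simulation. The generator
# emulates the structure of a multi-isoform transcriptome: genes with
# exons shared across isoforms through exon skipping, alternative 5'/3'
# boundaries (truncated exon variants) and intron retention (merged exon
# variants), with log-uniform expression spanning orders of magnitude
# and an optional unexpressed fraction.

#' Simulate a multi-isoform transcriptome
#'
#' Exon sequences are drawn uniformly over A/C/G/T (base entropy near 2
#' bits, matching the seeding gate). Each gene receives an isoform count
#' drawn from `isoform_dist`; the first isoform uses every exon and each
#' further isoform is derived by one alternative-splicing event (exon
#' skip, alternative boundary via exon truncation, or intron retention
#' via a merged exon variant). FPKM values are drawn log-uniformly over
#' `fpkm_range`, with a fraction `zero_fraction` set to 0 (unexpressed).
#'
#' @param n_genes Number of genes (default 20).
#' @param isoform_dist Named probability vector over isoform counts,
#'   names "1", "2", ... (default supports 1--5).
#' @param exon_len_range Exon length range in nt (default c(300, 800)).
#' @param fpkm_range FPKM range for the log-uniform draw (default
#'   c(2, 200)).
#' @param zero_fraction Fraction of isoforms set to FPKM 0 (default 0).
#' @return List of genes; each gene is a list with `gene_id`, `exons`
#'   (character vector in genomic order), `isoforms` (list of strictly
#'   increasing exon-index vectors), `isoform_id`, `fpkm`.
#' @export
simulate_transcriptome <- function(n_genes = 20L,
                                   isoform_dist = c("1" = 0.30, "2" = 0.25,
                                                    "3" = 0.20, "4" = 0.15,
                                                    "5" = 0.10),
                                   exon_len_range = c(300L, 800L),
                                   fpkm_range = c(2, 200),
                                   zero_fraction = 0) {
  stopifnot(n_genes >= 1L, all(isoform_dist >= 0), sum(isoform_dist) > 0,
            exon_len_range[1] >= 25L)
  lapply(seq_len(n_genes), function(gi) {
    n_iso <- as.integer(sample(names(isoform_dist), 1L,
                               prob = isoform_dist))
    simulate_gene(sprintf("gene%03d", gi), n_iso, exon_len_range,
                  fpkm_range, zero_fraction)
  })
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

simulate_gene <- function(gene_id, n_iso, exon_len_range, fpkm_range,
                          zero_fraction) {
  n_exons <- max(3L, n_iso + sample(1:2, 1L))
  lens <- sample(exon_len_range[1]:exon_len_range[2], n_exons, replace = TRUE)
  # exons keyed by genomic rank; derived variants slot in between
  ranks <- as.numeric(seq_len(n_exons))
  seqs <- vapply(lens, random_dna, character(1))
  isoforms_keys <- list(ranks)  # first isoform: all exons
  for (j in seq_len(max(0L, n_iso - 1L))) {
    for (try in 1:20) {
      ev <- sample(c("skip", "alt5", "alt3", "retention"), 1L)
      base <- isoforms_keys[[1]]  # events derive from the full isoform
      new <- switch(ev,
        skip = {
          internal <- base[base > min(base) & base < max(base)]
          if (!length(internal)) NULL else base[base != sample(internal, 1L)]
        },
        alt5 = ,
        alt3 = {
          jx <- sample(seq_along(base), 1L)
          orig <- seqs[match(base[jx], ranks)]
          keep <- nchar(orig) - sample(50:150, 1L)
          if (keep < 100L) NULL else {
            var_seq <- if (ev == "alt5") {
              substring(orig, nchar(orig) - keep + 1L)
            } else {
              substr(orig, 1L, keep)
            }
            var_rank <- base[jx] + 0.01 * (j + try)
            ranks <- c(ranks, var_rank)
            seqs <- c(seqs, var_seq)
            sort(c(base[-jx], var_rank))
          }
        },
        retention = {
          jx <- sample(seq_len(length(base) - 1L), 1L)
          a <- seqs[match(base[jx], ranks)]
          b <- seqs[match(base[jx + 1L], ranks)]
          merged <- paste0(a, random_dna(sample(80:200, 1L)), b)
          var_rank <- base[jx] + 0.5
          ranks <- c(ranks, var_rank)
          seqs <- c(seqs, merged)
          sort(c(base[-c(jx, jx + 1L)], var_rank))
        })
      if (is.null(new)) next
      if (!any(vapply(isoforms_keys, function(x) identical(x, new),
                      logical(1)))) {
        isoforms_keys[[length(isoforms_keys) + 1L]] <- new
        break
      }
    }
  }
  o <- order(ranks)
  ranks_sorted <- ranks[o]
  exons <- seqs[o]
  isoforms <- lapply(isoforms_keys, function(keys) {
    sort(match(keys, ranks_sorted))
  })
  n_iso_built <- length(isoforms)
  lf <- log(fpkm_range)
  fpkm <- exp(stats::runif(n_iso_built, lf[1], lf[2]))
  if (zero_fraction > 0) {
    fpkm[stats::runif(n_iso_built) < zero_fraction] <- 0
  }
  list(gene_id = gene_id, exons = exons, isoforms = isoforms,
       isoform_id = sprintf("%s.i%d", gene_id, seq_len(n_iso_built)),
       fpkm = fpkm)
}

#' Spell the transcript sequences of simulated genes
#'
#' @param genes Output of [simulate_transcriptome()].
#' @return Named character vector of isoform sequences.
#' @export
transcript_sequences <- function(genes) {
  out <- lapply(genes, function(g) {
    stats::setNames(vapply(g$isoforms, function(ix) {
      paste(g$exons[ix], collapse = "")
    }, character(1)), g$isoform_id)
  })
  unlist(out)
}

#' Simulate paired-end reads from a transcriptome
#'
#' Fragments are allocated across isoforms proportionally to
#' FPKM x length (multinomially), with the total chosen so that the mean
#' per-isoform read depth over expressed isoforms equals `depth` (or set
#' directly via `total_fragments`). Fragment lengths are Gaussian,
#' clamped to \[read_len, isoform length\]; mates are read off both
#' fragment ends (mate2 reverse-complemented); substitutions are applied
#' i.i.d. at `error_rate`. Realised FPKM is reported on the requested
#' scale (its expectation equals the requested FPKM).
#'
#' @param genes Output of [simulate_transcriptome()].
#' @param read_len Read length (default 100).
#' @param frag_mu,frag_sd Fragment-length mean and sd (default 250, 25).
#' @param depth Target mean per-isoform depth (default 25).
#' @param total_fragments Overrides `depth` when given.
#' @param error_rate Per-base substitution rate (default 0).
#' @param stranded Strand-specific library (default TRUE).
#' @return List with `reads` (a `read_pairs`), `truth` (data frame:
#'   isoform_id, gene_id, length, fpkm_requested, fpkm_realized,
#'   n_fragments), `origin` (per-fragment isoform_id).
#' @export
simulate_reads <- function(genes, read_len = 100L, frag_mu = 250,
                           frag_sd = 25, depth = 25, total_fragments = NULL,
                           error_rate = 0, stranded = TRUE) {
  stopifnot(frag_mu >= read_len)
  seqs <- transcript_sequences(genes)
  gene_of <- unlist(lapply(genes, function(g) {
    stats::setNames(rep(g$gene_id, length(g$isoform_id)), g$isoform_id)
  }))
  fpkm <- unlist(lapply(genes, `[[`, "fpkm"))
  names(fpkm) <- names(seqs)
  len <- nchar(seqs)
  short <- fpkm > 0 & len < read_len
  if (any(short)) {
    warning(sum(short), " isoform(s) shorter than the read length; skipped")
    fpkm[short] <- 0
  }
  lambda <- fpkm * len
  if (sum(lambda) == 0) {
    return(list(reads = read_pairs(character(0), character(0), character(0),
                                   stranded),
                truth = truth_table(names(seqs), gene_of, len, fpkm,
                                    integer(length(seqs)), 1),
                origin = character(0)))
  }
  N <- if (!is.null(total_fragments)) {
    as.integer(total_fragments)
  } else {
    expressed <- fpkm > 0
    max(1L, round(depth * sum(lambda) /
                    (2 * read_len * mean(fpkm[expressed]))))
  }
  n_frag <- as.integer(stats::rmultinom(1, N, lambda / sum(lambda)))
  names(n_frag) <- names(seqs)
  iso_idx <- rep(seq_along(seqs), n_frag)
  tlen <- len[iso_idx]
  flen <- pmin(pmax(round(stats::rnorm(length(iso_idx), frag_mu, frag_sd)),
                    read_len), tlen)
  start <- floor(stats::runif(length(iso_idx)) * (tlen - flen + 1)) + 1L
  m1 <- substr(seqs[iso_idx], start, start + read_len - 1L)
  end <- start + flen - 1L
  m2 <- revcomp(substr(seqs[iso_idx], end - read_len + 1L, end))
  if (error_rate > 0 && length(m1)) {
    m1 <- add_substitutions(m1, error_rate)
    m2 <- add_substitutions(m2, error_rate)
  }
  ids <- sprintf("f%07d", seq_along(iso_idx))
  reads <- read_pairs(ids, unname(m1), unname(m2), stranded)
  truth <- truth_table(names(seqs), gene_of, len, fpkm, n_frag,
                       scale = sum(lambda) / N)
  list(reads = reads, truth = truth,
       origin = names(seqs)[iso_idx])
}

truth_table <- function(ids, gene_of, len, fpkm, n_frag, scale) {
  data.frame(
    isoform_id = ids,
    gene_id = unname(gene_of[ids]),
    length = unname(len),
    fpkm_requested = unname(fpkm),
    fpkm_realized = unname(n_frag * scale / len),
    n_fragments = unname(n_frag),
    row.names = NULL)
}

add_substitutions <- function(seqs, rate) {
  nc <- nchar(seqs)
  total <- sum(nc)
  hit <- which(stats::runif(total) < rate)
  if (!length(hit)) return(seqs)
  ends <- cumsum(nc)
  read_i <- findInterval(hit - 1L, ends) + 1L
  pos <- hit - c(0L, ends)[read_i]
  subs <- sample(BASES, length(hit), replace = TRUE)
  for (j in seq_along(hit)) {
    i <- read_i[j]
    old <- substr(seqs[i], pos[j], pos[j])
    if (subs[j] != old) {
      substr(seqs[i], pos[j], pos[j]) <- subs[j]
    } else {
      # substitute with the next base in A<C<G<T order to guarantee change
      repl <- BASES[(match(old, BASES) %% 4L) + 1L]
      substr(seqs[i], pos[j], pos[j]) <- repl
    }
  }
  seqs
}

#' Write a simulation to disk
#'
#' Writes the reference FASTA (isoform sequences), a truth TSV and
#' paired FASTQ files (constant quality).
#'
#' @param sim Output of [simulate_reads()].
#' @param genes The simulated transcriptome.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- file.path(dir, "reference.fa")
  seqs <- Biostrings::DNAStringSet(transcript_sequences(genes))
  Biostrings::writeXStringSet(seqs, ref, width = 60L)
  truth <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  r1 <- file.path(dir, "reads_1.fastq")
  r2 <- file.path(dir, "reads_2.fastq")
  write_fastq(sim$reads$fragment_id, sim$reads$mate1, r1, "/1")
  write_fastq(sim$reads$fragment_id, sim$reads$mate2, r2, "/2")
  invisible(list(reference = ref, truth = truth, r1 = r1, r2 = r2))
}

write_fastq <- function(ids, seqs, path, suffix) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", ids, suffix), seqs, "+", qual))
  writeLines(lines, path)
  invisible(path)
}
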