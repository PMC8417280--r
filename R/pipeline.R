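# End-to-end assembly pipeline: k-mer counting -> error filtering ->
# splicing graphs -> candidate enumeration -> Bayesian transcript
# calling -> FASTA + machine-readable report.

#' Default pipeline configuration
#'
#' @return Named list of every tunable pipeline setting with its default.
#' @export
default_config <- function() {
  list(
    k = 25L,                    # k-mer length
    stranded = TRUE,            # strand-specific library
    seed = 1L,                  # RNG seed for the sampler
    min_dominance_ratio = 20,   # error k-mer filter
    min_count = 1L,
    branch_cap = 20L,           # branch openings per graph
    max_candidates = 100L,      # candidate cap per graph
    min_transcript_length = 200L,
    pi_prior = 0.5,             # Bernoulli prior on expression
    alpha = 1,                  # Dirichlet concentration
    sweeps = 2000L,
    burnin = 500L,
    call_threshold = 0.5,
    flen_mu = 250,              # fragment-length fallback
    flen_sd = 25,
    flen_min_n = 100L           # unique placements needed to estimate
  )
}

#' Assemble transcripts from paired-end reads (in-memory)
#'
#' Runs the full method on a `read_pairs` object: builds and filters the
#' k-mer table, constructs splicing graphs, enumerates candidates per
#' graph, estimates the fragment-length distribution from
#' single-candidate graphs, and calls expressed transcripts per graph
#' with the Gibbs sampler. Deterministic given `config$seed`.
#'
#' @param reads A `read_pairs` object.
#' @param config List of settings; see [default_config()]. Missing
#'   entries take their defaults.
#' @return List of class `assembly`: `transcripts` (data frame),
#'   `graphs`, `posteriors` (per-graph summaries), `flen`, `report`.
#' @export
assemble_transcripts <- function(reads, config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  set.seed(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  if (length(reads) == 0L) {
    return(structure(list(
      transcripts = empty_transcripts(), graphs = list(),
      posteriors = list(), flen = list(mu = cfg$flen_mu, sd = cfg$flen_sd),
      report = list(n_fragments = 0L, n_graphs = 0L, n_transcripts = 0L,
                    runtime_sec = 0)), class = "assembly"))
  }
  table <- build_kmer_table(reads, cfg$k, cfg$stranded)
  table <- filter_errors(table, cfg$min_dominance_ratio, cfg$min_count)
  graphs <- build_all_graphs(table, reads, branch_cap = cfg$branch_cap)
  kenv <- attr(graphs, "kmer_to_graph")
  assignment <- assign_fragments(reads, kenv, cfg$k, cfg$stranded)
  cand_sets <- lapply(graphs, enumerate_candidates,
                      max_candidates = cfg$max_candidates,
                      frag_mu = cfg$flen_mu)
  flen <- pipeline_flen(reads, graphs, cand_sets, assignment, cfg)
  # refresh effective lengths under the estimated fragment length
  cand_sets <- lapply(cand_sets, function(cs) {
    cs$candidates <- lapply(cs$candidates, function(cd) {
      cd$effective_length <- max(nchar(cd$sequence) - flen$mu + 1, 1)
      cd
    })
    cs
  })
  transcripts <- empty_transcripts()
  posteriors <- list()
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    frag_ids <- which(assignment == g$graph_id)
    sub <- subset_reads(reads, frag_ids)
    if (length(sub) == 0L) {
      posteriors[[g$graph_id]] <- NULL
      next
    }
    res <- withCallingHandlers(
      call_transcripts(g, cand_sets[[i]], sub, flen = flen,
                       config = cfg[c("pi_prior", "alpha", "sweeps", "burnin",
                                      "call_threshold",
                                      "min_transcript_length")]),
      warning = function(w) invokeRestart("muffleWarning"))
    transcripts <- rbind(transcripts, res$transcripts)
    posteriors[[g$graph_id]] <- res$summary
  }
  report <- list(
    n_fragments = length(reads),
    n_kmers = length(table$counts),
    n_graphs = length(graphs),
    nodes_per_graph = vapply(graphs, function(g) length(g$nodes), integer(1)),
    edges_per_graph = vapply(graphs, function(g) nrow(g$edges), integer(1)),
    candidates_per_graph = vapply(cand_sets, function(cs) {
      length(cs$candidates)
    }, integer(1)),
    transcripts_per_graph = if (nrow(transcripts)) {
      as.list(table(transcripts$graph_id))
    } else {
      list()
    },
    n_transcripts = nrow(transcripts),
    flen = flen,
    runtime_sec = round(proc.time()[["elapsed"]] - t0, 2))
  structure(list(transcripts = transcripts, graphs = graphs,
                 posteriors = posteriors, flen = flen, report = report),
            class = "assembly")
}

empty_transcripts <- function() {
  data.frame(transcript_id = character(0), sequence = character(0),
             graph_id = character(0), abundance = numeric(0),
             posterior_expression = numeric(0))
}

#' @export
print.assembly <- function(x, ...) {
  cat("assembly:", x$report$n_graphs, "graphs ->",
      x$report$n_transcripts, "transcripts from",
      x$report$n_fragments, "fragments\n")
  invisible(x)
}

# Assign each fragment to the graph owning most of its sampled k-mers.
assign_fragments <- function(reads, kenv, k, stranded) {
  s1 <- reads$mate1
  s2 <- if (stranded) revcomp(reads$mate2) else reads$mate2
  n <- length(s1)
  out <- character(n)
  for (i in seq_len(n)) {
    hits <- character(0)
    for (s in c(s1[i], s2[i])) {
      for (o in mate_offsets(nchar(s), k)) {
        w <- substr(s, o, o + k - 1L)
        g <- get0(w, envir = kenv, inherits = FALSE)
        if (!is.null(g)) hits <- c(hits, g)
      }
    }
    out[i] <- if (length(hits)) names(which.max(table(hits))) else NA_character_
  }
  out
}

subset_reads <- function(reads, idx) {
  read_pairs(reads$fragment_id[idx], reads$mate1[idx], reads$mate2[idx],
             reads$stranded)
}

# Fragment-length distribution from fragments uniquely placed on
# single-candidate graphs; configured fallback otherwise.
pipeline_flen <- function(reads, graphs, cand_sets, assignment, cfg) {
  lens <- integer(0)
  for (i in seq_along(graphs)) {
    if (length(cand_sets[[i]]$candidates) != 1L) next
    idx <- which(assignment == graphs[[i]]$graph_id)
    if (!length(idx)) next
    sub <- subset_reads(reads, idx)
    lens <- c(lens, implied_lengths(sub, cand_sets[[i]]$candidates[[1]],
                                    k = cfg$k))
    if (length(lens) >= 5000L) break
  }
  estimate_flen(lens, fallback = list(mu = cfg$flen_mu, sd = cfg$flen_sd),
                min_n = cfg$flen_min_n)
}

#' Run the full assembly pipeline on FASTQ input
#'
#' Reads paired FASTQ, assembles transcripts, and writes the output
#' FASTA, per-graph posterior tables (TSV) and a machine-readable JSON
#' run report into `out_dir`. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config List of settings. Required: either `left` and `right`
#'   (paired FASTQ paths) or `interleaved` (single path), and `out_dir`.
#'   All other entries as in [default_config()].
#' @return Invisibly, the `assembly` object with `paths` attached.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  reads <- if (!is.null(cfg$interleaved)) {
    read_fastq(cfg$interleaved, interleaved = TRUE, stranded = cfg$stranded)
  } else if (!is.null(cfg$left) && !is.null(cfg$right)) {
    read_fastq(cfg$left, cfg$right, stranded = cfg$stranded)
  } else if (!is.null(cfg$reads)) {
    cfg$reads
  } else {
    stop("config must provide left+right, interleaved, or reads")
  }
  asm <- assemble_transcripts(reads, cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(cfg$out_dir, "transcripts.fa")
  write_transcripts_fasta(asm$transcripts, fasta)
  post_dir <- file.path(cfg$out_dir, "posteriors")
  dir.create(post_dir, showWarnings = FALSE)
  for (gid in names(asm$posteriors)) {
    utils::write.table(asm$posteriors[[gid]],
                       file.path(post_dir, paste0(gid, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report_path <- file.path(cfg$out_dir, "report.json")
  report <- asm$report
  report$runtime_sec <- NULL  # keep report byte-stable across reruns
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  asm$paths <- list(fasta = fasta, report = report_path,
                    posteriors = post_dir)
  invisible(asm)
}

#' Parse a flat key=value configuration file
#'
#' Lines of the form `key = value` (or `key=value`); `#` comments and
#' blank lines ignored. Values are coerced to numeric or logical where
#' possible. Command-line flags override file values.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (toupper(val) %in% c("TRUE", "FALSE")) {
      as.logical(toupper(val))
    } else {
      val
    }
  }
  out
}
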