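#' Run configuration for the genotyping pipeline
#'
#' Collects the thresholds of the calling pipeline: the minimum truncated
#' mapping length at exon boundaries (70 bp), the central read ratio
#' threshold (0.2, failing strictly below), the harmonic-mean weights, the
#' low-coverage manual-review threshold on auc (0.5) and the read-count
#' warning threshold (7 million single reads, i.e. 3.5 million pairs).
#' Per-locus candidate lists can be adjusted with `force_include` /
#' `force_exclude`, mirroring the manual include/exclude tables of the
#' interactive workflow.
#'
#' @param read_len Read length (default 100).
#' @param min_trunc_len Minimum truncated mapping length (default 70).
#' @param central_threshold Central read ratio threshold (default 0.2).
#' @param weights Harmonic-mean weights, see [default_weights()].
#' @param low_cov_auc Low-coverage auc threshold (default 0.5).
#' @param min_reads Read-count warning threshold (default 7e6 reads).
#' @param force_include,force_exclude Character vectors of allele names
#'   added to / removed from the candidate lists after filtering.
#' @param k Index anchor k-mer length.
#' @return A list of class `run_config`.
#' @export
run_config <- function(read_len = 100L, min_trunc_len = 70L,
                       central_threshold = 0.2, weights = default_weights(),
                       low_cov_auc = 0.5, min_reads = 7e6,
                       force_include = character(),
                       force_exclude = character(), k = 16L) {
  stopifnot(min_trunc_len > 0L, central_threshold > 0, low_cov_auc > 0,
            min_reads > 0, all(weights > 0))
  cfg <- list(read_len = as.integer(read_len),
              min_trunc_len = as.integer(min_trunc_len),
              central_threshold = central_threshold, weights = weights,
              low_cov_auc = low_cov_auc, min_reads = min_reads,
              force_include = force_include, force_exclude = force_exclude,
              k = as.integer(k))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a key=value file
#'
#' Flat `key = value` lines (comments with `#`), with keys matching the
#' arguments of [run_config()]; `weights` is given as five comma-separated
#' numbers (asm, req, msl, mppr, auc) and `force_include` /
#' `force_exclude` as comma-separated allele names. Values supplied in
#' `overrides` (e.g. from command-line flags) win over the file.
#'
#' @param path Config file path.
#' @param overrides Named list of [run_config()] arguments taking
#'   precedence over the file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
  known <- names(formals(run_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  numeric_keys <- c("read_len", "min_trunc_len", "central_threshold",
                    "low_cov_auc", "min_reads", "k")
  for (nm in intersect(names(args), numeric_keys)) {
    args[[nm]] <- as.numeric(args[[nm]])
  }
  for (nm in intersect(names(args), c("force_include", "force_exclude"))) {
    args[[nm]] <- strsplit(args[[nm]], ",")[[1L]]
  }
  if ("weights" %in% names(args)) {
    w <- as.numeric(strsplit(args$weights, ",")[[1L]])
    if (length(w) != 5L) stop("weights must be five comma-separated numbers")
    args$weights <- default_weights(w[1L], w[2L], w[3L], w[4L], w[5L])
  }
  args[names(overrides)] <- overrides
  do.call(run_config, args)
}

#' Export a mapping table as TSV (debugging aid)
#'
#' Columns: read id, mate, allele, 0-based start, matched length,
#' truncation flags and strand.
#'
#' @param mappings data.table from [map_reads()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_mappings_tsv <- function(mappings, path) {
  fwrite(mappings, path, sep = "\t")
  invisible(path)
}

#' Genotype one sample from in-memory reads
#'
#' The full per-sample analysis: map both mates against every
#' (non-excluded) allele cDNA, reduce to single start-point profiles,
#' pre-filter candidates per locus and call the genotype of every locus by
#' exhaustive pair scoring. The per-stage counts (reads in, mapped reads,
#' kept start points, candidates, pairs scored) are returned for logging.
#'
#' @param reads1,reads2 Character vectors of mate sequences (`reads2` may
#'   be `NULL` for single-end input).
#' @param ids Read identifiers shared by the mates.
#' @param reference An `allele_reference`.
#' @param config A [run_config()].
#' @param index Optional prebuilt [build_index()] over `reference`.
#' @param sample_id Sample name used in the results table.
#' @return List with `results` (one data.table row per locus), `calls`
#'   (named list of `genotype_call`s), `qc` (per-locus QC tables),
#'   `profiles` and `counts`.
#' @export
genotype_sample <- function(reads1, reads2 = NULL, ids = NULL, reference,
                            config = run_config(), index = NULL,
                            sample_id = "sample") {
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads1))
  if (is.null(index)) {
    index <- build_index(reference, min_trunc_len = config$min_trunc_len,
                         k = config$k)
  }
  total_reads <- length(reads1) + length(reads2)
  m1 <- map_reads(reads1, index, ids = ids, mate = 1L)
  m2 <- if (length(reads2)) map_reads(reads2, index, ids = ids, mate = 2L) else empty_mappings()
  mappings <- rbind(m1, m2)
  mappings[, locus := allele_locus(allele)]

  loci <- reference_loci(reference)
  calls <- list(); qc <- list(); rows <- list(); profs <- list()
  counts <- data.table(locus = character(), n_mapped = integer(),
                       n_kept = integer(), n_candidates = integer(),
                       n_pairs = integer())
  for (l in loci) {
    alleles <- active_alleles(reference, l)
    lm <- mappings[locus == l]
    profiles <- lapply(alleles, function(a) {
      reduce_start_points(lm[allele == a], nchar(reference$cdna[[a]]),
                          read_len = config$read_len, allele = a)
    })
    names(profiles) <- alleles
    sample_auc <- if (length(profiles)) {
      max(vapply(profiles, function(p) {
        ideal <- ideal_profile(p$cdna_len, config$read_len,
                               config$min_trunc_len)
        min(1, sum(p$coverage) / sum(ideal))
      }, 0))
    } else 0
    pf <- prefilter_candidates(profiles,
                               central_threshold = config$central_threshold,
                               low_cov_mode = sample_auc < config$low_cov_auc)
    cand <- union(pf$candidates,
                  intersect(config$force_include, alleles))
    cand <- setdiff(cand, config$force_exclude)
    call <- call_genotype(cand, lm, profiles, locus = l,
                          weights = config$weights,
                          read_len = config$read_len,
                          min_trunc_len = config$min_trunc_len,
                          low_cov_auc = config$low_cov_auc,
                          total_reads = total_reads,
                          min_reads = config$min_reads)
    calls[[l]] <- call
    qc[[l]] <- pf$qc
    profs[[l]] <- profiles
    counts <- rbind(counts, data.table(
      locus = l, n_mapped = nrow(lm),
      n_kept = sum(vapply(profiles, function(p) nrow(p$kept), 0L)),
      n_candidates = length(cand),
      n_pairs = if (is.null(call$pairs)) 0L else nrow(call$pairs)
    ))
    rows[[l]] <- call_row(call, sample_id)
  }
  list(results = rbindlist(rows), calls = calls, qc = qc,
       profiles = profs,
       counts = cbind(counts, n_reads_total = total_reads))
}

call_row <- function(call, sample_id) {
  flags <- paste(names(Filter(isTRUE, call$flags)), collapse = ";")
  if (call$flags$no_call) {
    return(data.table(sample = sample_id, locus = call$locus,
                      allele1 = NA_character_, allele2 = NA_character_,
                      H = NA_real_, n_alternatives = 0L, alternatives = "",
                      asm = NA_real_, req = NA_real_, msl = NA_real_,
                      mppr = NA_real_, auc = NA_real_, flags = flags))
  }
  best <- call$pairs[1L]
  alt <- call$alternatives
  data.table(sample = sample_id, locus = call$locus,
             allele1 = best$allele1, allele2 = best$allele2, H = best$H,
             n_alternatives = nrow(alt),
             alternatives = if (nrow(alt)) {
               paste(paste(alt$allele1, alt$allele2, sep = "/"), collapse = ";")
             } else "",
             asm = best$asm, req = best$req, msl = best$msl,
             mppr = best$mppr, auc = best$auc, flags = flags)
}

#' Genotype a sample from paired FASTQ files
#'
#' Reads the FASTQ pair (plain or gzipped, Casava 1.8 headers), runs
#' [genotype_sample()] and optionally writes the results CSV and QC
#' tables.
#'
#' @param fastq1,fastq2 FASTQ paths (`fastq2` optional).
#' @param reference An `allele_reference`.
#' @param config A [run_config()].
#' @param out_csv Optional results CSV path (one row per locus).
#' @param qc_prefix Optional path prefix for per-locus QC TSVs.
#' @param sample_id Sample name; defaults to the FASTQ basename.
#' @param index Optional prebuilt index.
#' @return As [genotype_sample()].
#' @export
run_call <- function(fastq1, fastq2 = NULL, reference, config = run_config(),
                     out_csv = NULL, qc_prefix = NULL, sample_id = NULL,
                     index = NULL) {
  if (!file.exists(fastq1)) stop("cannot read FASTQ: ", fastq1)
  if (!is.null(fastq2) && !file.exists(fastq2)) {
    stop("cannot read FASTQ: ", fastq2)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("(_R?1)?\\.(fastq|fq)(\\.gz)?$", "", basename(fastq1))
  }
  f1 <- read_fastq(fastq1)
  f2 <- if (!is.null(fastq2)) read_fastq(fastq2) else NULL
  if (!is.null(f2) && length(f2$seqs) != length(f1$seqs)) {
    stop("mate files differ in read count")
  }
  res <- genotype_sample(f1$seqs, f2$seqs, ids = f1$ids, reference = reference,
                         config = config, index = index, sample_id = sample_id)
  if (!is.null(out_csv)) write_results_csv(res$results, out_csv)
  if (!is.null(qc_prefix)) write_qc_tables(res$qc, qc_prefix)
  res
}

#' Write a results table as CSV
#'
#' One row per sample and locus: the called allele pair, its harmonic-mean
#' score, the number and identity of alternative (indistinguishable)
#' pairs, the raw parameters of the best pair and the QC flags.
#'
#' @param results Results data.table from [genotype_sample()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_results_csv <- function(results, path) {
  fwrite(results, path, sep = ",")
  invisible(path)
}

#' Write per-locus QC tables as TSV
#'
#' For each locus, `<prefix><locus>_failed.tsv` (alleles that failed the
#' initial QC, with the number of QC-failed positions) and
#' `<prefix><locus>_undercovered.tsv` (top 50 alleles not covered 100%,
#' ascending by uncovered bases).
#'
#' @param qc Per-locus QC list from [genotype_sample()].
#' @param prefix Path prefix.
#' @return Invisibly, the paths written.
#' @export
write_qc_tables <- function(qc, prefix) {
  paths <- character()
  for (l in names(qc)) {
    p1 <- paste0(prefix, l, "_failed.tsv")
    p2 <- paste0(prefix, l, "_undercovered.tsv")
    fwrite(qc[[l]]$failed, p1, sep = "\t")
    fwrite(qc[[l]]$undercovered, p2, sep = "\t")
    paths <- c(paths, p1, p2)
    if (!is.null(qc[[l]]$review)) {
      p3 <- paste0(prefix, l, "_review.tsv")
      fwrite(qc[[l]]$review, p3, sep = "\t")
      paths <- c(paths, p3)
    }
  }
  invisible(paths)
}

#' Dump a per-allele coverage profile for plotting
#'
#' TSV with columns `position` (0-based), `observed` (unique start-point
#' coverage) and `ideal` (the expected profile when every admissible
#' start point occurs once).
#'
#' @param profile A `start_profile`.
#' @param path Output TSV path.
#' @param min_trunc_len Minimum truncated mapping length.
#' @return Invisibly, `path`.
#' @export
write_coverage_profile <- function(profile, path, min_trunc_len = 70L) {
  ideal <- ideal_profile(profile$cdna_len, profile$read_len, min_trunc_len)
  fwrite(data.table(position = seq_len(profile$cdna_len) - 1L,
                    observed = profile$coverage, ideal = ideal),
         path, sep = "\t")
  invisible(path)
}

#' Measure truth recovery of the caller on simulated genotypes
#'
#' Draws random diploid genotypes per locus (alleles sampled with
#' replacement, so homozygotes occur), simulates error-free paired reads
#' at the configured unique start-point depth, runs the full mapping,
#' filtering and pair-scoring pipeline, and records whether the true pair
#' is ranked first. This is the synthetic analogue of a benchmark call
#' rate: it measures the caller, not any particular real data set.
#'
#' @param sim Output of [simulate_reference()] (or an `allele_reference`).
#' @param n_per_locus Genotypes drawn per locus.
#' @param read_cfg A [sim_read_config()]; its seed is re-derived per
#'   genotype from `seed`.
#' @param config A [run_config()].
#' @param seed Master seed for genotype drawing and read simulation.
#' @param loci Optional subset of loci.
#' @return data.table with one row per simulated genotype: locus,
#'   replicate, truth and called pairs, rank-1 correctness, score and
#'   alternative count.
#' @export
evaluate_truth_recovery <- function(sim, n_per_locus = 100L,
                                    read_cfg = sim_read_config(),
                                    config = run_config(), seed = 1L,
                                    loci = NULL) {
  ref <- if (inherits(sim, "allele_reference")) sim else sim$reference
  if (is.null(loci)) loci <- reference_loci(ref)
  rows <- list()
  for (l in loci) {
    alleles <- active_alleles(ref, l)
    sub <- subset_reference(ref, alleles)
    index <- build_index(sub, min_trunc_len = config$min_trunc_len,
                         k = config$k)
    gts <- with_seed(derive_seed(seed, match(l, loci)), {
      matrix(sample(alleles, 2L * n_per_locus, replace = TRUE), ncol = 2L)
    })
    for (r in seq_len(n_per_locus)) {
      gt <- sort(gts[r, ])
      rc <- read_cfg
      rc$seed <- derive_seed(seed, 10000L + 100L * match(l, loci) + r)
      reads <- simulate_reads(gt, sub, rc, min_trunc_len = config$min_trunc_len)
      res <- genotype_sample(reads$reads1, reads$reads2, ids = reads$ids,
                             reference = sub, config = config, index = index,
                             sample_id = sprintf("%s_rep%03d", l, r))
      row <- res$results[1L]
      called <- sort(c(row$allele1, row$allele2))
      rows[[length(rows) + 1L]] <- data.table(
        locus = l, rep = r, truth1 = gt[1L], truth2 = gt[2L],
        called1 = called[1L], called2 = called[2L],
        correct = identical(called, gt), H = row$H,
        n_alternatives = row$n_alternatives
      )
    }
  }
  rbindlist(rows)
}

# Restrict a reference to a subset of alleles (used to run loci
# independently).
subset_reference <- function(ref, alleles) {
  keep <- ref$name %in% alleles
  excl <- ref$exclusion_reason[names(ref$exclusion_reason) %in% ref$name[keep]]
  allele_reference(ref$name[keep], unname(ref$cdna[keep]),
                   unname(ref$exons[keep]), excluded = excl)
}
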