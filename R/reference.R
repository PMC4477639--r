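#' Construct a validated multi-locus allele reference
#'
#' An allele reference holds the cDNA sequence of every allele, its exon
#' partition and an exclusion flag (e.g. for suspected chimeric database
#' entries, which are loaded but skipped by the caller). Exon bounds are
#' 0-based half-open intervals in cDNA coordinates and must exactly
#' partition each sequence.
#'
#' @param names Character vector of allele names (`LOCUS*F1:F2...`).
#' @param cdna Character vector of cDNA sequences over A/C/G/T.
#' @param exons List of two-column integer matrices (`start`, `end`),
#'   one per allele, 0-based half-open, partitioning `[0, nchar(cdna))`.
#' @param excluded Character vector of allele names to flag as excluded,
#'   or a named character vector whose names are alleles and values the
#'   reasons.
#' @return An object of class `allele_reference`.
#' @export
allele_reference <- function(names, cdna, exons, excluded = character()) {
  stopifnot(length(names) == length(cdna), length(cdna) == length(exons))
  if (anyDuplicated(names)) {
    stop("duplicate allele name(s): ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  bad <- !is_allele_name(names)
  if (any(bad)) stop("invalid allele name(s): ", paste(names[bad], collapse = ", "))
  cdna <- toupper(cdna)
  if (!all(is_dna(cdna)) || any(nchar(cdna) == 0L)) {
    stop("cDNA sequences must be nonempty and contain only A/C/G/T; offending: ",
         paste(names[!is_dna(cdna) | nchar(cdna) == 0L], collapse = ", "))
  }
  exons <- lapply(seq_along(exons), function(i) {
    m <- exons[[i]]
    m <- matrix(as.integer(m), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
    m <- m[order(m[, 1L]), , drop = FALSE]
    len <- nchar(cdna[i])
    ok <- nrow(m) >= 1L && m[1L, 1L] == 0L && m[nrow(m), 2L] == len &&
      all(m[, 2L] > m[, 1L]) &&
      (nrow(m) == 1L || all(m[-1L, 1L] == m[-nrow(m), 2L]))
    if (!ok) {
      stop("exon bounds of allele ", names[i],
           " do not partition [0, ", len, ")")
    }
    m
  })
  if (is.null(base::names(excluded))) {
    excluded <- stats::setNames(rep("excluded", length(excluded)), excluded)
  }
  unknown <- setdiff(base::names(excluded), names)
  if (length(unknown)) {
    stop("exclusion list names unknown allele(s): ", paste(unknown, collapse = ", "))
  }
  locus <- allele_locus(names)
  excl <- names %in% base::names(excluded)
  for (l in unique(locus)) {
    if (all(excl[locus == l])) {
      stop("locus ", l, " has no non-excluded allele")
    }
  }
  ref <- list(
    name = names,
    locus = locus,
    cdna = stats::setNames(cdna, names),
    exons = stats::setNames(exons, names),
    excluded = stats::setNames(excl, names),
    exclusion_reason = excluded
  )
  class(ref) <- "allele_reference"
  ref
}

#' @export
print.allele_reference <- function(x, ...) {
  cat("allele_reference:", length(x$name), "alleles,",
      length(unique(x$locus)), "loci\n")
  tab <- table(x$locus)
  for (l in names(tab)) {
    cat("  ", l, ": ", tab[[l]], " alleles (",
        sum(x$excluded[x$locus == l]), " excluded)\n", sep = "")
  }
  invisible(x)
}

#' @export
length.allele_reference <- function(x) length(x$name)

reference_loci <- function(ref) unique(ref$locus)

# Names of alleles usable for mapping/calling (non-excluded), optionally
# restricted to one locus.
active_alleles <- function(ref, locus = NULL) {
  keep <- !ref$excluded
  if (!is.null(locus)) keep <- keep & ref$locus == locus
  ref$name[keep]
}

#' Read an allele reference from FASTA plus exon annotation
#'
#' The FASTA dialect mirrors IMGT-style headers: the allele name is taken
#' from the second whitespace-separated header token when that token is a
#' valid allele name (as in `>HLA:HLA00001 A*01:01:01:01 1098 bp`), else
#' from the first token. Exon boundaries are supplied as a sidecar
#' tab-separated file with columns `allele_name`, `exon_index`, `start`,
#' `end` (0-based half-open). An optional plain-text exclusion list names
#' alleles to flag as excluded (one name per line, optionally followed by
#' a reason after a tab).
#'
#' @param fasta_file Path to the cDNA FASTA file.
#' @param exon_file Path to the exon annotation TSV.
#' @param exclusion_file Optional path to a plain-text exclusion list.
#' @return An `allele_reference`.
#' @export
read_allele_reference <- function(fasta_file, exon_file, exclusion_file = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_file)
  headers <- names(seqs)
  toks <- strsplit(headers, "[ \t]+")
  nm <- vapply(toks, function(t) {
    if (length(t) >= 2L && is_allele_name(t[2L])) t[2L] else t[1L]
  }, "")
  bad <- !is_allele_name(nm)
  if (any(bad)) {
    stop("FASTA header(s) carry no parseable allele name: ",
         paste(headers[bad], collapse = "; "))
  }
  ann <- fread(exon_file, sep = "\t", header = TRUE,
               colClasses = list(character = "allele_name"))
  req <- c("allele_name", "exon_index", "start", "end")
  if (!all(req %in% names(ann))) {
    stop("exon annotation must have columns: ", paste(req, collapse = ", "))
  }
  missing_ann <- setdiff(nm, ann$allele_name)
  if (length(missing_ann)) {
    stop("no exon annotation for allele(s): ", paste(missing_ann, collapse = ", "))
  }
  setorderv(ann, c("allele_name", "exon_index"))
  exons <- lapply(nm, function(a) {
    sub <- ann[ann$allele_name == a]
    cbind(start = sub$start, end = sub$end)
  })
  excl <- character()
  if (!is.null(exclusion_file)) {
    lines <- readLines(exclusion_file)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t")
    excl <- stats::setNames(
      vapply(parts, function(p) if (length(p) > 1L) p[2L] else "excluded", ""),
      vapply(parts, `[`, "", 1L)
    )
  }
  allele_reference(nm, as.character(seqs), exons, excluded = excl)
}

#' Write an allele reference to FASTA plus exon annotation
#'
#' Inverse of [read_allele_reference()]; writing then re-reading an
#' in-memory reference reproduces it exactly, and re-writing a file read
#' with [read_allele_reference()] reproduces the file byte-wise.
#'
#' @param ref An `allele_reference`.
#' @param fasta_file,exon_file Output paths.
#' @param exclusion_file Optional output path for the exclusion list; only
#'   written when the reference flags any allele.
#' @return Invisibly, `ref`.
#' @export
write_allele_reference <- function(ref, fasta_file, exon_file,
                                   exclusion_file = NULL) {
  headers <- sprintf("HLA:SIM%05d %s %d bp",
                     seq_along(ref$name), ref$name, nchar(ref$cdna))
  seqs <- Biostrings::DNAStringSet(unname(ref$cdna))
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, fasta_file, width = 80L)
  ann <- rbindlist(lapply(seq_along(ref$name), function(i) {
    m <- ref$exons[[i]]
    data.table(allele_name = ref$name[i], exon_index = seq_len(nrow(m)),
               start = m[, "start"], end = m[, "end"])
  }))
  fwrite(ann, exon_file, sep = "\t")
  if (!is.null(exclusion_file) && any(ref$excluded)) {
    nm <- names(ref$excluded)[ref$excluded]
    writeLines(paste(nm, ref$exclusion_reason[nm], sep = "\t"), exclusion_file)
  }
  invisible(ref)
}

#' Read a diploid genotype table
#'
#' Tab-separated with columns `sample`, `locus`, `allele1`, `allele2`;
#' one row per sample and locus, allele pairs unordered.
#'
#' @param file Path to the TSV file.
#' @return A data.table.
#' @export
read_genotype_table <- function(file) {
  gt <- fread(file, sep = "\t", header = TRUE)
  req <- c("sample", "locus", "allele1", "allele2")
  if (!all(req %in% names(gt))) {
    stop("genotype table must have columns: ", paste(req, collapse = ", "))
  }
  bad <- !is_allele_name(gt$allele1) | !is_allele_name(gt$allele2)
  if (any(bad)) {
    stop("unresolvable allele name(s) in genotype table rows: ",
         paste(which(bad), collapse = ", "))
  }
  gt
}
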