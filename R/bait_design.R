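#' Tile a sequence with fixed-length baits
#'
#' Non-overlapping tiling at offsets 0, L, 2L, ...; when a final partial
#' window shorter than the bait length remains, one extra bait anchored at
#' the 3' end is emitted (overlapping the previous tile) so the tail is
#' still covered.
#'
#' @param seq A DNA string.
#' @param source_id Name recorded for the tiled sequence.
#' @param bait_len Bait length in bp (capture probes are 120 bp RNA baits).
#' @return A data.table of baits with columns `sequence`, `source_id`,
#'   `start`, `end` (0-based half-open on the source). Sequences shorter
#'   than `bait_len` yield an empty table with a warning.
#' @export
tile_sequence <- function(seq, source_id = "seq", bait_len = 120L) {
  len <- nchar(seq)
  if (len < bait_len) {
    warning("sequence ", source_id, " shorter than bait length (", len,
            " < ", bait_len, "); no baits emitted")
    return(data.table(sequence = character(), source_id = character(),
                      start = integer(), end = integer()))
  }
  starts <- seq.int(0L, len - bait_len, by = bait_len)
  if (len %% bait_len != 0L) starts <- c(starts, len - bait_len)
  data.table(
    sequence = substring(seq, starts + 1L, starts + bait_len),
    source_id = source_id,
    start = as.integer(starts),
    end = as.integer(starts + bait_len)
  )
}

#' Mismatch-tolerant placements of one bait on a target
#'
#' Ungapped Hamming-distance scan of the bait and its reverse complement
#' at every offset of the target; placements with at most `max_mm`
#' mismatches are reported. Capture hybridisation tolerates scattered
#' mismatches but not gaps, so an ungapped scan is the appropriate model
#' for deciding which targets a bait can pull down.
#'
#' @param bait_seq Bait sequence (character scalar).
#' @param target Target DNA string.
#' @param max_mm Maximum number of mismatches (default 5).
#' @return data.table with columns `offset` (0-based), `mismatch_count`,
#'   `strand`.
#' @export
scan_mismatch_hits <- function(bait_seq, target, max_mm = 5L) {
  subject <- Biostrings::DNAString(target)
  hits_for <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  max.mismatch = max_mm, with.indels = FALSE,
                                  fixed = TRUE)
    if (length(m) == 0L) {
      return(data.table(offset = integer(), mismatch_count = integer(),
                        strand = character()))
    }
    st <- BiocGenerics::start(m)
    mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), subject,
                                      starting.at = st, with.indels = FALSE,
                                      fixed = TRUE)
    data.table(offset = st - 1L, mismatch_count = as.integer(mm),
               strand = strand)
  }
  res <- rbindlist(list(hits_for(bait_seq, "+"),
                        hits_for(revcomp(bait_seq), "-")))
  setorderv(res, c("offset", "strand"))
  res
}

# Footprints (0-based half-open intervals) of all panel baits on a target.
# Seed-and-verify Hamming scan: each bait is split into max_mm + 1 disjoint
# seed chunks, so any placement with <= max_mm mismatches contains at least
# one chunk exactly (pigeonhole); chunk occurrences are found in one exact
# multi-pattern pass and candidate placements verified by direct character
# comparison. Exact, and far faster than a per-bait scan.
.scanner_cache <- new.env(parent = emptyenv())

panel_footprints <- function(target, panel, max_mm) {
  seqs <- unique(panel$sequence)
  if (length(seqs) == 0L) return(data.table(start = integer(), end = integer()))
  bl <- nchar(seqs[1L])
  stopifnot(all(nchar(seqs) == bl))
  k <- max_mm + 1L
  w <- bl %/% k
  tlen <- nchar(target)
  if (tlen < w) return(data.table(start = integer(), end = integer()))
  # seed dictionary memo: panels are scanned against many targets in a row
  cc <- .scanner_cache
  if (!identical(cc$seqs, seqs) || !identical(cc$k, k)) {
    probes <- c(seqs, revcomp(seqs))
    chunk_off <- (seq_len(k) - 1L) * w
    seed_tab <- data.table(
      probe = rep(seq_along(probes), each = k),
      coff = rep(chunk_off, length(probes))
    )
    seed_tab[, seed := substring(probes[probe], coff + 1L, coff + w)]
    cc$seqs <- seqs; cc$k <- k; cc$probes <- probes
    cc$seed_tab <- seed_tab
    cc$useeds <- unique(seed_tab$seed)
    cc$pdict <- Biostrings::PDict(Biostrings::DNAStringSet(cc$useeds))
  }
  probes <- cc$probes
  seed_tab <- cc$seed_tab
  useeds <- cc$useeds
  m <- Biostrings::matchPDict(cc$pdict, Biostrings::DNAString(target))
  st <- BiocGenerics::start(m)
  occ <- data.table(seed = rep(useeds, lengths(st)), spos = unlist(st) - 1L)
  if (nrow(occ) == 0L) return(data.table(start = integer(), end = integer()))
  cand <- seed_tab[occ, on = "seed", allow.cartesian = TRUE]
  cand[, off := spos - coff]
  cand <- unique(cand[off >= 0L & off + bl <= tlen, list(probe, off)])
  if (nrow(cand) == 0L) return(data.table(start = integer(), end = integer()))
  # verify candidates: Hamming distance by direct character comparison
  pm <- matrix(unlist(strsplit(probes[cand$probe], "", fixed = TRUE)),
               ncol = bl, byrow = TRUE)
  tm <- matrix(unlist(strsplit(substring(target, cand$off + 1L,
                                         cand$off + bl), "", fixed = TRUE)),
               ncol = bl, byrow = TRUE)
  mm <- rowSums(pm != tm)
  hits <- cand[mm <= max_mm]
  if (nrow(hits) == 0L) return(data.table(start = integer(), end = integer()))
  unique(data.table(start = hits$off, end = hits$off + bl))
}

#' Uncovered runs of a target under a bait panel
#'
#' Marks every target position lying inside the footprint of any
#' mismatch-tolerant bait placement as covered; maximal uncovered runs of
#' at least `min_len` bases are returned as 0-based half-open intervals.
#'
#' @param target Target DNA string.
#' @param panel A bait panel (data.table with a `sequence` column, e.g.
#'   from [design_panel()] or [tile_sequence()]).
#' @param max_mm Maximum mismatches per bait placement.
#' @param min_len Minimum run length to report (the gap-filling step only
#'   acts on runs at least one bait length long).
#' @return data.table with columns `start`, `end`.
#' @export
uncovered_runs <- function(target, panel, max_mm = 5L, min_len = 120L) {
  stopifnot(min_len >= 1L)
  if (inherits(panel, "bait_panel")) panel <- panel$baits
  len <- nchar(target)
  fp <- panel_footprints(target, panel, max_mm)
  covered <- if (is.null(fp) || nrow(fp) == 0L) {
    rep(FALSE, len)
  } else {
    footprint_coverage(fp$start, fp$end - fp$start, len) > 0
  }
  runs <- logical_runs(!covered)
  runs[runs$end - runs$start >= min_len]
}

#' Design a capture bait panel by tiling plus iterative gap filling
#'
#' The panel starts as the plain tiling of the genomic reference
#' haplotypes. Each gDNA of the allele collection is then scanned in input
#' order against the current panel (mismatch-tolerant, both strands); any
#' uncovered run of at least one bait length is tiled from the gDNA's own
#' sequence and the new baits appended. The same pass is then run over the
#' cDNA collection, where each exon is treated as a stand-alone sequence.
#' Exon records shorter than the bait length cannot be tiled; they are
#' checked for containment inside an existing bait (at most `max_mm`
#' mismatches) and otherwise recorded as warnings.
#'
#' @param genomic_refs Named character vector of genomic reference
#'   haplotype sequences.
#' @param gdna_collection Named character vector of genomic allele
#'   sequences (may be empty).
#' @param cdna_exon_collection Named character vector of stand-alone exon
#'   sequences (may be empty).
#' @param bait_len Bait length (default 120 bp).
#' @param max_mm Maximum mismatches for a bait to count as covering
#'   (default 5).
#' @return A `bait_panel`: list with `baits` (data.table: `sequence`,
#'   `source_id`, `start`, `end`), `n_distinct` (the reported bait count,
#'   i.e. number of distinct sequences) and `warnings` (data.table of
#'   short uncoverable exon records). Deterministic for identical inputs
#'   in identical order.
#' @export
design_panel <- function(genomic_refs, gdna_collection = character(),
                         cdna_exon_collection = character(),
                         bait_len = 120L, max_mm = 5L) {
  stopifnot(length(genomic_refs) >= 1L, !is.null(names(genomic_refs)))
  baits <- rbindlist(lapply(names(genomic_refs), function(id) {
    tile_sequence(genomic_refs[[id]], id, bait_len)
  }))
  warn <- data.table(source_id = character(), length = integer())

  fill_gaps <- function(baits, targets) {
    for (id in names(targets)) {
      tg <- targets[[id]]
      if (nchar(tg) < bait_len) {
        contained <- any(vapply(unique(baits$sequence), function(b) {
          length(BiocGenerics::start(Biostrings::matchPattern(
            Biostrings::DNAString(tg), Biostrings::DNAString(b),
            max.mismatch = max_mm, with.indels = FALSE, fixed = TRUE))) > 0L ||
            length(BiocGenerics::start(Biostrings::matchPattern(
              Biostrings::DNAString(revcomp(tg)), Biostrings::DNAString(b),
              max.mismatch = max_mm, with.indels = FALSE, fixed = TRUE))) > 0L
        }, logical(1L)))
        if (!contained) {
          warning("record ", id, " shorter than bait length and not covered")
          warn <<- rbind(warn, data.table(source_id = id, length = nchar(tg)))
        }
        next
      }
      runs <- uncovered_runs(tg, baits, max_mm = max_mm, min_len = bait_len)
      if (nrow(runs)) {
        new <- rbindlist(lapply(seq_len(nrow(runs)), function(i) {
          sub <- substring(tg, runs$start[i] + 1L, runs$end[i])
          b <- tile_sequence(sub, id, bait_len)
          b$start <- b$start + runs$start[i]
          b$end <- b$end + runs$start[i]
          b
        }))
        baits <- rbind(baits, new[!new$sequence %in% baits$sequence])
      }
    }
    baits
  }

  baits <- fill_gaps(baits, as.list(gdna_collection))
  baits <- fill_gaps(baits, as.list(cdna_exon_collection))
  baits <- baits[!duplicated(baits$sequence)]
  panel <- list(baits = baits, n_distinct = length(unique(baits$sequence)),
                bait_len = bait_len, max_mm = max_mm, warnings = warn)
  class(panel) <- "bait_panel"
  panel
}

#' @export
print.bait_panel <- function(x, ...) {
  cat("bait_panel:", x$n_distinct, "distinct baits of", x$bait_len, "bp\n")
  if (nrow(x$warnings)) {
    cat("  uncoverable short records:", nrow(x$warnings), "\n")
  }
  invisible(x)
}

#' Write a bait panel as FASTA plus BED
#'
#' BED columns are `source_id`, `start`, `end`, `bait index` (0-based
#' half-open coordinates on the source sequence).
#'
#' @param panel A `bait_panel`.
#' @param fasta_file,bed_file Output paths.
#' @return Invisibly, `panel`.
#' @export
write_bait_panel <- function(panel, fasta_file, bed_file) {
  b <- panel$baits
  ids <- sprintf("bait_%05d %s:%d-%d", seq_len(nrow(b)), b$source_id,
                 b$start, b$end)
  seqs <- Biostrings::DNAStringSet(b$sequence)
  names(seqs) <- ids
  Biostrings::writeXStringSet(seqs, fasta_file, width = 80L)
  bed <- data.table(chrom = b$source_id, start = b$start, end = b$end,
                    name = sprintf("bait_%05d", seq_len(nrow(b))))
  fwrite(bed, bed_file, sep = "\t", col.names = FALSE)
  invisible(panel)
}
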