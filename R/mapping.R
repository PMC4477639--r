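#' Build an exact-match mapping index over a cDNA allele collection
#'
#' Mapping is strictly perfect-match: a read placement is admissible only
#' if the matched read substring equals the cDNA substring exactly. The
#' single exception is boundary truncation: a read prefix or suffix of at
#' least `min_trunc_len` bases may match provided the alignment terminates
#' exactly at a cDNA end or an annotated internal exon boundary on the
#' truncated side (such reads arise from genomic fragments straddling
#' exon/intron junctions or gene flanks). Both strands are searched.
#'
#' The index anchors candidate placements on the first `k` bases of the
#' (possibly reverse-complemented or reversed) read via a k-mer position
#' table and verifies each candidate by direct substring comparison, so
#' results are exact.
#'
#' @param reference An `allele_reference`.
#' @param min_trunc_len Minimum truncated mapping length at exon
#'   boundaries (default 70 bp).
#' @param k Anchor k-mer length (must not exceed `min_trunc_len`).
#' @param include_excluded Index alleles flagged as excluded too?
#' @return A `mapping_index`.
#' @export
build_index <- function(reference, min_trunc_len = 70L, k = 16L,
                        include_excluded = FALSE) {
  stopifnot(inherits(reference, "allele_reference"), k <= min_trunc_len)
  keep <- if (include_excluded) rep(TRUE, length(reference$name)) else !reference$excluded
  nm <- reference$name[keep]
  cdna <- unname(reference$cdna[nm])
  len <- nchar(cdna)
  if (any(len < k)) stop("cDNA shorter than anchor k-mer length")
  rev_cdna <- revstr(cdna)

  kmer_table <- function(texts) {
    rbindlist(lapply(seq_along(texts), function(i) {
      L <- nchar(texts[i])
      pos <- seq_len(L - k + 1L) - 1L
      data.table(kmer = substring(texts[i], pos + 1L, pos + k),
                 ai = i, pos = pos)
    }))
  }
  fwd_tab <- kmer_table(cdna)
  setkey(fwd_tab, kmer)
  rev_tab <- kmer_table(rev_cdna)
  setkey(rev_tab, kmer)

  # admissible truncation endpoints, forward text: internal exon ends + cDNA
  # end; reversed text: len - (exon starts), including len - 0
  ends_fwd <- rbindlist(lapply(seq_along(nm), function(i) {
    m <- reference$exons[[nm[i]]]
    data.table(ai = i, e = sort(unique(as.integer(m[, "end"]))))
  }))
  ends_rev <- rbindlist(lapply(seq_along(nm), function(i) {
    m <- reference$exons[[nm[i]]]
    data.table(ai = i, e = sort(unique(len[i] - as.integer(m[, "start"]))))
  }))

  idx <- list(allele = nm, locus = allele_locus(nm), cdna = cdna,
              rev_cdna = rev_cdna, len = len, fwd_tab = fwd_tab,
              rev_tab = rev_tab, ends_fwd = ends_fwd, ends_rev = ends_rev,
              k = k, min_trunc_len = as.integer(min_trunc_len))
  class(idx) <- "mapping_index"
  idx
}

#' @export
print.mapping_index <- function(x, ...) {
  cat("mapping_index:", length(x$allele), "alleles, k =", x$k,
      ", min truncated length =", x$min_trunc_len, "bp\n")
  invisible(x)
}

# One anchored pass: find placements where a PREFIX of each probe matches a
# text exactly, either full length or ending at an admissible endpoint with
# length >= min_trunc_len. `side` selects forward or reversed texts.
prefix_pass <- function(probes, idx, side = c("fwd", "rev"),
                        full_allowed = TRUE) {
  side <- match.arg(side)
  tab <- if (side == "fwd") idx$fwd_tab else idx$rev_tab
  texts <- if (side == "fwd") idx$cdna else idx$rev_cdna
  ends <- if (side == "fwd") idx$ends_fwd else idx$ends_rev
  k <- idx$k
  Tm <- idx$min_trunc_len
  n <- length(probes)
  plen <- nchar(probes)
  if (any(plen < Tm)) stop("probe shorter than min_trunc_len")
  cand <- tab[data.table(kmer = substring(probes, 1L, k), pidx = seq_len(n)),
              on = "kmer", nomatch = NULL]
  if (nrow(cand) == 0L) {
    return(data.table(pidx = integer(), ai = integer(), pos = integer(),
                      matched_len = integer(), full = logical()))
  }
  cand[, plen := plen[pidx]]
  cand[, tlen := idx$len[ai]]
  # full-length verification
  cand[, full := tlen - pos >= plen &
         substring(texts[ai], pos + 1L, pos + plen) ==
           substring(probes[pidx], 1L, plen)]
  out_full <- if (full_allowed) {
    cand[full == TRUE,
         list(pidx, ai, pos, matched_len = plen, full = TRUE)]
  } else {
    data.table(pidx = integer(), ai = integer(), pos = integer(),
               matched_len = integer(), full = logical())
  }
  # truncated: only where no full match at this placement
  tc <- cand[full == FALSE]
  if (nrow(tc)) {
    tc <- ends[tc, on = "ai", allow.cartesian = TRUE, nomatch = NULL]
    tc[, L := e - pos]
    tc <- tc[L >= Tm & L <= plen - 1L]
    if (nrow(tc)) {
      tc <- tc[substring(texts[ai], pos + 1L, e) ==
                 substring(probes[pidx], 1L, L)]
    }
    if (nrow(tc)) {
      # keep the longest admissible truncation per placement
      setorderv(tc, c("pidx", "ai", "pos", "L"), c(1L, 1L, 1L, -1L))
      tc <- tc[!duplicated(tc[, list(pidx, ai, pos)])]
      out_trunc <- tc[, list(pidx, ai, pos, matched_len = L, full = FALSE)]
      return(rbind(out_full, out_trunc))
    }
  }
  out_full
}

#' Map reads to the allele collection (perfect matches only)
#'
#' Returns every admissible placement of every read: full-length exact
#' matches on either strand, plus boundary-truncated prefix/suffix matches
#' of at least `min_trunc_len` bases (see [build_index()]). Reads mapping
#' many alleles keep all their placements — multi-mapping carries the
#' allele-specific signal used downstream. Reads containing N never match.
#'
#' @param seqs Character vector of read sequences.
#' @param index A `mapping_index`.
#' @param ids Read identifiers (defaults to seq_along).
#' @param mate Mate index per read (1 or 2), recycled.
#' @return data.table with columns `id`, `mate`, `allele`, `start`
#'   (0-based cDNA offset of the footprint), `matched_len`,
#'   `truncated_5p`, `truncated_3p`, `strand`. At most one placement per
#'   `(allele, start, strand)` is reported per read, preferring full-length
#'   over truncated and longer truncations over shorter.
#' @export
map_reads <- function(seqs, index, ids = seq_along(seqs), mate = 1L) {
  stopifnot(inherits(index, "mapping_index"))
  n <- length(seqs)
  if (n == 0L) return(empty_mappings())
  mate <- rep_len(as.integer(mate), n)
  seqs <- toupper(seqs)
  rc <- revcomp(seqs)
  rv <- revstr(seqs)
  cp <- complement_str(seqs)
  L <- index$len

  # pass A: read prefix vs forward text        -> '+' strand, 3' truncation
  # pass B: revcomp prefix vs forward text     -> '-' strand, 3' truncation
  # pass C: reversed read prefix vs rev text   -> '+' strand, 5' truncation
  # pass D: complement prefix vs rev text      -> '-' strand, 5' truncation
  a <- prefix_pass(seqs, index, "fwd")
  b <- prefix_pass(rc, index, "fwd")
  cc <- prefix_pass(rv, index, "rev", full_allowed = FALSE)
  d <- prefix_pass(cp, index, "rev", full_allowed = FALSE)

  conv_fwd <- function(x, strand) {
    if (nrow(x) == 0L) return(NULL)
    data.table(pidx = x$pidx, ai = x$ai, start = x$pos,
               matched_len = x$matched_len,
               truncated_5p = FALSE, truncated_3p = !x$full,
               strand = strand, full = x$full)
  }
  conv_rev <- function(x, strand) {
    if (nrow(x) == 0L) return(NULL)
    data.table(pidx = x$pidx, ai = x$ai,
               start = L[x$ai] - (x$pos + x$matched_len),
               matched_len = x$matched_len,
               truncated_5p = TRUE, truncated_3p = FALSE,
               strand = strand, full = FALSE)
  }
  res <- rbindlist(list(conv_fwd(a, "+"), conv_fwd(b, "-"),
                        conv_rev(cc, "+"), conv_rev(d, "-")))
  if (is.null(res) || nrow(res) == 0L) return(empty_mappings())
  setorderv(res, c("pidx", "ai", "start", "strand", "full", "matched_len"),
            c(1L, 1L, 1L, 1L, -1L, -1L))
  res <- res[!duplicated(res[, list(pidx, ai, start, strand)])]
  out <- data.table(
    id = ids[res$pidx], mate = mate[res$pidx],
    allele = index$allele[res$ai], start = res$start,
    matched_len = res$matched_len,
    truncated_5p = res$truncated_5p & !res$full,
    truncated_3p = res$truncated_3p & !res$full,
    strand = res$strand
  )
  out
}

empty_mappings <- function() {
  data.table(id = character(), mate = integer(), allele = character(),
             start = integer(), matched_len = integer(),
             truncated_5p = logical(), truncated_3p = logical(),
             strand = character())
}

#' Map a single read
#'
#' Convenience wrapper around [map_reads()].
#'
#' @param seq Read sequence.
#' @param index A `mapping_index`.
#' @param id Read identifier.
#' @return See [map_reads()].
#' @export
map_read <- function(seq, index, id = "read1") {
  map_reads(seq, index, ids = id)
}

#' Exact occurrences of a probe in the indexed collection
#'
#' Substring lookup of an arbitrary probe (length at least the anchor
#' k-mer) against every indexed cDNA, both strands, without boundary
#' truncation.
#'
#' @param index A `mapping_index`.
#' @param probe Probe sequence.
#' @return data.table with columns `allele`, `start` (0-based), `strand`.
#' @export
query_index <- function(index, probe) {
  stopifnot(nchar(probe) >= index$k)
  hit_one <- function(p, strand) {
    cand <- index$fwd_tab[list(substring(p, 1L, index$k)), on = "kmer",
                          nomatch = NULL]
    if (nrow(cand) == 0L) return(NULL)
    Lp <- nchar(p)
    ok <- index$len[cand$ai] - cand$pos >= Lp &
      substring(index$cdna[cand$ai], cand$pos + 1L, cand$pos + Lp) == p
    cand <- cand[ok]
    if (nrow(cand) == 0L) return(NULL)
    data.table(allele = index$allele[cand$ai], start = cand$pos,
               strand = strand)
  }
  res <- rbindlist(list(hit_one(toupper(probe), "+"),
                        hit_one(revcomp(toupper(probe)), "-")))
  if (is.null(res) || nrow(res) == 0L) {
    return(data.table(allele = character(), start = integer(),
                      strand = character()))
  }
  setorderv(res, c("allele", "start", "strand"))
  res
}

#' Reduce mappings of one allele to single start-point mappings
#'
#' Collapses all mappings sharing the same placement (start, matched
#' length and strand) on one allele to a single representative, removing
#' the depth inflation caused by duplicated fragments. The representative
#' is the first record in (id, mate) order, so reduction is deterministic
#' and idempotent.
#'
#' @param mappings data.table of mappings (as from [map_reads()]), all on
#'   the same allele.
#' @param cdna_len Length of the allele's cDNA.
#' @param read_len Nominal read length (used downstream by the central
#'   read filter and the ideal profile).
#' @param allele Allele name (taken from `mappings` if present).
#' @return A `start_profile`: list with `allele`, `cdna_len`, `read_len`,
#'   `kept` (the deduplicated mapping table), `starts` (per-position count
#'   of distinct mapping start points) and `coverage` (per-position depth
#'   of the kept mappings).
#' @export
reduce_start_points <- function(mappings, cdna_len, read_len = 100L,
                                allele = NULL) {
  m <- as.data.table(mappings)
  if (is.null(allele)) {
    allele <- if (nrow(m)) m$allele[1L] else NA_character_
  }
  if (nrow(m) && length(unique(m$allele)) > 1L) {
    stop("mappings reference more than one allele")
  }
  if (nrow(m)) {
    setorderv(m, c("start", "matched_len", "strand", "id", "mate"))
    kept <- m[!duplicated(m[, list(start, matched_len, strand)])]
  } else {
    kept <- m
  }
  starts <- tabulate(kept$start + 1L, nbins = cdna_len)
  coverage <- footprint_coverage(kept$start, kept$matched_len, cdna_len)
  prof <- list(allele = allele, cdna_len = as.integer(cdna_len),
               read_len = as.integer(read_len), kept = kept,
               starts = starts, coverage = coverage)
  class(prof) <- "start_profile"
  prof
}

#' @export
print.start_profile <- function(x, ...) {
  cat("start_profile for", x$allele, ":", nrow(x$kept),
      "kept mappings over", x$cdna_len, "bp; mean coverage",
      round(mean(x$coverage), 1), "\n")
  invisible(x)
}

#' Ideal single start-point coverage profile
#'
#' Expected per-position coverage of a cDNA when every admissible mapping
#' window occurs exactly once on each strand: full-length windows at every
#' offset plus boundary-truncated windows of length `min_trunc_len` to
#' `read_len - 1` anchored at the cDNA ends. The profile has a flat
#' interior plateau of `2 * read_len` and ramps at both ends shaped by the
#' truncation rule; it is the normalisation reference for the coverage
#' area-under-curve (auc) statistic and the red background of per-allele
#' coverage plots.
#'
#' @param cdna_len cDNA length (must be at least `min_trunc_len`).
#' @param read_len Read length (default 100).
#' @param min_trunc_len Minimum truncated mapping length (default 70).
#' @return Integer vector of length `cdna_len`.
#' @export
ideal_profile <- function(cdna_len, read_len = 100L, min_trunc_len = 70L) {
  if (cdna_len < min_trunc_len) {
    stop("cdna_len must be >= min_trunc_len")
  }
  wins <- admissible_windows(cdna_len, read_len, min_trunc_len)
  2L * as.integer(footprint_coverage(wins$start, wins$end - wins$start,
                                     cdna_len))
}

# Distinct admissible windows (one strand) on a cDNA: full-length at every
# offset; end-anchored truncations of length min_trunc_len..read_len-1.
admissible_windows <- function(cdna_len, read_len, min_trunc_len) {
  full <- if (cdna_len >= read_len) {
    data.table(start = 0L:(cdna_len - read_len),
               end = read_len + 0L:(cdna_len - read_len))
  } else NULL
  ts <- seq.int(min_trunc_len, min(read_len - 1L, cdna_len))
  left <- data.table(start = 0L, end = ts)
  right <- data.table(start = cdna_len - ts, end = cdna_len)
  w <- rbindlist(list(full, left, right))
  unique(w, by = c("start", "end"))
}
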