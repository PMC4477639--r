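#' Default parameter weights for the harmonic-mean score
#'
#' The five mapping-derived parameters entering the pair score are
#' weighted `asm` 0.5, `req` 1, `msl` 0.1, `mppr` 0.1 and `auc` 1; these
#' weights gave the best calling concordance on the tuning set used to
#' develop the method.
#'
#' @param asm,req,msl,mppr,auc Positive weights.
#' @return Named numeric vector of weights.
#' @export
default_weights <- function(asm = 0.5, req = 1, msl = 0.1, mppr = 0.1,
                            auc = 1) {
  w <- c(asm = asm, req = req, msl = msl, mppr = mppr, auc = auc)
  if (any(w <= 0)) stop("all weights must be > 0")
  w
}

#' Weighted harmonic-mean pair score
#'
#' For scaled parameters \eqn{P_k \in [0,1]} and weights \eqn{w_k}, the
#' score is
#' \deqn{H = \frac{(\sum_k 1/w_k) \prod_k P_k}{\sum_k (1/w_k) P_k}.}
#' With the default weights this is
#' `H = 24 * asm*req*msl*mppr*auc / (2*asm + req + 10*msl + 10*mppr + auc)`.
#' H is 1 when all parameters are 1, 0 as soon as any parameter is 0, and
#' strictly increasing in each parameter while the others are positive.
#'
#' @param p Numeric vector of 5 scaled parameters in `[0, 1]` (order:
#'   asm, req, msl, mppr, auc), or a matrix with 5 columns for many pairs.
#' @param w Weights, see [default_weights()].
#' @return Numeric score(s) in `[0, 1]`.
#' @export
harmonic_score <- function(p, w = default_weights()) {
  if (any(w <= 0)) stop("all weights must be > 0")
  if (is.matrix(p)) {
    stopifnot(ncol(p) == length(w))
    num <- sum(1 / w) * apply(p, 1L, prod)
    den <- as.numeric(p %*% (1 / w))
    ifelse(den == 0, 0, num / den)
  } else {
    stopifnot(length(p) == length(w))
    den <- sum(p / w)
    if (den == 0) return(0)
    sum(1 / w) * prod(p) / den
  }
}

#' Central/noncentral read ratio of a coverage profile
#'
#' Central reads are kept mappings lying fully inside the central window
#' `[read_len/2, cdna_len - read_len/2)`; all other kept mappings are
#' noncentral. Alleles supported only by reads piling up at the sequence
#' ends or exon boundaries (a signature of cross-mapping artifacts rather
#' than true origin) have a low ratio and are filtered: the ratio must not
#' drop below 0.2, i.e. exactly 0.2 still passes.
#'
#' @param profile A `start_profile`.
#' @return The ratio (central / noncentral); `Inf` when there are no
#'   noncentral reads, `NA` when the profile has no mappings at all (the
#'   allele then fails the filter).
#' @export
central_read_ratio <- function(profile) {
  kept <- profile$kept
  if (nrow(kept) == 0L) return(NA_real_)
  margin <- profile$read_len %/% 2L
  central <- kept$start >= margin &
    kept$start + kept$matched_len <= profile$cdna_len - margin
  n_c <- sum(central)
  n_nc <- sum(!central)
  if (n_nc == 0L) Inf else n_c / n_nc
}

#' Pre-filter candidate alleles of one locus
#'
#' An allele passes only if (a) every cDNA position has kept-mapping
#' coverage of at least 1 (full coverage) and (b) its central read ratio
#' is at least `central_threshold`. Failures are recorded in two QC
#' tables: `failed` lists every rejected allele with `error` = number of
#' zero-coverage positions (sorted ascending, so the most nearly passing
#' alleles come first), and `undercovered` lists the top `top_n` alleles
#' that were not covered 100%, sorted ascending by uncovered bases. In low
#' coverage mode (sample auc below the review threshold) a `review` table
#' repeats the failed alleles in ascending error order as an explicit
#' manual-review request instead of a silent drop.
#'
#' @param profiles Named list of `start_profile`s, one per (non-excluded)
#'   allele of the locus.
#' @param central_threshold Minimum central read ratio (default 0.2).
#' @param low_cov_mode Sample has low coverage (auc < 0.5)?
#' @param top_n Length cap of the undercovered table (default 50).
#' @return List with `candidates` (character vector of allele names) and
#'   `qc` (list of data.tables `failed`, `undercovered`, and `review` in
#'   low coverage mode).
#' @export
prefilter_candidates <- function(profiles, central_threshold = 0.2,
                                 low_cov_mode = FALSE, top_n = 50L) {
  stats <- rbindlist(lapply(profiles, function(p) {
    uncov <- sum(p$coverage == 0L)
    ratio <- central_read_ratio(p)
    data.table(allele = p$allele, uncovered = uncov, central_ratio = ratio)
  }))
  stats[, pass := uncovered == 0L & !is.na(central_ratio) &
          central_ratio >= central_threshold]
  failed <- stats[pass == FALSE,
                  list(allele, error = uncovered, central_ratio)]
  setorderv(failed, c("error", "allele"))
  undercovered <- stats[uncovered > 0L, list(allele, uncovered)]
  setorderv(undercovered, c("uncovered", "allele"))
  undercovered <- utils::head(undercovered, top_n)
  qc <- list(failed = failed, undercovered = undercovered)
  if (low_cov_mode) qc$review <- failed
  list(candidates = stats[pass == TRUE]$allele, qc = qc)
}

# Per-allele mapping summaries shared by all pairs of a locus.
# mappings: full (pre-reduction) mapping table of the locus; profiles: the
# reduced per-allele profiles (for coverage/auc).
locus_evidence <- function(mappings, profiles, candidates, read_len = 100L,
                           min_trunc_len = 70L) {
  m <- as.data.table(mappings)[allele %in% candidates]
  inst <- unique(m[, list(id, mate, allele)])
  rid <- paste(inst$id, inst$mate)
  rids <- unique(rid)
  M <- matrix(FALSE, length(rids), length(candidates),
              dimnames = list(NULL, candidates))
  M[cbind(match(rid, rids), match(inst$allele, candidates))] <- TRUE
  tot <- colSums(M)
  co <- crossprod(M)
  nmap <- rowSums(M)
  # reads exclusive to one candidate vs all other candidates
  excl <- vapply(seq_along(candidates),
                 function(i) sum(M[, i] & nmap == 1L), 0)
  names(excl) <- candidates
  # mate co-mapping per allele: instances whose other mate maps the allele
  pr <- inst[, list(nm = length(unique(mate))), by = list(id, allele)]
  paired <- stats::setNames(numeric(length(candidates)), candidates)
  both <- pr[nm == 2L, list(n = .N), by = allele]
  paired[both$allele] <- 2 * both$n
  auc <- vapply(candidates, function(a) {
    p <- profiles[[a]]
    ideal <- ideal_profile(p$cdna_len, read_len, min_trunc_len)
    min(1, sum(p$coverage) / sum(ideal))
  }, 0)
  lens <- vapply(candidates, function(a) profiles[[a]]$cdna_len, 0L)
  list(candidates = candidates, M = M, tot = tot, co = co, excl = excl,
       paired = paired, auc = auc, lens = lens, n_reads = length(rids))
}

#' Raw pair parameters for a candidate allele pair
#'
#' For a heterozygous pair, `asm_a`/`asm_b` count the reads mapping one
#' allele of the pair but not the other; the pair-level `asm` is their
#' sum and `req = min(asm_a, asm_b) / max(asm_a, asm_b)` measures the
#' balance of exclusive evidence (0/0 gives 0). For a homozygous pair the
#' two alleles are identical, so exclusivity is measured against the union
#' of all other candidate alleles of the locus, `req` is 1 by definition
#' (perfectly balanced), and the pair-level `asm` counts that exclusive
#' evidence once. `msl` is the mean cDNA length of the pair, `mppr` the
#' fraction of mapped read instances on the pair whose mate maps the same
#' allele, and `auc` the mean over the pair of per-allele coverage area
#' under the curve normalised by the ideal profile (capped at 1).
#'
#' @param a,b Candidate allele names (`a == b` for a homozygous pair).
#' @param ev Locus evidence from the internal summariser (built by
#'   [call_genotype()]).
#' @return One-row data.table of raw parameters.
#' @keywords internal
pair_raw_params <- function(a, b, ev) {
  ia <- match(a, ev$candidates)
  ib <- match(b, ev$candidates)
  if (is.na(ia) || is.na(ib)) stop("alleles must be candidates of the locus")
  if (a == b) {
    e <- unname(ev$excl[a])
    asm_a <- asm_b <- e
    asm <- e
    req <- 1
    denom <- ev$tot[[a]]
    num <- ev$paired[[a]]
    msl <- as.numeric(ev$lens[[a]])
    auc <- unname(ev$auc[a])
  } else {
    shared <- ev$co[ia, ib]
    asm_a <- unname(ev$tot[a] - shared)
    asm_b <- unname(ev$tot[b] - shared)
    asm <- asm_a + asm_b
    req <- if (max(asm_a, asm_b) == 0) 0 else min(asm_a, asm_b) / max(asm_a, asm_b)
    denom <- ev$tot[[a]] + ev$tot[[b]]
    num <- ev$paired[[a]] + ev$paired[[b]]
    msl <- (as.numeric(ev$lens[[a]]) + as.numeric(ev$lens[[b]])) / 2
    auc <- (unname(ev$auc[a]) + unname(ev$auc[b])) / 2
  }
  mppr <- if (denom == 0) 0 else num / denom
  data.table(allele1 = a, allele2 = b, asm_a = asm_a, asm_b = asm_b,
             asm = asm, req = req, msl = msl, mppr = mppr, auc = auc)
}

#' Scale raw pair parameters to the unit interval
#'
#' Each of the five parameters is divided by its maximum over all
#' candidate pairs of the locus, so the best pair attains 1 in every
#' parameter it leads; a parameter whose maximum is 0 scales to 0 for all
#' pairs. Scaling is idempotent.
#'
#' @param raw data.table of raw pair parameters (columns `asm`, `req`,
#'   `msl`, `mppr`, `auc`).
#' @return Matrix of scaled parameters with one row per pair.
#' @export
scale_params <- function(raw) {
  cols <- c("asm", "req", "msl", "mppr", "auc")
  sapply(cols, function(cn) {
    v <- as.numeric(raw[[cn]])
    mx <- max(v)
    if (mx == 0) rep(0, length(v)) else v / mx
  }) |> matrix(nrow = nrow(raw), dimnames = list(NULL, cols))
}

#' Call the genotype of one locus
#'
#' Enumerates every unordered pair of candidate alleles (homozygous pairs
#' included), computes the raw and scaled pair parameters and ranks pairs
#' by descending harmonic-mean score; ties are ordered lexicographically
#' by allele names for determinism. The best pair is the call.
#' Alternatives are the other pairs carrying indistinguishable evidence:
#' pairs whose per-allele read support sets equal the best pair's, plus
#' exact score ties. Flags: `low_coverage` when the best pair's raw auc is
#' below `low_cov_auc`, `low_read_count` when the sample read count is
#' below `min_reads`, and `no_call` when no candidate passed filtering.
#'
#' @param candidates Character vector of candidate allele names.
#' @param mappings Mapping table of the locus (pre-reduction).
#' @param profiles Named list of `start_profile`s for the locus alleles.
#' @param locus Locus name.
#' @param weights Parameter weights, see [default_weights()].
#' @param read_len,min_trunc_len Read geometry for the ideal profile.
#' @param low_cov_auc Manual-review threshold on the best pair's raw auc
#'   (default 0.5).
#' @param total_reads,min_reads Sample read count and warning threshold
#'   (default 7e6 single reads).
#' @return A `genotype_call`: list with `locus`, `pairs` (ranked score
#'   table), `best` (character vector of the two allele names),
#'   `alternatives` (data.table of indistinguishable pairs) and `flags`.
#' @export
call_genotype <- function(candidates, mappings, profiles, locus = NA_character_,
                          weights = default_weights(), read_len = 100L,
                          min_trunc_len = 70L, low_cov_auc = 0.5,
                          total_reads = NA_real_, min_reads = 7e6) {
  flags <- list(low_coverage = FALSE, low_read_count = FALSE, no_call = FALSE)
  if (!is.na(total_reads) && total_reads < min_reads) {
    flags$low_read_count <- TRUE
  }
  if (length(candidates) == 0L) {
    flags$no_call <- TRUE
    call <- list(locus = locus, pairs = NULL, best = c(NA_character_, NA_character_),
                 alternatives = NULL, flags = flags)
    class(call) <- "genotype_call"
    return(call)
  }
  candidates <- sort(candidates)
  ev <- locus_evidence(mappings, profiles, candidates, read_len, min_trunc_len)
  idx <- which(upper.tri(matrix(0, length(candidates), length(candidates)),
                         diag = TRUE), arr.ind = TRUE)
  raw <- rbindlist(lapply(seq_len(nrow(idx)), function(r) {
    pair_raw_params(candidates[idx[r, 1L]], candidates[idx[r, 2L]], ev)
  }))
  scaled <- scale_params(raw)
  raw[, H := harmonic_score(scaled, weights)]
  setorderv(raw, c("H", "allele1", "allele2"), c(-1L, 1L, 1L))
  best <- raw[1L]

  # support-set signature: the unordered pair of per-allele read sets
  sig <- function(a, b) {
    sa <- paste(which(ev$M[, a]), collapse = ",")
    sb <- paste(which(ev$M[, b]), collapse = ",")
    paste(sort(c(sa, sb)), collapse = "|")
  }
  sigs <- vapply(seq_len(nrow(raw)),
                 function(r) sig(raw$allele1[r], raw$allele2[r]), "")
  alt <- raw[-1L][sigs[-1L] == sigs[1L] | raw$H[-1L] == raw$H[1L]]
  flags$low_coverage <- best$auc < low_cov_auc
  call <- list(locus = locus, pairs = raw,
               best = c(best$allele1, best$allele2),
               alternatives = alt, flags = flags,
               n_candidates = length(candidates))
  class(call) <- "genotype_call"
  call
}

#' @export
print.genotype_call <- function(x, ...) {
  if (x$flags$no_call) {
    cat("genotype_call [", x$locus, "]: no call (no candidate alleles)\n")
    return(invisible(x))
  }
  cat("genotype_call [", x$locus, "]: ", x$best[1L], " / ", x$best[2L],
      "  H = ", signif(x$pairs$H[1L], 4), sep = "")
  if (nrow(x$alternatives)) {
    cat("  (+", nrow(x$alternatives), "alternative pair(s))")
  }
  fl <- names(Filter(isTRUE, x$flags))
  if (length(fl)) cat("  flags:", paste(fl, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Flag abnormal coverage segments against the ideal profile
#'
#' Reports, per exon, the maximal segments where the observed unique
#' start-point coverage is zero although the ideal profile expects
#' coverage. A gap abutting an exon 3' (or 5') boundary is the signature
#' of an erroneous reference allele: reads from the true allele cannot
#' cross the few positions where the (wrong) reference differs, but
#' boundary-truncated reads still cover the rest of the exon, so the
#' profile collapses only in the short stretch next to the boundary.
#'
#' @param profile A `start_profile` of the allele under scrutiny.
#' @param exons Exon bounds matrix of the allele (0-based half-open), e.g.
#'   `reference$exons[[name]]`.
#' @param min_trunc_len Minimum truncated mapping length.
#' @param boundary_tol Tolerance (bp) when deciding whether a gap abuts an
#'   exon boundary. A junction-crossing read whose first intron base
#'   coincidentally equals the next cDNA base extends its perfect match
#'   across the boundary, covering a base or two inside an otherwise
#'   boundary-abutting gap (probability 4^-k for k bases), so exact
#'   abutment is too strict by a few bases.
#' @return data.table with columns `exon`, `start`, `end`, `length`,
#'   `abuts_5p`, `abuts_3p`. Empty when the allele is fully covered.
#' @export
discriminate_boundary_variant <- function(profile, exons,
                                          min_trunc_len = 70L,
                                          boundary_tol = 3L) {
  ideal <- ideal_profile(profile$cdna_len, profile$read_len, min_trunc_len)
  gap <- profile$coverage == 0L & ideal > 0L
  runs <- logical_runs(gap)
  if (nrow(runs) == 0L) {
    return(data.table(exon = integer(), start = integer(), end = integer(),
                      length = integer(), abuts_5p = logical(),
                      abuts_3p = logical()))
  }
  res <- rbindlist(lapply(seq_len(nrow(exons)), function(i) {
    b <- exons[i, "start"]; e <- exons[i, "end"]
    seg <- runs[pmax(runs$start, b) < pmin(runs$end, e)]
    if (nrow(seg) == 0L) return(NULL)
    s <- pmax(seg$start, b); en <- pmin(seg$end, e)
    data.table(exon = i, start = s, end = en, length = en - s,
               abuts_5p = s <= b + boundary_tol,
               abuts_3p = en >= e - boundary_tol)
  }))
  if (is.null(res)) {
    res <- data.table(exon = integer(), start = integer(), end = integer(),
                      length = integer(), abuts_5p = logical(),
                      abuts_3p = logical())
  }
  res
}
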