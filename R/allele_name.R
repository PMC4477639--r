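#' Parse an HLA allele name
#'
#' Allele names follow the field-based nomenclature `LOCUS*F1:F2[:F3[:F4]]`,
#' e.g. `B*38:02:01`. Field 1 is the allele group, field 2 the protein and
#' field 3 the synonymous cDNA variant, so three-field ("six-digit") names
#' distinguish cDNA-level variants.
#'
#' @param x Character vector of allele names.
#' @return A data.table with columns `name`, `locus` and a list column
#'   `fields` of character vectors.
#' @examples
#' parse_allele_name("B*38:02:01")
#' @export
parse_allele_name <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z][A-Za-z0-9]*)\\*([0-9]+(?::[0-9]+){0,3})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("not a valid allele name: ", paste(x[bad], collapse = ", "))
  }
  data.table(
    name = x,
    locus = vapply(m, `[`, "", 2L),
    fields = lapply(m, function(g) strsplit(g[3L], ":", fixed = TRUE)[[1L]])
  )
}

is_allele_name <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9]*\\*[0-9]+(:[0-9]+){0,3}$", x)
}

allele_locus <- function(x) {
  sub("\\*.*$", "", x)
}

#' Truncate allele names to a lower field resolution
#'
#' Reduces allele names to their first `n_fields` fields, e.g. to compare
#' three-field calls against two-field reference genotypes. Names that
#' already have `n_fields` fields or fewer are returned unchanged, so the
#' operation is idempotent.
#'
#' @param name Character vector of allele names.
#' @param n_fields Number of fields to keep (at least 1).
#' @return Character vector of truncated names.
#' @examples
#' truncate_resolution("B*38:02:01", 2) # "B*38:02"
#' @export
truncate_resolution <- function(name, n_fields) {
  if (n_fields < 1L) stop("n_fields must be >= 1")
  parsed <- parse_allele_name(name)
  vapply(seq_along(name), function(i) {
    f <- parsed$fields[[i]]
    paste0(parsed$locus[i], "*",
           paste(f[seq_len(min(n_fields, length(f)))], collapse = ":"))
  }, "")
}
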