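#' In-frame codon alignment
#'
#' Container for a gap-free, in-frame coding alignment over the 61 sense
#' codons. Stop codons and gaps are rejected: run [remove_gapped_columns()]
#' on raw alignments first.
#'
#' @param sequences character vector of aligned DNA sequences (equal length,
#'   length divisible by 3, A/C/G/T only), or a character matrix of codons
#'   (rows = sequences).
#' @param ids sequence identifiers; defaults to `names(sequences)`.
#' @return an object of class `codon_alignment` with elements `ids`,
#'   `states` (n x c integer matrix indexing [SENSE_CODONS]), `n`, `c`.
#' @export
codon_alignment <- function(sequences, ids = names(sequences)) {
  if (is.matrix(sequences)) {
    codons <- sequences
    ids <- ids %||% rownames(sequences)
  } else {
    sequences <- toupper(sequences)
    len <- unique(nchar(sequences))
    if (length(len) != 1L) stop2("sequences must be aligned (equal length)")
    if (len %% 3L != 0L) stop2("alignment length not divisible by 3")
    codons <- t(vapply(
      sequences,
      function(s) substring(s, seq(1L, len, 3L), seq(3L, len, 3L)),
      character(len / 3L)
    ))
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(codons)))
  if (anyDuplicated(ids)) stop2("duplicate sequence ids")
  states <- matrix(match(codons, SENSE_CODONS),
    nrow = nrow(codons),
    dimnames = list(ids, NULL)
  )
  if (anyNA(states)) {
    bad <- unique(codons[is.na(states)])
    if (any(grepl("-", bad, fixed = TRUE))) {
      stop2("alignment contains gaps; apply remove_gapped_columns() first")
    }
    stop2(
      "invalid codons (stop codon or non-ACGT): ",
      paste(utils::head(bad, 5L), collapse = ", ")
    )
  }
  structure(
    list(ids = ids, states = states, n = nrow(states), c = ncol(states)),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", x$n, "sequences x", x$c, "codons\n")
  invisible(x)
}

#' @export
as.character.codon_alignment <- function(x, ...) {
  out <- apply(x$states, 1L, function(s) paste(SENSE_CODONS[s], collapse = ""))
  names(out) <- x$ids
  out
}

#' Subset a codon alignment by codon interval
#'
#' @param alignment a [codon_alignment].
#' @param start,end 1-based inclusive codon positions.
#' @return a [codon_alignment] over codons `start..end`.
#' @export
subset_codons <- function(alignment, start, end) {
  stopifnot(inherits(alignment, "codon_alignment"))
  if (start < 1L || end > alignment$c || start > end) {
    stop2("codon interval [", start, ", ", end, "] outside 1..", alignment$c)
  }
  codon_alignment(
    matrix(SENSE_CODONS[alignment$states[, start:end, drop = FALSE]],
      nrow = alignment$n, dimnames = list(alignment$ids, NULL)
    )
  )
}

#' Read a protein or codon multiple alignment from FASTA
#'
#' @param path FASTA file.
#' @param kind `"protein"` or `"codon"`. Codon alignments are validated for
#'   reading frame (length divisible by 3) and in-frame stop codons; gaps are
#'   allowed at this stage and can be stripped with [remove_gapped_columns()].
#' @return a character matrix (rows = sequences, columns = residues or
#'   nucleotides, rownames = ids) with attribute `kind`.
#' @export
read_alignment <- function(path, kind = c("protein", "codon")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop2("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop2("duplicate sequence ids in ", path)
  seqs <- toupper(as.character(set))
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop2("ragged alignment: sequence lengths differ")
  if (len == 0L) stop2("empty alignment")
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- ids
  if (kind == "codon") {
    if (len %% 3L != 0L) stop2("codon alignment length not divisible by 3")
    .check_stops(mat)
  }
  structure(mat, kind = kind)
}

.check_stops <- function(mat) {
  stops <- c("TAA", "TAG", "TGA")
  nc <- ncol(mat) / 3L
  for (j in seq_len(nc)) {
    cod <- apply(mat[, (3L * j - 2L):(3L * j), drop = FALSE], 1L, paste, collapse = "")
    if (any(cod %in% stops)) {
      stop2("in-frame stop codon at codon position ", j)
    }
  }
  invisible(TRUE)
}

#' Remove alignment columns containing gaps
#'
#' Every column (codon alignments: every whole codon) containing at least one
#' gap character (`-` or `.`) is removed. The returned object carries a
#' `column_map` attribute: an integer vector giving, for each retained column
#' (codon), its 1-based index in the original alignment, so downstream site
#' positions can be reported in original coordinates.
#'
#' @param alignment a character matrix from [read_alignment()].
#' @return the filtered alignment matrix with attributes `kind` and
#'   `column_map`.
#' @export
remove_gapped_columns <- function(alignment) {
  stopifnot(is.matrix(alignment))
  kind <- attr(alignment, "kind") %||% "protein"
  gap <- alignment == "-" | alignment == "."
  if (kind == "codon") {
    nc <- ncol(alignment) / 3L
    keep_codon <- vapply(
      seq_len(nc),
      function(j) !any(gap[, (3L * j - 2L):(3L * j)]), logical(1)
    )
    if (!any(keep_codon)) stop2("no gap-free codons remain")
    keep_cols <- as.vector(t(outer(which(keep_codon) * 3L - 2L, 0:2, "+")))
    out <- alignment[, keep_cols, drop = FALSE]
    map <- which(keep_codon)
  } else {
    keep <- !apply(gap, 2L, any)
    if (!any(keep)) stop2("no gap-free columns remain")
    out <- alignment[, keep, drop = FALSE]
    map <- which(keep)
  }
  structure(out, kind = kind, column_map = map)
}

#' Convert a gap-free nucleotide alignment matrix to a codon alignment
#'
#' @param alignment character matrix with `kind = "codon"` (see
#'   [read_alignment()]), gap-free.
#' @return a [codon_alignment]; the `column_map` attribute, if present, is
#'   propagated.
#' @export
as_codon_alignment <- function(alignment) {
  if (inherits(alignment, "codon_alignment")) return(alignment)
  stopifnot(is.matrix(alignment))
  seqs <- apply(alignment, 1L, paste, collapse = "")
  out <- codon_alignment(seqs, ids = rownames(alignment))
  out$column_map <- attr(alignment, "column_map")
  out
}

#' Write sequences to FASTA
#'
#' @param x a [codon_alignment], a character matrix alignment, or a named
#'   character vector of sequences.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (inherits(x, "codon_alignment")) x <- as.character(x)
  if (is.matrix(x)) {
    ids <- rownames(x)
    x <- apply(x, 1L, paste, collapse = "")
    names(x) <- ids
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
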