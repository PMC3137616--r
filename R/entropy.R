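## Site-wise Shannon entropy of protein alignments, in bits (log base 2, so
## the maximum over the 20 amino acids is log2(20) ~ 4.32 and the
## hypervariability threshold of 2 bits corresponds to four equally frequent
## residues). Gaps and ambiguous residues (X, B, Z, J, U, O, *) are excluded
## from the frequency denominators.

AA20 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Shannon entropy of one alignment column
#'
#' `H = -sum_a f_a log2 f_a` over the 20 amino acids, with `f_a` the residue
#' frequency among counted (non-gap, unambiguous) residues.
#'
#' @param column character vector of residues (one per sequence); gaps (`-`,
#'   `.`) and ambiguity codes are ignored.
#' @return entropy in bits; `NA` if no residue is countable (all-gap column).
#' @export
column_entropy <- function(column) {
  cnt <- table(factor(toupper(column), levels = AA20))
  n <- sum(cnt)
  if (n == 0L) return(NA_real_)
  f <- cnt[cnt > 0] / n
  -sum(f * log2(f))
}

#' Entropy profile of a protein alignment
#'
#' Computes per-column Shannon entropy with gaps excluded from the counts.
#' Columns whose gap fraction exceeds `max_gap_fraction` are masked: their
#' entropy is reported as `NA` (never 0) and they are not eligible for
#' hypervariable calls. Hypervariable columns are those with `H > 2` bits
#' (strict inequality, so a 4-state uniform column at exactly 2 bits is not
#' called).
#'
#' @param alignment protein alignment: a character matrix (rows = sequences)
#'   from [read_alignment()], or a named character vector of aligned
#'   sequences.
#' @param max_gap_fraction mask columns with a greater gap fraction
#'   (default 0.5). Use 1 to keep every column with at least one residue.
#' @param alignment_id optional label stored in the profile.
#' @return an object of class `entropy_profile`: a data.frame with columns
#'   `column` (1-based), `H` (bits), `n_effective`, `masked`,
#'   `hypervariable`.
#' @export
profile_alignment <- function(alignment, max_gap_fraction = 0.5,
                              alignment_id = NULL) {
  if (!is.matrix(alignment)) {
    len <- unique(nchar(alignment))
    if (length(len) != 1L) stop2("ragged alignment: sequence lengths differ")
    alignment <- do.call(rbind, strsplit(toupper(alignment), ""))
  }
  n_seq <- nrow(alignment)
  gap <- alignment == "-" | alignment == "."
  gap_frac <- colMeans(gap)
  H <- apply(alignment, 2L, column_entropy)
  n_eff <- apply(alignment, 2L, function(col) {
    sum(toupper(col) %in% AA20)
  })
  masked <- gap_frac > max_gap_fraction | n_eff == 0L
  H[masked] <- NA_real_
  out <- data.frame(
    column = seq_len(ncol(alignment)),
    H = H,
    n_effective = n_eff,
    masked = masked,
    hypervariable = !masked & !is.na(H) & H > 2
  )
  attr(out, "alignment_id") <- alignment_id
  attr(out, "n_sequences") <- n_seq
  class(out) <- c("entropy_profile", "data.frame")
  out
}

#' Count hypervariable sites shared between two profiles
#'
#' Given a column correspondence from a joint alignment (an injective map
#' between columns of profile `a` and columns of profile `b`), counts the
#' hypervariable sites of each profile and those hypervariable in both
#' members of a mapped pair.
#'
#' @param profile_a,profile_b `entropy_profile` objects.
#' @param site_map two-column integer matrix or data.frame; column 1 indexes
#'   columns of `profile_a`, column 2 the corresponding columns of
#'   `profile_b`.
#' @return list with `n_a`, `n_b` (total hypervariable sites in each
#'   profile) and `n_shared` (mapped pairs hypervariable in both).
#' @export
shared_hypervariable <- function(profile_a, profile_b, site_map) {
  site_map <- as.matrix(site_map)
  stopifnot(ncol(site_map) == 2L)
  if (anyDuplicated(site_map[, 1L]) || anyDuplicated(site_map[, 2L])) {
    stop2("site_map must be injective")
  }
  if (any(site_map[, 1L] < 1L | site_map[, 1L] > nrow(profile_a)) ||
        any(site_map[, 2L] < 1L | site_map[, 2L] > nrow(profile_b))) {
    stop2("site_map indexes columns outside the profiles")
  }
  hv_a <- profile_a$hypervariable
  hv_b <- profile_b$hypervariable
  list(
    n_a = sum(hv_a),
    n_b = sum(hv_b),
    n_shared = sum(hv_a[site_map[, 1L]] & hv_b[site_map[, 2L]])
  )
}

#' Write an entropy profile as tab-separated text
#'
#' @param profile an `entropy_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_entropy_profile <- function(profile, path) {
  utils::write.table(
    as.data.frame(profile), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
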