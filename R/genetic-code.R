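## Universal genetic code on the 61 sense codons (stop codons excluded from
## the state space, the standard GY94 convention). All pairwise single-change
## classifications are precomputed once at install time.

NUCS <- c("T", "C", "A", "G")

.codon_tables <- local({
  all64 <- as.vector(outer(
    outer(NUCS, NUCS, paste0), NUCS,
    function(ab, c) paste0(ab, c)
  ))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[all64])
  sense <- all64[aa != "*"]
  aa <- aa[match(sense, all64)]
  stopifnot(length(sense) == 61L)

  nuc_idx <- t(vapply(
    strsplit(sense, ""),
    function(x) match(x, NUCS), integer(3)
  ))

  n <- length(sense)
  ndiff <- matrix(0L, n, n)
  ts <- matrix(FALSE, n, n) # the single change is a transition
  for (p in 1:3) {
    a <- nuc_idx[, p]
    d <- outer(a, a, "!=")
    ndiff <- ndiff + d
    # transitions: T<->C (idx 1,2) and A<->G (idx 3,4)
    pur <- a >= 3L
    ts <- ts | (d & outer(pur, pur, "=="))
  }
  one <- ndiff == 1L
  syn <- one & outer(aa, aa, "==")

  list(
    codons = sense, aa = aa, nuc_idx = nuc_idx,
    one_diff = one, is_ts = ts & one, is_syn = syn
  )
})

SENSE_CODONS <- .codon_tables$codons
CODON_AA <- .codon_tables$aa

#' Codon equilibrium frequencies under the F3x4 model
#'
#' Computes codon frequencies as the product of position-specific nucleotide
#' frequencies, renormalized over the 61 sense codons. With the default
#' uniform composition this gives equal weight to every sense codon product
#' (1/64 before renormalization).
#'
#' @param nuc_freqs either a single vector of 4 nucleotide frequencies
#'   (order T, C, A, G) applied to all three codon positions, or a 3x4 matrix
#'   of position-specific frequencies.
#' @return numeric vector of 61 frequencies (names = codons), summing to 1.
#' @export
f3x4_frequencies <- function(nuc_freqs = rep(0.25, 4)) {
  if (is.matrix(nuc_freqs)) {
    stopifnot(nrow(nuc_freqs) == 3L, ncol(nuc_freqs) == 4L)
    fm <- nuc_freqs
  } else {
    stopifnot(length(nuc_freqs) == 4L)
    fm <- matrix(nuc_freqs, 3, 4, byrow = TRUE)
  }
  if (any(fm < 0) || any(abs(rowSums(fm) - 1) > 1e-6)) {
    stop2("nucleotide frequencies must be non-negative and sum to 1 per position")
  }
  # guard against exactly-zero compositions producing zero codon frequencies
  fm <- (fm + 1e-8) / rowSums(fm + 1e-8)
  idx <- .codon_tables$nuc_idx
  pi <- fm[1, idx[, 1]] * fm[2, idx[, 2]] * fm[3, idx[, 3]]
  pi <- pi / sum(pi)
  names(pi) <- SENSE_CODONS
  pi
}

## Position-specific nucleotide composition of a codon alignment (3x4 matrix,
## columns in T,C,A,G order), for data-driven F3x4 frequencies.
codon_position_freqs <- function(states) {
  idx <- .codon_tables$nuc_idx
  fm <- matrix(0, 3, 4)
  tab <- tabulate(as.integer(states), nbins = 61L)
  for (p in 1:3) {
    for (b in 1:4) fm[p, b] <- sum(tab[idx[, p] == b])
  }
  fm / rowSums(fm)
}

#' Estimate F3x4 codon frequencies from a codon alignment
#'
#' @param alignment a [codon_alignment].
#' @return numeric vector of 61 codon frequencies.
#' @export
alignment_f3x4 <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  f3x4_frequencies(codon_position_freqs(alignment$states))
}
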