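## GY94-type codon substitution model with HKY85 nucleotide exchangeabilities:
## q_ij = 0 for multi-nucleotide changes, pi_j for single transversions,
## kappa*pi_j for single transitions, multiplied by omega when the change is
## nonsynonymous. The model is time-reversible, so P(t) = exp(Qt) is computed
## by spectral decomposition of the symmetrized generator.

#' GY94xHKY85 instantaneous rate matrix
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param codon_frequencies equilibrium frequencies of the 61 sense codons
#'   (positive, summing to 1); see [f3x4_frequencies()].
#' @param scale if `TRUE` (default) the matrix is scaled so the expected
#'   substitution rate at equilibrium is 1, i.e. time is measured in expected
#'   substitutions per codon at the supplied `(kappa, omega)`.
#' @return 61 x 61 rate matrix (rows sum to 0), dimnames = codons.
#' @export
codon_rate_matrix <- function(kappa, omega,
                              codon_frequencies = f3x4_frequencies(),
                              scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0)
  pi <- .check_codon_freqs(codon_frequencies)
  tb <- .codon_tables
  q <- matrix(0, 61, 61, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  q[tb$one_diff] <- rep(pi, each = 61)[tb$one_diff]
  q[tb$is_ts] <- q[tb$is_ts] * kappa
  ns <- tb$one_diff & !tb$is_syn
  q[ns] <- q[ns] * omega
  diag(q) <- -rowSums(q)
  if (scale) {
    r <- -sum(pi * diag(q))
    if (r <= 0) stop2("degenerate rate matrix (rate 0); cannot scale")
    q <- q / r
  }
  q
}

.check_codon_freqs <- function(pi) {
  if (length(pi) != 61L || any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    stop2("codon_frequencies must be 61 positive values summing to 1")
  }
  unname(pi)
}

## Expected substitution rate at equilibrium of the *unscaled* GY94 matrix.
codon_mean_rate <- function(kappa, omega, pi) {
  q <- codon_rate_matrix(kappa, omega, pi, scale = FALSE)
  -sum(pi * diag(q))
}

## Spectral decomposition of a reversible Q: with D = diag(pi),
## B = D^(1/2) Q D^(-1/2) is symmetric; Q = D^(-1/2) V L V' D^(1/2), so
## P(t) = A exp(Lt) Ainv with A = D^(-1/2) V, Ainv = V' D^(1/2).
ctmc_spectral <- function(q, pi) {
  s <- sqrt(pi)
  b <- q * (s %o% (1 / s))
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  list(
    A = e$vectors / s,
    Ainv = t(e$vectors) * rep(s, each = 61L),
    values = e$values
  )
}

## Transition probability matrix from a spectral decomposition.
ctmc_pmat <- function(sp, t) {
  p <- sp$A %*% (exp(sp$values * t) * sp$Ainv)
  p[p < 0] <- 0
  p
}

#' Codon transition probability matrix P(t) = exp(Qt)
#'
#' @inheritParams codon_rate_matrix
#' @param t elapsed time (expected substitutions per codon when `scale=TRUE`).
#' @return 61 x 61 stochastic matrix.
#' @export
codon_transition_matrix <- function(t, kappa, omega,
                                    codon_frequencies = f3x4_frequencies(),
                                    scale = TRUE) {
  stopifnot(t >= 0)
  pi <- .check_codon_freqs(codon_frequencies)
  q <- codon_rate_matrix(kappa, omega, pi, scale = scale)
  p <- ctmc_pmat(ctmc_spectral(q, pi), t)
  dimnames(p) <- list(SENSE_CODONS, SENSE_CODONS)
  p
}
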