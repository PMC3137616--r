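## Simulation studies that calibrate the pipeline's statistical behaviour:
## type-I error and power of the M1a-M2a LRT, parameter recovery, breakpoint
## recovery and false-positive rates, and the enrichment test's rejection
## rates. These are the package's own reproducibility checks; the methods
## vignette documents the study conditions.

## Random non-ultrametric tree with the study's branch-length distribution.
.study_tree <- function(n_taxa, seed, min_bl = 0.05, max_bl = 0.3) {
  with_seed(seed, {
    tr <- ape::rtree(n_taxa)
    tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
    tr
  })
}

#' Type-I error study for the M1a vs M2a likelihood-ratio test
#'
#' Simulates `n_rep` alignments under M1a (no positive selection; omega0 =
#' 0.2 on 70% of sites, kappa = 2) on random non-ultrametric trees, fits M1a
#' and M2a on the true tree, and returns the LRT p-values.
#'
#' @param n_rep number of replicates.
#' @param n_taxa,n_codons data dimensions per replicate.
#' @param seed master seed (each replicate derives its own tree/data seeds).
#' @return numeric vector of p-values (length `n_rep`).
#' @export
lrt_type1_study <- function(n_rep = 50L, n_taxa = 12L, n_codons = 200L,
                            seed = 1L) {
  regime <- selection_regime("M1a", kappa = 2, omegas = c(0.2, 1),
                             proportions = c(0.7, 0.3))
  seeds <- derive_seeds(seed, 2L * n_rep)
  vapply(seq_len(n_rep), function(i) {
    tr <- .study_tree(n_taxa, seeds[2L * i - 1L])
    sim <- simulate_codon_alignment(tr, regime, n_codons, seeds[2L * i])
    f1 <- fit_site_model(sim$alignment, tr, "M1a")
    f2 <- fit_site_model(sim$alignment, tr, "M2a",
      options = list(init = .warm_start(f1, "M2a"))
    )
    suppressWarnings(lrt(f1, f2)$p_value)
  }, numeric(1))
}

#' Power and parameter-recovery study for the M1a vs M2a test
#'
#' Simulates alignments under M2a (default omega_pos = 4 on 15% of sites,
#' kappa = 2) on random 24-taxon trees with total length above 5 expected
#' substitutions per codon, fits the nested pair, and reports the LRT
#' p-value and the M2a estimates of `omega_pos` and `p_pos` per replicate.
#'
#' @inheritParams lrt_type1_study
#' @param omega_pos,p_pos generating values of the positive class.
#' @return data.frame with columns `p_value`, `omega_pos_hat`, `p_pos_hat`.
#' @export
lrt_power_study <- function(n_rep = 20L, n_taxa = 24L, n_codons = 400L,
                            omega_pos = 4, p_pos = 0.15, seed = 1L) {
  regime <- selection_regime(
    "M2a", kappa = 2,
    omegas = c(0.2, 1, omega_pos),
    proportions = c(1 - p_pos - 0.25, 0.25, p_pos)
  )
  seeds <- derive_seeds(seed + 1L, 2L * n_rep)
  out <- lapply(seq_len(n_rep), function(i) {
    tr <- .study_tree(n_taxa, seeds[2L * i - 1L], 0.08, 0.25)
    sim <- simulate_codon_alignment(tr, regime, n_codons, seeds[2L * i])
    f1 <- fit_site_model(sim$alignment, tr, "M1a")
    f2 <- fit_site_model(sim$alignment, tr, "M2a",
      options = list(init = .warm_start(f1, "M2a"))
    )
    data.frame(
      p_value = suppressWarnings(lrt(f1, f2)$p_value),
      omega_pos_hat = f2$omega_pos, p_pos_hat = f2$p_pos
    )
  })
  do.call(rbind, out)
}

## Two maximally discordant 8-taxon topologies used by the breakpoint studies.
.discordant_trees <- function() {
  list(
    ape::read.tree(text = paste0(
      "((((a:0.1,b:0.1):0.1,c:0.2):0.1,d:0.3):0.1,",
      "(((e:0.1,f:0.1):0.1,g:0.2):0.1,h:0.3):0.1);"
    )),
    ape::read.tree(text = paste0(
      "((((a:0.1,h:0.1):0.1,c:0.2):0.1,f:0.3):0.1,",
      "(((e:0.1,b:0.1):0.1,g:0.2):0.1,d:0.3):0.1);"
    ))
  )
}

#' Breakpoint recovery study on single-switch recombinants
#'
#' Simulates 200-codon alignments whose first and second 100 codons follow
#' two maximally discordant 8-taxon topologies, scans for breakpoints, and
#' reports whether an accepted breakpoint falls within `tolerance` codons of
#' the true switch.
#'
#' @param n_rep number of replicates.
#' @param tolerance codon tolerance around the true breakpoint (default 10).
#' @param seed master seed.
#' @return logical vector (hit per replicate), with attribute `breakpoints`
#'   (list of accepted breakpoint vectors).
#' @export
breakpoint_recovery_study <- function(n_rep = 20L, tolerance = 10L, seed = 1L) {
  trees <- .discordant_trees()
  regime <- selection_regime("M0", kappa = 2, omegas = 0.5)
  seeds <- derive_seeds(seed + 2L, n_rep)
  bps <- lapply(seq_len(n_rep), function(i) {
    rec <- simulate_recombinant_alignment(trees, regime, c(100L, 100L), seeds[i])
    scan_breakpoints(rec$alignment, max_breakpoints = 4L)$breakpoints
  })
  hits <- vapply(bps, function(b) any(abs(b - 100L) <= tolerance), logical(1))
  attr(hits, "breakpoints") <- bps
  hits
}

#' Breakpoint false-positive study on non-recombinant alignments
#'
#' Simulates single-topology alignments (12 taxa, 300 codons) and reports
#' whether the scan accepts any breakpoint.
#'
#' @inheritParams breakpoint_recovery_study
#' @param n_taxa,n_codons data dimensions.
#' @return logical vector (any breakpoint accepted, per replicate).
#' @export
breakpoint_null_study <- function(n_rep = 20L, n_taxa = 12L, n_codons = 300L,
                                  seed = 1L) {
  regime <- selection_regime("M0", kappa = 2, omegas = 0.5)
  seeds <- derive_seeds(seed + 3L, 2L * n_rep)
  vapply(seq_len(n_rep), function(i) {
    tr <- .study_tree(n_taxa, seeds[2L * i - 1L])
    sim <- simulate_codon_alignment(tr, regime, n_codons, seeds[2L * i])
    length(scan_breakpoints(sim$alignment, max_breakpoints = 4L)$breakpoints) > 0L
  }, logical(1))
}

#' Rejection-rate study for the neighbourhood enrichment test
#'
#' Simulates annotated genomes from the default [synthetic_genome_spec()]
#' (2,000 genes of which 50 belong to the designated family) at a given
#' enrichment factor and returns the chi-square p-values.
#'
#' @param n_rep number of replicate genomes.
#' @param enrichment_factor placement-density factor of the family inside
#'   neighbourhoods (1 = null).
#' @param seed master seed.
#' @return numeric vector of p-values.
#' @export
enrichment_calibration_study <- function(n_rep = 500L, enrichment_factor = 1,
                                         seed = 1L) {
  seeds <- derive_seeds(seed + 4L, n_rep)
  vapply(seq_len(n_rep), function(i) {
    spec <- synthetic_genome_spec(
      enrichment_factor = enrichment_factor, seed = seeds[i]
    )
    ann <- simulate_genome_annotation(spec)
    run_colocalization(ann, "classIV", collapse = FALSE)$result$p_value
  }, numeric(1))
}
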