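#' Selection regime for codon-alignment simulation
#'
#' Describes a site-class mixture of omega values under one of the standard
#' site models. For M7/M8 the omega classes are derived by discretizing a
#' beta(p, q) distribution ([discretize_beta()]).
#'
#' @param model_id one of `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"`.
#' @param kappa transition/transversion ratio (> 0).
#' @param omegas per-class dN/dS values: length 1 for M0; `c(omega0 < 1, 1)`
#'   for M1a; `c(omega0 < 1, 1, omega_pos >= 1)` for M2a. Ignored for M7/M8.
#' @param proportions site-class probabilities (same length as the class
#'   list, summing to 1). For M7 this is implied; for M8 supply `p_pos`
#'   instead.
#' @param beta_p,beta_q beta shape parameters (M7/M8).
#' @param omega_pos omega of the extra positive-selection class (M2a/M8).
#' @param p_pos proportion of the positive class (M8).
#' @param n_beta_classes discretization resolution for M7/M8 (default 10).
#' @return an object of class `selection_regime` with resolved `class_omegas`
#'   and `class_proportions`.
#' @export
selection_regime <- function(model_id, kappa = 2,
                             omegas = NULL, proportions = NULL,
                             beta_p = NULL, beta_q = NULL,
                             omega_pos = NULL, p_pos = NULL,
                             n_beta_classes = 10L) {
  model_id <- match.arg(model_id, SITE_MODELS)
  stopifnot(kappa > 0)
  tol <- 1e-12
  if (model_id %in% c("M7", "M8")) {
    if (is.null(beta_p) || is.null(beta_q) || beta_p <= 0 || beta_q <= 0) {
      stop2(model_id, " requires beta_p > 0 and beta_q > 0")
    }
    cls <- discretize_beta(beta_p, beta_q, n_beta_classes)
    if (model_id == "M7") {
      omegas <- cls
      proportions <- rep(1 / n_beta_classes, n_beta_classes)
    } else {
      if (is.null(omega_pos) || is.null(p_pos)) {
        stop2("M8 requires omega_pos and p_pos")
      }
      if (omega_pos < 1) stop2("omega_pos must be >= 1")
      if (p_pos < 0 || p_pos > 1) stop2("p_pos must be in [0, 1]")
      omegas <- c(cls, omega_pos)
      proportions <- c(rep((1 - p_pos) / n_beta_classes, n_beta_classes), p_pos)
    }
  } else {
    if (is.null(omegas)) stop2(model_id, " requires omegas")
    if (model_id == "M0") {
      if (length(omegas) != 1L) stop2("M0 has a single omega class")
      proportions <- 1
    }
    if (model_id == "M1a") {
      if (length(omegas) != 2L || omegas[1] >= 1 || omegas[2] != 1) {
        stop2("M1a requires omegas = c(omega0 < 1, 1)")
      }
    }
    if (model_id == "M2a") {
      if (length(omegas) != 3L || omegas[1] >= 1 || omegas[2] != 1 ||
            omegas[3] < 1) {
        stop2("M2a requires omegas = c(omega0 < 1, 1, omega_pos >= 1)")
      }
      omega_pos <- omegas[3]
      p_pos <- proportions[3]
    }
    if (is.null(proportions) || length(proportions) != length(omegas)) {
      stop2("proportions must match omegas in length")
    }
  }
  if (any(omegas < 0)) stop2("omega values must be >= 0")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > tol) {
    stop2("proportions must be non-negative and sum to 1 (tol 1e-12)")
  }
  structure(
    list(
      model_id = model_id, kappa = kappa,
      class_omegas = unname(omegas), class_proportions = unname(proportions),
      beta_p = beta_p, beta_q = beta_q,
      omega_pos = omega_pos, p_pos = p_pos
    ),
    class = "selection_regime"
  )
}

#' @export
print.selection_regime <- function(x, ...) {
  cat("selection_regime", x$model_id, "kappa =", x$kappa, "\n")
  cat("  omegas:", paste(signif(x$class_omegas, 4), collapse = " "), "\n")
  cat("  props: ", paste(signif(x$class_proportions, 4), collapse = " "), "\n")
  invisible(x)
}

#' Simulate an in-frame codon alignment under a site-class selection regime
#'
#' Sites draw their omega class i.i.d. from the regime proportions; each site
#' then evolves independently down the tree under the GY94xHKY85 process with
#' that class's omega and the shared kappa. Rate matrices for all classes
#' share one normalization (the mixture-average rate equals 1), so branch
#' lengths are expected substitutions per codon under the mixture.
#'
#' @param tree ape `phylo` with non-negative branch lengths (>= 2 leaves;
#'   need not be ultrametric).
#' @param regime a [selection_regime].
#' @param n_codons number of codons to simulate (>= 1).
#' @param seed RNG seed governing all draws (class labels, root states,
#'   branch transitions, in that order).
#' @param codon_frequencies equilibrium frequencies (default uniform F3x4).
#' @return a list with elements `alignment` (a [codon_alignment] over the
#'   tree's leaves), `site_classes` (integer class label per codon, the index
#'   into `regime$class_omegas`) and `regime`.
#' @export
simulate_codon_alignment <- function(tree, regime, n_codons, seed,
                                     codon_frequencies = f3x4_frequencies()) {
  stopifnot(inherits(regime, "selection_regime"), n_codons >= 1L)
  pi <- .check_codon_freqs(codon_frequencies)
  if (!inherits(tree, "phylo")) stop2("tree must be an ape 'phylo'")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop2("tree must have non-negative branch lengths")
  }
  if (length(tree$tip.label) < 2L) stop2("tree must have >= 2 leaves")

  omegas <- regime$class_omegas
  props <- regime$class_proportions
  rates <- vapply(omegas, codon_mean_rate, numeric(1),
    kappa = regime$kappa, pi = pi
  )
  rbar <- sum(props * rates) # shared mixture normalization
  spectra <- lapply(omegas, function(om) {
    ctmc_spectral(
      codon_rate_matrix(regime$kappa, om, pi, scale = FALSE) / rbar, pi
    )
  })

  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  # preorder = reversed postorder edge list
  edge <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]
  elen <- rev(tr$edge.length)

  with_seed(seed, {
    classes <- sample.int(length(omegas), n_codons, replace = TRUE, prob = props)
    node_state <- matrix(0L, max(tr$edge), n_codons)
    node_state[n_tip + 1L, ] <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
    for (k in seq_len(nrow(edge))) {
      par <- node_state[edge[k, 1L], ]
      child <- integer(n_codons)
      for (cl in unique(classes)) {
        pm <- ctmc_pmat(spectra[[cl]], elen[k])
        sel <- which(classes == cl)
        for (st in unique(par[sel])) {
          ss <- sel[par[sel] == st]
          child[ss] <- sample.int(61L, length(ss), replace = TRUE, prob = pm[st, ])
        }
      }
      node_state[edge[k, 2L], ] <- child
    }
    aln <- codon_alignment(
      matrix(SENSE_CODONS[node_state[seq_len(n_tip), , drop = FALSE]],
        nrow = n_tip, dimnames = list(tr$tip.label, NULL)
      )
    )
    list(alignment = aln, site_classes = classes, regime = regime)
  })
}

#' Simulate a recombinant codon alignment with known breakpoints
#'
#' Concatenates independent simulations on a list of trees sharing the same
#' leaf set; the topology switch positions are returned as true breakpoints.
#'
#' @param trees list of >= 1 ape `phylo` objects with identical leaf label
#'   sets.
#' @param regime a [selection_regime] shared by all segments.
#' @param segment_lengths codons per segment (same length as `trees`).
#' @param seed RNG seed; segment i uses a seed derived from it.
#' @param codon_frequencies equilibrium frequencies.
#' @return list with `alignment`, `breakpoints` (codon position of the last
#'   codon of each segment but the final one; empty for a single segment),
#'   `site_classes`, and `segments` (start/end codon table).
#' @export
simulate_recombinant_alignment <- function(trees, regime, segment_lengths, seed,
                                           codon_frequencies = f3x4_frequencies()) {
  stopifnot(is.list(trees), length(trees) >= 1L,
            length(segment_lengths) == length(trees))
  labs <- sort(trees[[1L]]$tip.label)
  for (tr in trees[-1L]) {
    if (!identical(sort(tr$tip.label), labs)) {
      stop2("all trees must share the same leaf label set")
    }
  }
  seeds <- derive_seeds(seed, length(trees))
  sims <- lapply(seq_along(trees), function(i) {
    simulate_codon_alignment(
      trees[[i]], regime, segment_lengths[i], seeds[i], codon_frequencies
    )
  })
  states <- do.call(cbind, lapply(sims, function(s) {
    s$alignment$states[labs, , drop = FALSE]
  }))
  ends <- cumsum(segment_lengths)
  list(
    alignment = codon_alignment(
      matrix(SENSE_CODONS[states], nrow = length(labs),
             dimnames = list(labs, NULL))
    ),
    breakpoints = ends[-length(ends)],
    site_classes = unlist(lapply(sims, `[[`, "site_classes"), use.names = FALSE),
    segments = data.frame(
      segment = seq_along(trees),
      start = c(1L, utils::head(ends, -1L) + 1L),
      end = ends
    )
  )
}

## Controlled vocabulary of domain tokens and typical amino-acid lengths used
## by the domain-table simulator.
DOMAIN_VOCAB <- c(
  RING = 45L, BBOX = 40L, CC = 70L, COS = 60L, FN3 = 90L, `B30.2` = 170L,
  PHD = 50L, BROMO = 100L, NHL = 40L, FILAMIN = 95L, ARF = 160L, PYRIN = 90L,
  TM = 25L, MATH = 140L, CHROMO = 55L, RANBD = 130L, CYPA = 160L, other = 50L
)

#' Simulate a per-protein domain-annotation table
#'
#' Each protein draws an architecture string from `architecture_mix` and is
#' given ordered, non-overlapping domain intervals realizing it (typical
#' domain lengths, short inter-domain linkers).
#'
#' @param n_proteins number of proteins.
#' @param architecture_mix named numeric vector: names are comma-separated
#'   architecture strings over the domain vocabulary, values are frequencies
#'   summing to 1. An empty mix yields an empty table.
#' @param seed RNG seed.
#' @return data.frame with columns `protein_id`, `domain`, `start`, `end`
#'   (1-based inclusive amino-acid coordinates, sorted by start within
#'   protein).
#' @export
simulate_domain_table <- function(n_proteins, architecture_mix, seed) {
  empty <- data.frame(
    protein_id = character(), domain = character(),
    start = integer(), end = integer()
  )
  if (length(architecture_mix) == 0L) return(empty)
  stopifnot(abs(sum(architecture_mix) - 1) < 1e-8)
  archs <- strsplit(names(architecture_mix), ",", fixed = TRUE)
  toks <- unique(unlist(archs))
  bad <- setdiff(toks, names(DOMAIN_VOCAB))
  if (length(bad)) stop2("unknown domain token(s): ", paste(bad, collapse = ", "))
  if (n_proteins == 0L) return(empty)
  with_seed(seed, {
    pick <- sample.int(length(archs), n_proteins,
      replace = TRUE, prob = architecture_mix
    )
    rows <- lapply(seq_len(n_proteins), function(i) {
      doms <- archs[[pick[i]]]
      lens <- DOMAIN_VOCAB[doms]
      linkers <- sample(5:25, length(doms), replace = TRUE)
      starts <- cumsum(linkers + c(0L, utils::head(lens, -1L)))
      data.frame(
        protein_id = sprintf("prot%03d", i), domain = doms,
        start = as.integer(starts), end = as.integer(starts + lens - 1L)
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
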