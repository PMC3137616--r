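## Felsenstein pruning over the 61-codon state space, vectorized across
## alignment sites (one 61 x S partial-likelihood matrix per node, combined
## by dense matrix products) with per-site rescaling against underflow.

## Preprocess an ape "phylo" for pruning against an alignment's ids.
tree_struct <- function(tree, ids) {
  if (!inherits(tree, "phylo")) stop2("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop2("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop2("tree has negative branch lengths")
  if (length(tree$tip.label) < 2L) stop2("tree must have >= 2 leaves")
  miss <- setdiff(tree$tip.label, ids)
  if (length(miss)) {
    stop2("tree leaves without sequences: ", paste(miss, collapse = ", "))
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  list(
    parent = tree$edge[, 1L], child = tree$edge[, 2L],
    length = tree$edge.length, n_tip = n_tip,
    n_nodes = max(tree$edge), root = n_tip + 1L,
    tip_row = match(tree$tip.label, ids)
  )
}

## Collapse identical site patterns; returns compressed state matrix, weights
## and the site -> pattern index map.
compress_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(
    states = states[, u, drop = FALSE],
    weights = as.vector(table(factor(idx, levels = seq_len(sum(u))))),
    index = idx
  )
}

## Per-pattern log-likelihood under a single omega class. `sp` is the
## spectral decomposition of the (unscaled) generator, `nu` a multiplier on
## branch lengths, `pi` the root/equilibrium frequencies.
prune_loglik <- function(states, ts, sp, nu, pi) {
  S <- ncol(states)
  partial <- vector("list", ts$n_nodes)
  logscale <- numeric(S)
  for (k in seq_along(ts$parent)) {
    p <- ts$parent[k]
    ch <- ts$child[k]
    pm <- sp$A %*% (exp(sp$values * (nu * ts$length[k])) * sp$Ainv)
    pm[pm < 0] <- 0
    if (ch <= ts$n_tip) {
      contrib <- pm[, states[ts$tip_row[ch], ], drop = FALSE]
    } else {
      contrib <- pm %*% partial[[ch]]
      partial[ch] <- list(NULL)
    }
    # per-site rescale (column sums) against underflow on deep trees
    m <- .colSums(contrib, 61L, S)
    m[m <= 0] <- 1
    logscale <- logscale + log(m)
    contrib <- contrib * rep(1 / m, each = 61L)
    partial[[p]] <- if (is.null(partial[[p]])) contrib else partial[[p]] * contrib
  }
  log(colSums(partial[[ts$root]] * pi)) + logscale
}

## Per-pattern log-likelihoods for a set of omega classes sharing kappa and a
## branch-length multiplier nu. Two-layer memoisation: spectral decompositions
## keyed on (kappa, omega), pruned vectors keyed on (kappa, omega, nu) — so
## optimizer steps that perturb one parameter only recompute what changed.
class_site_logliks <- function(pat, ts, pi, kappa, omegas, nu, cache = NULL) {
  S <- ncol(pat$states)
  out <- matrix(0, S, length(omegas))
  for (k in seq_along(omegas)) {
    om <- omegas[k]
    llkey <- sprintf("l%.15g|%.15g|%.15g", kappa, om, nu)
    ll <- if (!is.null(cache)) cache[[llkey]] else NULL
    if (is.null(ll)) {
      spkey <- sprintf("s%.15g|%.15g", kappa, om)
      sp <- if (!is.null(cache)) cache[[spkey]] else NULL
      if (is.null(sp)) {
        sp <- ctmc_spectral(codon_rate_matrix(kappa, om, pi, scale = FALSE), pi)
        if (!is.null(cache)) cache[[spkey]] <- sp
      }
      ll <- prune_loglik(pat$states, ts, sp, nu, pi)
      if (!is.null(cache)) {
        cache[[llkey]] <- ll
        cache$.n_entries <- (cache$.n_entries %||% 0L) + 1L
      }
    }
    out[, k] <- ll
  }
  out
}

#' Per-site log-likelihood of a codon alignment on a tree
#'
#' Computes the log-likelihood of every codon site under a single-ratio
#' GY94xHKY85 model by Felsenstein pruning. Branch lengths are interpreted as
#' expected substitutions per codon at the supplied `(kappa, omega)`.
#'
#' @param alignment a [codon_alignment].
#' @param tree an ape `phylo` with branch lengths; leaves must be a subset of
#'   the alignment ids (every leaf needs a sequence).
#' @param kappa,omega model parameters.
#' @param frequencies equilibrium codon frequencies (61 values) or the string
#'   `"F3x4"` (estimated from the alignment) / `"F61"` (observed codon
#'   frequencies with a pseudocount).
#' @return numeric vector of length `alignment$c` of per-site log-likelihoods.
#' @export
site_likelihood <- function(alignment, tree, kappa, omega,
                            frequencies = "F3x4") {
  stopifnot(inherits(alignment, "codon_alignment"))
  pi <- resolve_frequencies(frequencies, alignment)
  ts <- tree_struct(tree, alignment$ids)
  states <- alignment$states
  if (ts$n_tip < alignment$n) {
    states <- states[ts$tip_row, , drop = FALSE]
    ts$tip_row <- seq_len(ts$n_tip)
  }
  pat <- compress_patterns(states)
  r <- codon_mean_rate(kappa, omega, pi)
  sp <- ctmc_spectral(codon_rate_matrix(kappa, omega, pi, scale = FALSE), pi)
  ll <- prune_loglik(pat$states, ts, sp, 1 / r, pi)
  ll[pat$index]
}

## Resolve a frequency specification against an alignment.
resolve_frequencies <- function(frequencies, alignment) {
  if (is.character(frequencies)) {
    freq <- match.arg(frequencies, c("F3x4", "F61"))
    if (freq == "F3x4") {
      return(unname(alignment_f3x4(alignment)))
    }
    cnt <- tabulate(as.integer(alignment$states), nbins = 61L) + 0.5
    return(cnt / sum(cnt))
  }
  .check_codon_freqs(frequencies)
}
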