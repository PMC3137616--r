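# Shared small fixtures built in code.

fixture_tree <- function(n_taxa, seed = 1, min_bl = 0.05, max_bl = 0.3) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

# quartet phylo ((t1,t2),(t3,t4)) with given branch lengths
# bl = c(t1, t2, t3, t4, internal)
fixture_quartet <- function(bl) {
  tr <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):0);")
  # ape stores this as a rooted binary tree; unroot to the 4-taxon topology
  tr <- ape::unroot(tr)
  o <- match(paste0("t", 1:4), tr$tip.label)
  # set per-edge lengths: tips then internal
  for (i in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[i, 2]
    tr$edge.length[i] <- if (ch <= 4) bl[which(o == ch)] else bl[5]
  }
  tr
}

fixture_m2a_regime <- function(omega_pos = 4, p_pos = 0.1, kappa = 2) {
  selection_regime("M2a",
    kappa = kappa, omegas = c(0.2, 1, omega_pos),
    proportions = c(0.9 - p_pos, 0.1, p_pos)
  )
}

random_aa_column <- function(n, alphabet_size = 20) {
  aa <- c(
    "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
  )
  sample(aa[seq_len(alphabet_size)], n, replace = TRUE)
}
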