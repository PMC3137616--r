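# Independent oracles used across tests. These deliberately avoid the
# package's pruning / counting code paths.

# Brute-force site likelihood by exhaustive enumeration of internal-node
# states, for the two fixed test topologies below. P matrices come from
# codon_transition_matrix (validated separately against a matrix-exponential
# oracle).

# unrooted 3-taxon star: one internal node r with tips 1..3
brute_loglik_star3 <- function(alignment, bl, kappa, omega, pi) {
  P <- lapply(bl, codon_transition_matrix,
    kappa = kappa, omega = omega, codon_frequencies = pi
  )
  st <- alignment$states
  vapply(seq_len(alignment$c), function(s) {
    tot <- 0
    for (r in 1:61) {
      tot <- tot + pi[r] * P[[1]][r, st[1, s]] * P[[2]][r, st[2, s]] *
        P[[3]][r, st[3, s]]
    }
    log(tot)
  }, numeric(1))
}

# unrooted 4-taxon tree ((t1,t2),(t3,t4)): internal nodes r (ancestor of
# t1,t2 and root) and u (ancestor of t3,t4), joined by branch bl[5]
brute_loglik_quartet <- function(alignment, bl, kappa, omega, pi) {
  P <- lapply(bl, codon_transition_matrix,
    kappa = kappa, omega = omega, codon_frequencies = pi
  )
  st <- alignment$states
  vapply(seq_len(alignment$c), function(s) {
    tot <- 0
    for (r in 1:61) {
      for (u in 1:61) {
        tot <- tot + pi[r] * P[[1]][r, st[1, s]] * P[[2]][r, st[2, s]] *
          P[[5]][r, u] * P[[3]][u, st[3, s]] * P[[4]][u, st[4, s]]
      }
    }
    log(tot)
  }, numeric(1))
}

# histogram-based Shannon entropy (bits) of a residue vector
entropy_oracle <- function(col) {
  aa <- c(
    "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
  )
  col <- col[col %in% aa]
  if (length(col) == 0) return(NA_real_)
  f <- as.numeric(table(col)) / length(col)
  -sum(f * log2(f))
}

# textbook Pearson chi-square from expected counts e_ij = row_i * col_j / N
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Nei-Gojobori (1986) counting estimate of dN/dS for two aligned sequences,
# with Jukes-Cantor correction; assumes kappa = 1 in the site counting.
ng86_omega <- function(seq1, seq2) {
  nucs <- c("T", "C", "A", "G")
  stops <- c("TAA", "TAG", "TGA")
  gc <- Biostrings::GENETIC_CODE
  split_codons <- function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  syn_sites <- function(codon) {
    # expected number of synonymous sites among the 3 positions
    tot <- 0
    for (p in 1:3) {
      alt <- nucs[nucs != substr(codon, p, p)]
      muts <- vapply(alt, function(b) {
        m <- codon
        substr(m, p, p) <- b
        m
      }, character(1))
      muts <- muts[!muts %in% stops]
      if (length(muts) > 0) {
        tot <- tot + sum(gc[muts] == gc[codon]) / 3
      }
    }
    tot
  }
  count_diffs <- function(c1, c2) {
    # average syn/nonsyn differences over all shortest mutational pathways
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(pos) == 0) return(c(0, 0))
    paths <- if (length(pos) == 1) list(pos) else {
      perms <- if (length(pos) == 2) list(pos, rev(pos)) else {
        do.call(c, lapply(seq_along(pos), function(i) {
          lapply(list(pos[-i], rev(pos[-i])), function(rest) c(pos[i], rest))
        }))
      }
      perms
    }
    acc <- c(0, 0)
    nok <- 0
    for (path in paths) {
      cur <- c1
      sd <- 0
      nd <- 0
      bad <- FALSE
      for (p in path) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (nxt %in% stops) {
          bad <- TRUE
          break
        }
        if (gc[nxt] == gc[cur]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (!bad) {
        acc <- acc + c(sd, nd)
        nok <- nok + 1
      }
    }
    acc / max(nok, 1)
  }
  cod1 <- split_codons(seq1)
  cod2 <- split_codons(seq2)
  S <- mean(c(sum(vapply(cod1, syn_sites, 0)), sum(vapply(cod2, syn_sites, 0))))
  N <- 3 * length(cod1) - S
  d <- vapply(seq_along(cod1), function(i) count_diffs(cod1[i], cod2[i]), numeric(2))
  ps <- sum(d[1, ]) / S
  pn <- sum(d[2, ]) / N
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  jc(pn) / jc(ps)
}
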