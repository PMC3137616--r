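## Recombination breakpoint detection: greedy forward search over a codon
## grid, comparing a single-phylogeny fit against segmented fits under
## small-sample corrected AIC (c-AIC). Per-segment likelihoods use the
## nucleotide HKY85 model with 4 discrete-gamma rate categories on
## neighbor-joining trees; kappa, base frequencies and the gamma shape are
## estimated once on the whole alignment and held fixed, so the scan is
## deterministic. This is a deliberately simple, deterministic substitution
## for a genetic-algorithm breakpoint search; per-segment parameter counts
## still charge 2n-3 branch lengths plus kappa and shape.

## codon_alignment -> nucleotide character matrix
codon_to_nuc_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  seqs <- as.character(alignment)
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- alignment$ids
  mat
}

## Whole-alignment HKY+G(4) fit for the shared nuisance parameters.
.global_hky_fit <- function(nucmat) {
  dat <- phangorn::phyDat(nucmat, type = "DNA")
  tr <- .nj_nuc_tree(nucmat)
  fit <- phangorn::pml(tr, dat, k = 4L, shape = 1)
  fit <- phangorn::optim.pml(
    fit,
    model = "HKY", optGamma = TRUE, optEdge = TRUE,
    control = phangorn::pml.control(trace = 0)
  )
  list(Q = fit$Q, bf = fit$bf, shape = fit$shape)
}

.nj_nuc_tree <- function(nucmat) {
  db <- ape::as.DNAbin(nucmat)
  d <- ape::dist.dna(db, model = "JC69", pairwise.deletion = TRUE)
  d[!is.finite(d)] <- 3
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

## lnL of one segment (codon coordinates, inclusive) under HKY+G(4) on its
## own NJ tree, with global nuisance parameters.
.segment_lnl <- function(nucmat, start, end, glob) {
  cols <- (3L * start - 2L):(3L * end)
  sub <- nucmat[, cols, drop = FALSE]
  tr <- .nj_nuc_tree(sub)
  dat <- phangorn::phyDat(sub, type = "DNA")
  fit <- phangorn::pml(tr, dat, bf = glob$bf, Q = glob$Q, shape = glob$shape, k = 4L)
  list(lnl = as.numeric(fit$logLik), tree = tr)
}

## small-sample corrected AIC
caic <- function(lnl, k, n) {
  pen <- 2 * k * (k + 1) / (n - k - 1)
  if (n - k - 1 <= 0) pen <- Inf
  -2 * lnl + 2 * k + pen
}

#' Scan a codon alignment for recombination breakpoints
#'
#' Greedy forward search: at each round, every candidate breakpoint on the
#' codon grid is scored by the c-AIC of the resulting partition (per-segment
#' NJ trees, HKY85 + discrete-gamma likelihood, shared kappa/shape/base
#' frequencies estimated once on the whole alignment); the best candidate is
#' added while it strictly decreases the total c-AIC. Segments shorter than
#' `min_segment` codons are never created.
#'
#' @param alignment a [codon_alignment].
#' @param max_breakpoints maximum number of breakpoints to add (>= 1).
#' @param grid_step candidate spacing in codons (default 3).
#' @param min_segment minimum segment length in codons (default 10).
#' @return an object of class `breakpoint_partition`: `breakpoints` (codon
#'   positions: a breakpoint at b splits codons b | b+1; integer(0) if none
#'   accepted), `breakpoints_nuc` (3 * codon position), `segments`
#'   (data.frame start/end/lnl), `trees` (per-segment NJ trees),
#'   `caic_single`, `caic_total`, `delta_caic`, `n_params`.
#' @export
scan_breakpoints <- function(alignment, max_breakpoints = 8L, grid_step = 3L,
                             min_segment = 10L) {
  stopifnot(inherits(alignment, "codon_alignment"), max_breakpoints >= 1L)
  cc <- alignment$c
  if (cc < 2L * grid_step) stop2("alignment too short for the candidate grid")
  nucmat <- codon_to_nuc_matrix(alignment)
  glob <- .global_hky_fit(nucmat)
  n_nuc <- ncol(nucmat)
  k_seg <- (2L * alignment$n - 3L) + 2L # branch lengths + kappa + shape

  cache <- new.env(parent = emptyenv())
  seg_fit <- function(start, end) {
    key <- paste0(start, "|", end)
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- .segment_lnl(nucmat, start, end, glob)
      cache[[key]] <- hit
    }
    hit
  }
  total_caic <- function(bps) {
    segs <- .bps_to_segments(bps, cc)
    lnl <- sum(vapply(
      seq_len(nrow(segs)),
      function(i) seg_fit(segs$start[i], segs$end[i])$lnl, numeric(1)
    ))
    caic(lnl, k_seg * nrow(segs), n_nuc)
  }

  bps <- integer(0)
  caic_single <- total_caic(bps)
  current <- caic_single
  repeat {
    if (length(bps) >= max_breakpoints) break
    bounds <- c(0L, bps, cc)
    cand <- setdiff(as.integer(seq(grid_step, cc - grid_step, by = grid_step)), bps)
    ok <- vapply(cand, function(b) {
      lo <- max(bounds[bounds < b])
      hi <- min(bounds[bounds > b])
      (b - lo) >= min_segment && (hi - b) >= min_segment
    }, logical(1))
    cand <- cand[ok]
    if (length(cand) == 0L) break
    scores <- vapply(cand, function(b) total_caic(sort(c(bps, b))), numeric(1))
    best <- which.min(scores)
    if (scores[best] >= current) break
    bps <- sort(c(bps, cand[best]))
    current <- scores[best]
  }

  segs <- .bps_to_segments(bps, cc)
  fits <- lapply(seq_len(nrow(segs)), function(i) seg_fit(segs$start[i], segs$end[i]))
  segs$lnl <- vapply(fits, `[[`, numeric(1), "lnl")
  structure(
    list(
      breakpoints = bps,
      breakpoints_nuc = 3L * bps,
      segments = segs,
      trees = lapply(fits, `[[`, "tree"),
      caic_single = caic_single,
      caic_total = current,
      delta_caic = caic_single - current,
      n_params = k_seg * nrow(segs),
      grid_step = grid_step, min_segment = min_segment
    ),
    class = "breakpoint_partition"
  )
}

.bps_to_segments <- function(bps, cc) {
  bounds <- as.integer(c(0L, sort(bps), cc))
  data.frame(
    start = utils::head(bounds, -1L) + 1L,
    end = bounds[-1L]
  )
}

#' @export
print.breakpoint_partition <- function(x, ...) {
  cat("breakpoint_partition:", length(x$breakpoints), "breakpoint(s)")
  if (length(x$breakpoints)) {
    cat(" at codon(s)", paste(x$breakpoints, collapse = ", "),
        "(nt", paste(x$breakpoints_nuc, collapse = ", "), ")")
  }
  cat(sprintf(
    "\n  c-AIC single = %.2f, partitioned = %.2f, delta = %.2f\n",
    x$caic_single, x$caic_total, x$delta_caic
  ))
  invisible(x)
}

#' Re-test positive selection independently within each segment
#'
#' Runs the nested site-model comparisons (M1a vs M2a and, optionally, M7 vs
#' M8) on each segment of a breakpoint partition, each segment on its own
#' internal NJ tree. Positively selected sites (BEB for M2a, NEB for M8,
#' posterior > 0.95) are reported in whole-alignment codon coordinates. A
#' failed segment is recorded and does not abort the others.
#'
#' @param alignment the [codon_alignment] that was scanned.
#' @param partition a `breakpoint_partition` (or anything with a `segments`
#'   data.frame of codon start/end).
#' @param model_pairs subset of `c("M1a-M2a", "M7-M8")`.
#' @param options optimizer options passed to [fit_site_model()].
#' @return list of per-segment results: `segment`, `start`, `end`, `fits`,
#'   `lrts` (named list of `lrt_result`), `positive_sites` (data.frame with
#'   whole-alignment codon positions), or `error`.
#' @export
segment_selection_tests <- function(alignment, partition,
                                    model_pairs = c("M1a-M2a", "M7-M8"),
                                    options = list()) {
  stopifnot(inherits(alignment, "codon_alignment"))
  model_pairs <- match.arg(model_pairs, several.ok = TRUE)
  segs <- partition$segments
  lapply(seq_len(nrow(segs)), function(i) {
    s <- segs$start[i]
    e <- segs$end[i]
    res <- list(segment = i, start = s, end = e)
    tryCatch(
      {
        sub <- subset_codons(alignment, s, e)
        tr <- nj_codon_tree(sub)
        fits <- list()
        lrts <- list()
        if ("M1a-M2a" %in% model_pairs) {
          fits$M1a <- fit_site_model(sub, tr, "M1a", options = options)
          warm <- utils::modifyList(options, list(init = .warm_start(fits$M1a, "M2a")))
          fits$M2a <- fit_site_model(sub, tr, "M2a", options = warm)
          lrts[["M1a-M2a"]] <- suppressWarnings(lrt(fits$M1a, fits$M2a))
        }
        if ("M7-M8" %in% model_pairs) {
          fits$M7 <- fit_site_model(sub, tr, "M7", options = options)
          warm <- utils::modifyList(options, list(init = .warm_start(fits$M7, "M8")))
          fits$M8 <- fit_site_model(sub, tr, "M8", options = warm)
          lrts[["M7-M8"]] <- suppressWarnings(lrt(fits$M7, fits$M8))
        }
        pos <- NULL
        if (!is.null(fits$M2a)) {
          sp <- site_posteriors(fits$M2a, sub, tr, method = "BEB")
          sp <- sp[sp$significant, , drop = FALSE]
          if (nrow(sp)) {
            pos <- data.frame(
              site = sp$site + s - 1L, # whole-alignment codon coordinates
              segment_site = sp$site,
              posterior = sp$posterior, method = sp$method
            )
          }
        }
        res$fits <- fits
        res$lrts <- lrts
        res$positive_sites <- pos %||% data.frame(
          site = integer(), segment_site = integer(),
          posterior = numeric(), method = character()
        )
        res
      },
      error = function(e) {
        res$error <- conditionMessage(e)
        res
      }
    )
  })
}

## Warm start for the alternative model of a nested pair, seeded from the
## null fit's MLEs (positive class starts tiny).
.warm_start <- function(null_fit, alt_model) {
  if (null_fit$model_id == "M1a" && alt_model == "M2a") {
    p0 <- null_fit$class_proportions[1L]
    c(
      lkappa = log(null_fit$kappa),
      qp0 = stats::qlogis(min(max(p0 * 0.98, 1e-4), 1 - 1e-4)),
      qp1 = stats::qlogis(0.95),
      qw0 = stats::qlogis(min(max(null_fit$class_omegas[1L], 1e-4), 1 - 1e-4)),
      lwpos = log(0.5), # omega_pos starts at 1.5

      lnu = log(null_fit$nu)
    )
  } else if (null_fit$model_id == "M7" && alt_model == "M8") {
    c(
      lkappa = log(null_fit$kappa),
      qp0 = stats::qlogis(0.98),
      lp = log(null_fit$beta_p),
      lq = log(null_fit$beta_q),
      lwpos = log(0.5),
      lnu = log(null_fit$nu)
    )
  } else {
    NULL
  }
}
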