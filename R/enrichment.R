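## Marker-neighbourhood co-localization analysis: build merged 5 Mb
## neighbourhoods around markers, collapse tandem gene clusters to single
## occurrences, and test family enrichment inside neighbourhoods with a 2x2
## Pearson chi-square (no continuity correction).

#' Build merged marker neighbourhoods
#'
#' For each marker, takes the interval `[position - flank, position + flank]`
#' clipped to the chromosome, and merges overlapping intervals per
#' chromosome. A gene is counted inside iff its start coordinate lies in a
#' merged interval (`rule = "start"`; `rule = "midpoint"` uses the gene
#' midpoint instead).
#'
#' @param annotation a `genome_annotation` (see
#'   [simulate_genome_annotation()] or [read_genome_annotation()]).
#' @param flank half-width in bp (default 5 Mb, the MHC-proper size used for
#'   MHC neighbourhoods).
#' @param rule gene-inclusion rule.
#' @return an object of class `neighbourhood_set`: `intervals` (chrom, start,
#'   end; 0-based half-open), `flank`, `total_length`, `n_genes_inside`,
#'   `rule`.
#' @export
build_neighbourhoods <- function(annotation, flank = 5e6,
                                 rule = c("start", "midpoint")) {
  stopifnot(inherits(annotation, "genome_annotation"), flank >= 0)
  rule <- match.arg(rule)
  merged <- .merge_marker_intervals(
    annotation$markers, annotation$chromosomes, flank
  )
  intervals <- do.call(rbind, lapply(names(merged), function(cn) {
    cbind(data.frame(chrom = cn), merged[[cn]])
  }))
  rownames(intervals) <- NULL
  ns <- structure(
    list(
      intervals = intervals, flank = flank,
      total_length = sum(intervals$end - intervals$start),
      rule = rule
    ),
    class = "neighbourhood_set"
  )
  ns$n_genes_inside <- sum(genes_inside(annotation$genes, ns))
  ns
}

#' @export
print.neighbourhood_set <- function(x, ...) {
  cat(
    "neighbourhood_set:", nrow(x$intervals), "merged intervals,",
    "total", format(x$total_length, big.mark = ","), "bp,",
    x$n_genes_inside %||% NA, "genes inside\n"
  )
  invisible(x)
}

#' Which genes (or occurrences) fall inside a neighbourhood set
#'
#' @param genes data.frame with columns `chrom`, `start` and either `end`
#'   (genes) or nothing else needed (`position` is used if present, e.g.
#'   collapsed occurrences).
#' @param nhood a `neighbourhood_set`.
#' @return logical vector, one entry per row of `genes`.
#' @export
genes_inside <- function(genes, nhood) {
  stopifnot(inherits(nhood, "neighbourhood_set"))
  pos <- if (!is.null(genes$position)) {
    genes$position
  } else if (nhood$rule == "midpoint") {
    (genes$start + genes$end) / 2
  } else {
    genes$start
  }
  out <- logical(nrow(genes))
  for (cn in unique(nhood$intervals$chrom)) {
    iv <- nhood$intervals[nhood$intervals$chrom == cn, ]
    sel <- genes$chrom == cn
    if (!any(sel)) next
    p <- pos[sel]
    hit <- logical(sum(sel))
    for (r in seq_len(nrow(iv))) {
      hit <- hit | (p >= iv$start[r] & p < iv$end[r])
    }
    out[sel] <- hit
  }
  out
}

#' Collapse tandem gene clusters into single occurrences
#'
#' Consecutive genes of one family on one chromosome whose inter-gene gap
#' (next start minus previous end) is at most `max_gap` form a cluster; each
#' cluster contributes one occurrence located at the midpoint of the cluster
#' span. This prevents recently tandem-duplicated genes from inflating
#' enrichment counts.
#'
#' @param genes data.frame of one family's genes (`chrom`, `start`, `end`,
#'   `gene_id`).
#' @param max_gap maximum intra-cluster gap in bp (default 500 kb).
#' @return data.frame of occurrences: `chrom`, `position` (cluster midpoint),
#'   `start`, `end` (cluster span), `n_genes`.
#' @export
collapse_tandem_clusters <- function(genes, max_gap = 5e5) {
  if (nrow(genes) == 0L) {
    return(data.frame(
      chrom = character(), position = numeric(), start = numeric(),
      end = numeric(), n_genes = integer()
    ))
  }
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  new_cluster <- c(
    TRUE,
    genes$chrom[-1L] != genes$chrom[-nrow(genes)] |
      genes$start[-1L] - genes$end[-nrow(genes)] > max_gap
  )
  cid <- cumsum(new_cluster)
  out <- do.call(rbind, lapply(split(seq_len(nrow(genes)), cid), function(ix) {
    s <- min(genes$start[ix])
    e <- max(genes$end[ix])
    data.frame(
      chrom = genes$chrom[ix[1L]], position = (s + e) / 2,
      start = s, end = e, n_genes = length(ix)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Chi-square test of family enrichment inside neighbourhoods
#'
#' Pearson chi-square test of independence (df = 1, no continuity
#' correction) on the 2x2 table of family vs other genes, inside vs outside
#' neighbourhoods. "Other" counts are the gene totals minus the family
#' counts.
#'
#' @param n_family_inside,n_family_outside family gene (or occurrence) counts.
#' @param n_genes_inside,n_genes_outside total gene counts inside/outside.
#' @param collapsed bookkeeping flag: whether family counts are collapsed
#'   cluster occurrences.
#' @return an object of class `enrichment_result`: `counts` (2x2 matrix),
#'   `chi2`, `df`, `p_value`, `collapsed`.
#' @export
enrichment_test <- function(n_family_inside, n_family_outside,
                            n_genes_inside, n_genes_outside,
                            collapsed = FALSE) {
  if (n_family_inside > n_genes_inside || n_family_outside > n_genes_outside) {
    stop2("family counts exceed gene totals")
  }
  counts <- matrix(
    c(
      n_family_inside, n_genes_inside - n_family_inside,
      n_family_outside, n_genes_outside - n_family_outside
    ),
    nrow = 2L,
    dimnames = list(c("family", "other"), c("inside", "outside"))
  )
  if (any(counts < 0)) stop2("negative cell count")
  margins <- c(
    family = sum(counts["family", ]), other = sum(counts["other", ]),
    inside = sum(counts[, "inside"]), outside = sum(counts[, "outside"])
  )
  if (any(margins == 0)) {
    stop2("empty margin: ", paste(names(margins)[margins == 0], collapse = ", "))
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(
    list(
      counts = counts, chi2 = unname(ct$statistic), df = 1L,
      p_value = unname(ct$p.value), collapsed = collapsed
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result (2x2 independence chi-square, df = 1",
      if (x$collapsed) ", collapsed occurrences" else "", ")\n", sep = "")
  print(x$counts)
  cat(sprintf("  chi2 = %.4f, p = %.4g\n", x$chi2, x$p_value))
  invisible(x)
}

#' Run the full family/neighbourhood co-localization analysis
#'
#' Composes [build_neighbourhoods()], [collapse_tandem_clusters()] and
#' [enrichment_test()]: when `collapse = TRUE` the family is counted as
#' cluster occurrences while the gene totals remain raw gene counts (the
#' construction used for the published MHC analysis, e.g. 62 class-IV
#' occurrences against 24,147 genes).
#'
#' @param annotation a `genome_annotation`.
#' @param family family label to test.
#' @param flank neighbourhood half-width (bp).
#' @param max_gap cluster-collapsing gap (bp).
#' @param collapse collapse tandem clusters before counting the family?
#' @param rule gene-inclusion rule (see [build_neighbourhoods()]).
#' @return list with `result` (an `enrichment_result`), `neighbourhoods`
#'   (a `neighbourhood_set`), and `occurrences` (the family occurrence table
#'   with an `inside` column).
#' @export
run_colocalization <- function(annotation, family, flank = 5e6,
                               max_gap = 5e5, collapse = TRUE,
                               rule = c("start", "midpoint")) {
  stopifnot(inherits(annotation, "genome_annotation"))
  rule <- match.arg(rule)
  fam_genes <- annotation$genes[annotation$genes$family == family, , drop = FALSE]
  if (nrow(fam_genes) == 0L) stop2("family not present in annotation: ", family)
  nhood <- build_neighbourhoods(annotation, flank, rule)
  inside_all <- genes_inside(annotation$genes, nhood)
  n_in <- sum(inside_all)
  n_out <- length(inside_all) - n_in
  occ <- if (collapse) {
    collapse_tandem_clusters(fam_genes, max_gap)
  } else {
    fam_genes
  }
  occ$inside <- genes_inside(occ, nhood)
  res <- enrichment_test(
    sum(occ$inside), sum(!occ$inside), n_in, n_out,
    collapsed = collapse
  )
  list(result = res, neighbourhoods = nhood, occurrences = occ)
}

#' Read a genome annotation from delimited text files
#'
#' @param genes_path TSV with columns chrom, start, end, gene_id, family
#'   (header optional; BED-like order).
#' @param markers_path TSV with columns chrom, position, marker_id.
#' @param sizes_path two-column TSV: chromosome name, length.
#' @param one_based if `TRUE`, input gene/marker coordinates are 1-based
#'   inclusive and are converted to the internal 0-based half-open dialect.
#' @return a `genome_annotation`.
#' @export
read_genome_annotation <- function(genes_path, markers_path, sizes_path,
                                   one_based = FALSE) {
  rd <- function(path, cols) {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    if (is.character(x[[2]]) || identical(as.character(x[1, 1]), cols[1])) {
      x <- x[-1, , drop = FALSE] # header row
      for (j in 2:ncol(x)) {
        sup <- suppressWarnings(as.numeric(x[[j]]))
        if (!all(is.na(sup))) x[[j]] <- sup
      }
    }
    names(x)[seq_along(cols)] <- cols
    x
  }
  sizes <- rd(sizes_path, c("name", "length"))
  genes <- rd(genes_path, c("chrom", "start", "end", "gene_id", "family"))
  markers <- rd(markers_path, c("chrom", "position", "marker_id"))
  if (one_based) {
    genes$start <- genes$start - 1
    markers$position <- markers$position - 1
  }
  if (anyDuplicated(genes$gene_id)) stop2("duplicate gene ids")
  len <- sizes$length[match(genes$chrom, sizes$name)]
  if (anyNA(len)) stop2("gene on unknown chromosome")
  if (any(genes$start < 0 | genes$start >= genes$end | genes$end > len)) {
    stop2("gene coordinates outside chromosome bounds")
  }
  structure(
    list(
      chromosomes = sizes[, c("name", "length")],
      genes = genes, markers = markers
    ),
    class = "genome_annotation"
  )
}

#' Write a genome annotation (and optionally neighbourhood intervals) to disk
#'
#' @param annotation a `genome_annotation`.
#' @param dir output directory (created if needed).
#' @param nhood optional `neighbourhood_set` written as BED.
#' @return the directory, invisibly.
#' @export
write_genome_annotation <- function(annotation, dir, nhood = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) {
    utils::write.table(x, file.path(dir, f),
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  wr(annotation$genes[, c("chrom", "start", "end", "gene_id", "family")], "genes.tsv")
  wr(annotation$markers[, c("chrom", "position", "marker_id")], "markers.tsv")
  wr(annotation$chromosomes, "chrom.sizes")
  if (!is.null(nhood)) {
    wr(nhood$intervals[, c("chrom", "start", "end")], "neighbourhoods.bed")
  }
  invisible(dir)
}
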