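#' Specification of a synthetic annotated genome
#'
#' Describes chromosomes, a background gene count, tandemly clustered gene
#' families, marker positions, and the enrichment of one designated family
#' inside marker neighbourhoods (+/- `flank` bp around each marker).
#' `enrichment_factor = 1` means the designated family is placed from the
#' same uniform distribution as the background (no enrichment); 0 forbids
#' placement inside neighbourhoods; larger values multiply the placement
#' density inside.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_lengths lengths in bp (recycled to `n_chromosomes`).
#' @param n_background_genes number of background ("other") genes.
#' @param family_specs list of lists with fields `family`, `n_clusters`,
#'   `genes_per_cluster`, `gap` (intra-cluster inter-gene gap, bp).
#' @param markers data.frame with columns `chrom` (index or name),
#'   `position`; default places two markers per chromosome at 20% and 60% of
#'   its length.
#' @param enrichment_factor relative placement density of the designated
#'   family inside marker neighbourhoods (>= 0).
#' @param enriched_family family label subject to the enrichment factor;
#'   defaults to the first family in `family_specs`.
#' @param gene_length gene footprint in bp.
#' @param flank neighbourhood half-width in bp (default 5 Mb).
#' @param seed RNG seed.
#' @return an object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_chromosomes = 4L,
                                  chromosome_lengths = 5e7,
                                  n_background_genes = 1950L,
                                  family_specs = list(list(
                                    family = "classIV", n_clusters = 50L,
                                    genes_per_cluster = 1L, gap = 2e4
                                  )),
                                  markers = NULL,
                                  enrichment_factor = 1,
                                  enriched_family = NULL,
                                  gene_length = 2000L,
                                  flank = 5e6,
                                  seed = 1L) {
  stopifnot(n_chromosomes >= 1L, enrichment_factor >= 0, gene_length >= 1)
  lens <- rep_len(chromosome_lengths, n_chromosomes)
  chroms <- data.frame(
    name = paste0("chr", seq_len(n_chromosomes)), length = lens
  )
  if (is.null(markers)) {
    markers <- data.frame(
      chrom = chroms$name,
      position = round(rep(lens, each = 1L) * 0.2)
    )
    markers <- rbind(
      markers,
      data.frame(chrom = chroms$name, position = round(lens * 0.6))
    )
  }
  if (is.numeric(markers$chrom)) markers$chrom <- chroms$name[markers$chrom]
  if (is.null(markers$marker_id)) {
    markers$marker_id <- paste0("marker", seq_len(nrow(markers)))
  }
  bad <- !markers$chrom %in% chroms$name
  if (any(bad)) stop2("marker on unknown chromosome: ", markers$chrom[bad][1])
  mlen <- chroms$length[match(markers$chrom, chroms$name)]
  if (any(markers$position < 0 | markers$position > mlen)) {
    stop2("marker position outside chromosome bounds")
  }
  for (fs in family_specs) {
    stopifnot(
      is.character(fs$family), fs$n_clusters >= 0L,
      fs$genes_per_cluster >= 1L, fs$gap >= 0
    )
  }
  structure(
    list(
      chromosomes = chroms, n_background_genes = as.integer(n_background_genes),
      family_specs = family_specs, markers = markers,
      enrichment_factor = enrichment_factor,
      enriched_family = enriched_family %||% family_specs[[1L]]$family,
      gene_length = as.integer(gene_length), flank = flank,
      seed = as.integer(seed)
    ),
    class = "synthetic_genome_spec"
  )
}

#' Simulate a genome annotation from a specification
#'
#' Background genes are placed uniformly (chromosome chosen proportional to
#' length). Family clusters are tandem runs of `genes_per_cluster` genes
#' separated by `gap` bp; the designated family's cluster anchors are drawn
#' by rejection from the background distribution, accepting positions inside
#' marker neighbourhoods with relative probability `enrichment_factor`
#' (so factor 1 is exactly the background distribution and factor 0 never
#' places the family inside).
#'
#' @param spec a [synthetic_genome_spec].
#' @return an object of class `genome_annotation`: `chromosomes`, `genes`
#'   (chrom, start, end, gene_id, family; 0-based half-open), `markers`.
#' @export
simulate_genome_annotation <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  chroms <- spec$chromosomes
  glen <- spec$gene_length
  total_gene_bp <- glen * (spec$n_background_genes +
    sum(vapply(spec$family_specs, function(f) f$n_clusters * f$genes_per_cluster, 0)))
  if (total_gene_bp > 0.5 * sum(chroms$length)) {
    stop2("infeasible packing: requested genes exceed half the genome length")
  }
  nhood <- .merge_marker_intervals(spec$markers, chroms, spec$flank)

  with_seed(spec$seed, {
    draw_pos <- function() {
      ci <- sample.int(nrow(chroms), 1L, prob = chroms$length)
      c(ci, floor(stats::runif(1, 0, chroms$length[ci] - glen)))
    }
    inside_nhood <- function(ci, pos) {
      iv <- nhood[[chroms$name[ci]]]
      !is.null(iv) && any(pos >= iv$start & pos < iv$end)
    }
    genes <- vector("list", 0L)

    # background genes
    if (spec$n_background_genes > 0L) {
      ci <- sample.int(nrow(chroms), spec$n_background_genes,
        replace = TRUE, prob = chroms$length
      )
      st <- floor(stats::runif(spec$n_background_genes, 0, chroms$length[ci] - glen))
      genes[[1L]] <- data.frame(
        chrom = chroms$name[ci], start = st, end = st + glen,
        gene_id = sprintf("bg%05d", seq_len(spec$n_background_genes)),
        family = "background"
      )
    }

    f <- spec$enrichment_factor
    acc_in <- f / max(f, 1)
    acc_out <- 1 / max(f, 1)
    for (fs in spec$family_specs) {
      enriched <- identical(fs$family, spec$enriched_family)
      span <- fs$genes_per_cluster * glen + (fs$genes_per_cluster - 1L) * fs$gap
      k <- 0L
      rows <- vector("list", fs$n_clusters)
      for (cl in seq_len(fs$n_clusters)) {
        for (try in seq_len(100000L)) {
          dp <- draw_pos()
          ci <- dp[1L]
          pos <- dp[2L]
          if (pos + span > chroms$length[ci]) next
          if (enriched) {
            p_acc <- if (inside_nhood(ci, pos)) acc_in else acc_out
            if (stats::runif(1) > p_acc) next
          }
          break
        }
        if (try >= 100000L) stop2("could not place cluster (placement rejected)")
        starts <- pos + (seq_len(fs$genes_per_cluster) - 1L) * (glen + fs$gap)
        k <- k + 1L
        rows[[k]] <- data.frame(
          chrom = chroms$name[ci], start = starts, end = starts + glen,
          gene_id = sprintf("%s_c%03d_g%02d", fs$family, cl,
                            seq_len(fs$genes_per_cluster)),
          family = fs$family
        )
      }
      genes[[length(genes) + 1L]] <- do.call(rbind, rows)
    }
    genes <- do.call(rbind, genes)
    rownames(genes) <- NULL
    structure(
      list(chromosomes = chroms, genes = genes, markers = spec$markers),
      class = "genome_annotation"
    )
  })
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(
    "genome_annotation:", nrow(x$chromosomes), "chromosomes,",
    nrow(x$genes), "genes,", nrow(x$markers), "markers\n"
  )
  invisible(x)
}

## Merged, clipped marker intervals per chromosome (named list of data.frames
## with 0-based half-open start/end), via IRanges::reduce.
.merge_marker_intervals <- function(markers, chroms, flank) {
  out <- list()
  for (cn in unique(markers$chrom)) {
    len <- chroms$length[match(cn, chroms$name)]
    if (is.na(len)) stop2("marker on unknown chromosome: ", cn)
    pos <- markers$position[markers$chrom == cn]
    if (any(pos < 0 | pos > len)) stop2("marker position outside chromosome ", cn)
    s <- pmax(0, pos - flank)
    e <- pmin(len, pos + flank)
    ir <- IRanges::reduce(IRanges::IRanges(start = s + 1, end = e))
    out[[cn]] <- data.frame(
      start = IRanges::start(ir) - 1, end = IRanges::end(ir)
    )
  }
  out
}
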