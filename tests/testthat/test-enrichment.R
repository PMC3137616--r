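mk_annotation <- function(genes, markers, chroms) {
  structure(
    list(chromosomes = chroms, genes = genes, markers = markers),
    class = "genome_annotation"
  )
}

test_that("neighbourhood intervals are built, clipped and merged", {
  chroms <- data.frame(name = "chr1", length = 30e6)
  genes <- data.frame(
    chrom = "chr1", start = c(1e6, 6e6), end = c(1.002e6, 6.002e6),
    gene_id = c("g1", "g2"), family = "x"
  )
  mk <- function(pos) {
    data.frame(chrom = "chr1", position = pos,
               marker_id = paste0("m", seq_along(pos)))
  }
  # plain arithmetic
  ns <- build_neighbourhoods(mk_annotation(genes, mk(10e6), chroms))
  expect_equal(ns$intervals$start, 5e6)
  expect_equal(ns$intervals$end, 15e6)
  # boundary clipping
  ns2 <- build_neighbourhoods(mk_annotation(genes, mk(2e6), chroms))
  expect_equal(ns2$intervals$start, 0)
  expect_equal(ns2$intervals$end, 7e6)
  expect_equal(ns2$n_genes_inside, 2)
  # merging two overlapping neighbourhoods, against a brute-force scan
  ns3 <- build_neighbourhoods(mk_annotation(genes, mk(c(10e6, 14e6)), chroms))
  expect_equal(nrow(ns3$intervals), 1)
  expect_equal(ns3$total_length, 14e6)
  grid <- seq(0, 30e6 - 1, by = 1e4) # brute-force position scan
  covered <- (grid >= 5e6 & grid < 15e6) | (grid >= 9e6 & grid < 19e6)
  in_merged <- grid >= ns3$intervals$start & grid < ns3$intervals$end
  expect_identical(in_merged, covered)
  # invariance to marker input order
  ns4 <- build_neighbourhoods(mk_annotation(genes, mk(c(14e6, 10e6)), chroms))
  expect_equal(ns3$total_length, ns4$total_length)
  # marker off the chromosome is an error
  expect_error(
    build_neighbourhoods(mk_annotation(genes, mk(40e6), chroms)),
    "outside chromosome"
  )
})

test_that("tandem-cluster collapsing follows the gap rule", {
  gene <- function(id, chrom, start, fam = "f") {
    data.frame(chrom = chrom, start = start, end = start + 2e3,
               gene_id = id, family = fam)
  }
  # 5 tandem genes with 20 kb gaps -> one occurrence
  run <- do.call(rbind, lapply(1:5, function(i) {
    gene(paste0("g", i), "chr1", 1e6 + (i - 1) * 22e3)
  }))
  occ <- collapse_tandem_clusters(run, max_gap = 5e5)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$n_genes, 5)
  expect_equal(occ$position, (min(run$start) + max(run$end)) / 2)
  # 2 genes 2 Mb apart -> two occurrences
  two <- rbind(gene("a", "chr1", 1e6), gene("b", "chr1", 3e6))
  expect_equal(nrow(collapse_tandem_clusters(two, max_gap = 5e5)), 2)
  # chromosome boundaries always split clusters
  cross <- rbind(gene("a", "chr1", 1e6), gene("b", "chr2", 1.01e6))
  expect_equal(nrow(collapse_tandem_clusters(cross, max_gap = 5e5)), 2)
})

test_that("family-wise collapsing matches an exhaustive grouping oracle", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    genes <- data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample.int(5e6, n),
      gene_id = paste0("g", 1:n),
      family = sample(c("A", "B"), n, replace = TRUE)
    )
    genes$end <- genes$start + 1e3
    max_gap <- 2e5
    for (fam in c("A", "B")) {
      sub <- genes[genes$family == fam, , drop = FALSE]
      got <- nrow(collapse_tandem_clusters(sub, max_gap))
      # oracle: exhaustive pairwise chaining within chromosome
      if (nrow(sub) == 0) {
        expect_equal(got, 0)
        next
      }
      sub <- sub[order(sub$chrom, sub$start), ]
      links <- 0
      for (i in seq_len(nrow(sub) - 1)) {
        if (sub$chrom[i + 1] == sub$chrom[i] &&
              sub$start[i + 1] - sub$end[i] <= max_gap) {
          links <- links + 1
        }
      }
      expect_equal(got, nrow(sub) - links)
    }
  }
})

test_that("chi-square matches the textbook independence statistic", {
  # worked example from the published class-IV/MHC table
  res <- enrichment_test(31, 31, 7884, 16263)
  expect_equal(res$chi2, chisq_oracle(res$counts), tolerance = 1e-10)
  # equal proportions give chi2 = 0, p = 1
  r0 <- enrichment_test(10, 20, 100, 200)
  expect_equal(r0$chi2, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  # spot case against the from-scratch oracle
  r1 <- enrichment_test(10, 5, 100, 100)
  expect_equal(r1$chi2, chisq_oracle(r1$counts), tolerance = 1e-10)
  # 1000 random tables
  set.seed(8)
  for (i in 1:1000) {
    fi <- sample.int(50, 1)
    fo <- sample.int(50, 1)
    gi <- fi + sample.int(500, 1)
    go <- fo + sample.int(500, 1)
    r <- enrichment_test(fi, fo, gi, go)
    expect_equal(r$chi2, chisq_oracle(r$counts), tolerance = 1e-10)
    expect_equal(
      r$p_value, stats::pchisq(r$chi2, 1, lower.tail = FALSE),
      tolerance = 1e-12
    )
  }
})

test_that("degenerate tables fail with the empty margin named", {
  expect_error(enrichment_test(0, 0, 100, 100), "family")
  expect_error(enrichment_test(5, 0, 5, 0), "outside")
  expect_error(enrichment_test(10, 5, 5, 100), "exceed")
})

test_that("run_colocalization composes counts consistently", {
  spec <- synthetic_genome_spec(
    n_background_genes = 500L,
    family_specs = list(list(family = "classIV", n_clusters = 8L,
                             genes_per_cluster = 4L, gap = 2e4)),
    enrichment_factor = 2, seed = 77
  )
  ann <- simulate_genome_annotation(spec)
  res <- run_colocalization(ann, "classIV", collapse = TRUE)
  # gene totals stay raw: the table margins add up to the full gene count
  expect_equal(sum(res$result$counts), nrow(ann$genes))
  # family counts are collapsed occurrences (8 clusters unless two merged)
  expect_lte(nrow(res$occurrences), 8)
  expect_gte(nrow(res$occurrences), 6)
  expect_equal(sum(res$result$counts["family", ]), nrow(res$occurrences))
  # uncollapsed counts use the raw family genes
  res2 <- run_colocalization(ann, "classIV", collapse = FALSE)
  expect_equal(sum(res2$result$counts["family", ]), 32)
  expect_equal(sum(res2$result$counts), nrow(ann$genes))
  expect_error(run_colocalization(ann, "absent_family"), "not present")
})

test_that("annotation tables round-trip through disk", {
  spec <- synthetic_genome_spec(n_background_genes = 50L, seed = 5)
  ann <- simulate_genome_annotation(spec)
  dir <- withr::local_tempdir()
  write_genome_annotation(ann, dir)
  back <- read_genome_annotation(
    file.path(dir, "genes.tsv"), file.path(dir, "markers.tsv"),
    file.path(dir, "chrom.sizes")
  )
  expect_equal(nrow(back$genes), nrow(ann$genes))
  expect_equal(sort(back$genes$gene_id), sort(ann$genes$gene_id))
  expect_equal(back$genes$start[order(back$genes$gene_id)],
               ann$genes$start[order(ann$genes$gene_id)])
})
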