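## Pipeline orchestration: a validated flat configuration that round-trips
## to disk as plain key=value text, and a runner that executes the toggled
## stages (classify -> entropy -> recomb -> select -> coloc) on file inputs,
## writing tab-separated stage outputs and a machine-readable key=value
## summary (versions, seed, options, per-stage results; no timestamps, so
## identical configurations yield identical summaries).

.config_defaults <- function() {
  list(
    seed = 1L, out_dir = "trimevol-out",
    # stage toggles
    classify = FALSE, entropy = FALSE, recomb = FALSE, select = FALSE,
    coloc = FALSE,
    # input paths
    domain_table = NA_character_, protein_alignment = NA_character_,
    codon_alignment = NA_character_, tree = NA_character_,
    genes = NA_character_, markers = NA_character_,
    chrom_sizes = NA_character_,
    # stage options
    max_gap_fraction = 0.5,
    select_models = "M0,M1a,M2a", frequencies = "F3x4",
    max_breakpoints = 8L, grid_step = 3L, min_segment = 10L,
    family = NA_character_, flank = 5e6, max_gap = 5e5, collapse = TRUE
  )
}

#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Unknown keys are
#' rejected. See [write_pipeline_config()] / [read_pipeline_config()] for the
#' lossless plain-text round trip.
#'
#' @param ... configuration entries overriding the defaults: stage toggles
#'   (`classify`, `entropy`, `recomb`, `select`, `coloc`), input paths
#'   (`domain_table`, `protein_alignment`, `codon_alignment`, `tree`,
#'   `genes`, `markers`, `chrom_sizes`), `seed`, `out_dir`, and stage options
#'   (`max_gap_fraction`, `select_models`, `frequencies`, `max_breakpoints`,
#'   `grid_step`, `min_segment`, `family`, `flank`, `max_gap`, `collapse`).
#' @return an object of class `pipeline_config` (named list).
#' @export
pipeline_config <- function(...) {
  opts <- list(...)
  defaults <- .config_defaults()
  unknown <- setdiff(names(opts), names(defaults))
  if (length(unknown)) {
    stop2("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, opts)
  for (k in c("classify", "entropy", "recomb", "select", "coloc", "collapse")) {
    cfg[[k]] <- as.logical(cfg[[k]])
  }
  for (k in c("seed", "max_breakpoints", "grid_step", "min_segment")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path file path for the key=value text form.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, "=", if (is.na(v)) "NA" else format(v, scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  defaults <- .config_defaults()
  parsed <- lapply(seq_along(keys), function(i) {
    k <- keys[i]
    v <- vals[i]
    proto <- defaults[[k]]
    if (is.null(proto)) return(v) # rejected below by pipeline_config()
    if (identical(v, "NA")) return(proto[NA][1L])
    if (is.logical(proto)) as.logical(v)
    else if (is.integer(proto)) as.integer(v)
    else if (is.numeric(proto)) as.numeric(v)
    else v
  })
  names(parsed) <- keys
  do.call(pipeline_config, parsed)
}

#' Run the analysis pipeline
#'
#' Executes the toggled stages on the configured inputs and writes
#' tab-separated stage outputs plus a `summary.txt` (key=value) recording the
#' package version, the seed, every option used, and each stage's headline
#' results. A failing stage is recorded (`status = 3`) and stages depending
#' on its inputs are skipped; invalid inputs give `status = 2`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with `status` (0 ok, 2 invalid input, 3 stage
#'   failure), per-stage result objects, and `summary_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 5L)
  out <- list(status = 0L)
  summary_kv <- c(
    package = "trimevol",
    version = as.character(utils::packageVersion("trimevol")),
    seed = config$seed
  )
  for (k in setdiff(names(config), c("seed"))) {
    summary_kv[paste0("config.", k)] <- as.character(config[[k]])
  }
  fail <- function(stage, e, code = 3L) {
    out$status <<- max(out$status, code)
    summary_kv[paste0(stage, ".error")] <<- conditionMessage(e)
  }

  if (config$classify) {
    tryCatch({
      dt <- read_domain_table(config$domain_table)
      calls <- classify_domain_table(dt)
      novel <- detect_novel_combinations(calls)
      utils::write.table(calls, file.path(config$out_dir, "classify_calls.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      tab <- table(calls$trim_class)
      summary_kv[paste0("classify.n_", names(tab))] <- as.integer(tab)
      summary_kv["classify.n_novel_architectures"] <- nrow(novel)
      out$classify <- list(calls = calls, novel = novel)
    }, error = function(e) fail("classify", e))
  }

  if (config$entropy) {
    tryCatch({
      aln <- read_alignment(config$protein_alignment, "protein")
      prof <- profile_alignment(aln, config$max_gap_fraction)
      write_entropy_profile(prof, file.path(config$out_dir, "entropy_profile.tsv"))
      summary_kv["entropy.n_columns"] <- nrow(prof)
      summary_kv["entropy.n_hypervariable"] <- sum(prof$hypervariable)
      summary_kv["entropy.n_masked"] <- sum(prof$masked)
      out$entropy <- prof
    }, error = function(e) fail("entropy", e))
  }

  caln <- NULL
  cmap <- NULL
  if (config$recomb || config$select) {
    tryCatch({
      raw <- read_alignment(config$codon_alignment, "codon")
      nog <- remove_gapped_columns(raw)
      caln <- as_codon_alignment(nog)
      cmap <- attr(nog, "column_map")
      summary_kv["codon.n_sequences"] <- caln$n
      summary_kv["codon.n_codons"] <- caln$c
    }, error = function(e) fail("codon_input", e, 2L))
  }

  if (config$recomb) {
    if (is.null(caln)) {
      summary_kv["recomb.skipped"] <- "missing codon alignment"
    } else {
      tryCatch({
        part <- scan_breakpoints(
          caln, config$max_breakpoints, config$grid_step, config$min_segment
        )
        bp_orig <- cmap[part$breakpoints]
        utils::write.table(
          data.frame(
            index = seq_along(part$breakpoints),
            codon = bp_orig,
            nucleotide = 3L * bp_orig,
            delta_caic = part$delta_caic
          ),
          file.path(config$out_dir, "breakpoints.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE
        )
        summary_kv["recomb.n_breakpoints"] <- length(part$breakpoints)
        summary_kv["recomb.delta_caic"] <- sprintf("%.4f", part$delta_caic)
        out$recomb <- part
      }, error = function(e) fail("recomb", e))
    }
  }

  if (config$select) {
    if (is.null(caln)) {
      summary_kv["select.skipped"] <- "missing codon alignment"
    } else {
      tryCatch({
        models <- strsplit(config$select_models, ",", fixed = TRUE)[[1L]]
        tree <- if (!is.na(config$tree)) ape::read.tree(config$tree) else NULL
        fits <- list()
        for (m in models) {
          warm <- if (m == "M2a" && !is.null(fits$M1a)) {
            list(init = .warm_start(fits$M1a, "M2a"), seed = seeds[4L])
          } else if (m == "M8" && !is.null(fits$M7)) {
            list(init = .warm_start(fits$M7, "M8"), seed = seeds[4L])
          } else {
            list(seed = seeds[4L])
          }
          fits[[m]] <- fit_site_model(caln, tree, m,
            frequencies = config$frequencies, options = warm
          )
          summary_kv[paste0("select.", m, ".lnL")] <- sprintf("%.6f", fits[[m]]$lnL)
        }
        if (all(c("M1a", "M2a") %in% names(fits))) {
          t12 <- suppressWarnings(lrt(fits$M1a, fits$M2a))
          summary_kv["select.lrt.M1a_M2a.p"] <- sprintf("%.6g", t12$p_value)
          sp <- site_posteriors(fits$M2a, caln, method = "BEB")
          sig <- sp[sp$significant, , drop = FALSE]
          sig$site_original <- cmap[sig$site]
          utils::write.table(
            cbind(site_original = cmap[sp$site], sp),
            file.path(config$out_dir, "site_posteriors.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE
          )
          summary_kv["select.n_positive_sites"] <- nrow(sig)
        }
        if (all(c("M7", "M8") %in% names(fits))) {
          t78 <- suppressWarnings(lrt(fits$M7, fits$M8))
          summary_kv["select.lrt.M7_M8.p"] <- sprintf("%.6g", t78$p_value)
        }
        out$select <- fits
      }, error = function(e) fail("select", e))
    }
  }

  if (config$coloc) {
    tryCatch({
      ann <- read_genome_annotation(
        config$genes, config$markers, config$chrom_sizes
      )
      res <- run_colocalization(
        ann, config$family, config$flank, config$max_gap, config$collapse
      )
      write_genome_annotation(ann, config$out_dir, res$neighbourhoods)
      summary_kv["coloc.chi2"] <- sprintf("%.4f", res$result$chi2)
      summary_kv["coloc.p_value"] <- sprintf("%.6g", res$result$p_value)
      summary_kv["coloc.n_family_inside"] <- res$result$counts["family", "inside"]
      summary_kv["coloc.n_family_outside"] <- res$result$counts["family", "outside"]
      out$coloc <- res
    }, error = function(e) fail("coloc", e))
  }

  summary_kv["status"] <- out$status
  sp <- file.path(config$out_dir, "summary.txt")
  writeLines(paste0(names(summary_kv), "=", summary_kv), sp)
  out$summary_path <- sp
  invisible(out)
}
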