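## TRIM structural classification from domain-annotation tables. The nine
## classes are keyed on the C-terminal domain content downstream of the
## RING/B-box/coiled-coil (RBCC) module; RBCC completeness is recorded as
## flags rather than blocking classification, since domain losses (RING in
## particular) are common in fish TRIM repertoires.

## class-defining C-terminal domain tokens
CLASS_DOMAINS <- c("COS", "FN3", "B30.2", "PHD", "BROMO", "FILAMIN", "NHL",
                   "MATH", "ARF")

#' Canonical TRIM class lookup table
#'
#' The shipped mapping from C-terminal domain content (downstream of the
#' RBCC) to structural class: COS+FN3+B30.2 -> I; COS -> II; COS+FN3 -> III;
#' B30.2 -> IV; none -> V; PHD+BROMO -> VI; FILAMIN+NHL -> VII; MATH -> VIII;
#' ARF -> IX. Returned as an editable data.frame (signature strings are
#' sorted, "+"-joined domain sets).
#'
#' @return data.frame with columns `signature` and `trim_class`.
#' @export
trim_class_table <- function() {
  sig <- function(...) paste(sort(c(...)), collapse = "+")
  data.frame(
    signature = c(
      sig("COS", "FN3", "B30.2"), sig("COS"), sig("COS", "FN3"),
      sig("B30.2"), "", sig("PHD", "BROMO"), sig("FILAMIN", "NHL"),
      sig("MATH"), sig("ARF")
    ),
    trim_class = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX")
  )
}

#' Classify one protein's domain architecture into a TRIM class
#'
#' The class is decided by the set of class-defining C-terminal domains
#' present (COS, FN3, B30.2, PHD, BROMO, FILAMIN, NHL, MATH, ARF), looked up
#' in [trim_class_table()]. Proteins with neither RING nor B-box are
#' non-TRIM. Missing RBCC components are recorded as flags
#' (`missing_RING`, `missing_BBOX`, `missing_CC`) without preventing
#' classification; any domain token outside the RBCC and class-defining sets
#' (for example TM, CHROMO, RANBD, CYPA), or a class signature absent from
#' the table, raises the `novel_combination` flag.
#'
#' @param domains data.frame for one protein with columns `domain`, `start`,
#'   `end` (1-based inclusive), or a character vector of domain tokens in
#'   N-to-C order.
#' @param protein_id identifier recorded in the call.
#' @return an object of class `architecture_call` (a one-row data.frame):
#'   `protein_id`, `architecture` (ordered, comma-joined), `trim_class`
#'   (I..IX, unclassified, non-TRIM), `flags` (comma-joined).
#' @export
classify_architecture <- function(domains, protein_id = "protein") {
  if (is.character(domains)) {
    doms <- domains
  } else {
    if (nrow(domains) > 0L) {
      if (any(domains$start > domains$end)) stop2("domain with start > end")
      domains <- domains[order(domains$start), , drop = FALSE]
    }
    doms <- as.character(domains$domain)
    if (!is.null(domains$protein_id) && nrow(domains) > 0L) {
      protein_id <- as.character(domains$protein_id[1L])
    }
  }
  bad <- setdiff(doms, names(DOMAIN_VOCAB))
  if (length(bad)) stop2("unknown domain token(s): ", paste(bad, collapse = ", "))

  flags <- character()
  if (length(doms) == 0L || (!"RING" %in% doms && !"BBOX" %in% doms)) {
    cls <- "non-TRIM"
    if (length(doms) > 0L) flags <- "missing_RING,missing_BBOX fallthrough"
    return(.arch_call(protein_id, doms, cls, character()))
  }
  if (!"RING" %in% doms) flags <- c(flags, "missing_RING")
  if (!"BBOX" %in% doms) flags <- c(flags, "missing_BBOX")
  if (!"CC" %in% doms) flags <- c(flags, "missing_CC")

  signature <- paste(sort(unique(intersect(doms, CLASS_DOMAINS))), collapse = "+")
  tab <- trim_class_table()
  hit <- match(signature, tab$signature)
  cls <- if (is.na(hit)) "unclassified" else tab$trim_class[hit]

  extra <- setdiff(doms, c("RING", "BBOX", "CC", CLASS_DOMAINS))
  if (length(extra) > 0L || is.na(hit)) {
    flags <- c(flags, "novel_combination")
  }
  .arch_call(protein_id, doms, cls, flags)
}

.arch_call <- function(protein_id, doms, cls, flags) {
  out <- data.frame(
    protein_id = protein_id,
    architecture = paste(doms, collapse = ","),
    trim_class = cls,
    flags = paste(flags, collapse = ",")
  )
  class(out) <- c("architecture_call", "data.frame")
  out
}

#' Classify every protein of a domain-annotation table
#'
#' @param domain_table data.frame with columns `protein_id`, `domain`,
#'   `start`, `end` (e.g. from [simulate_domain_table()] or
#'   [read_domain_table()]).
#' @return data.frame of architecture calls, one row per protein.
#' @export
classify_domain_table <- function(domain_table) {
  if (nrow(domain_table) == 0L) {
    return(data.frame(
      protein_id = character(), architecture = character(),
      trim_class = character(), flags = character()
    ))
  }
  calls <- lapply(
    split(domain_table, domain_table$protein_id),
    classify_architecture
  )
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out[order(out$protein_id), , drop = FALSE]
}

#' Report non-canonical domain architectures
#'
#' Collects architectures flagged as novel combinations and names the three
#' recognized gain-of-domain patterns: a C-terminal chromodomain replacing
#' B30.2 (`chromodomain_gain`, ftr06-like), a C-terminal RanBD + cyclophilin A
#' pair (`cypa_gain`, ftr52-like), and a transmembrane segment replacing the
#' B-box/coiled-coil between RING and B30.2 (`ring_tm_b30.2`, btr31-like).
#' Other novelties are reported as `other_novel`.
#'
#' @param calls data.frame of architecture calls
#'   (see [classify_domain_table()]).
#' @return data.frame with columns `architecture`, `pattern`, `n_proteins`,
#'   `protein_ids`; zero rows when every architecture is canonical.
#' @export
detect_novel_combinations <- function(calls) {
  novel <- calls[grepl("novel_combination", calls$flags), , drop = FALSE]
  if (nrow(novel) == 0L) {
    return(data.frame(
      architecture = character(), pattern = character(),
      n_proteins = integer(), protein_ids = character()
    ))
  }
  pattern_of <- function(arch) {
    doms <- strsplit(arch, ",", fixed = TRUE)[[1L]]
    last <- doms[length(doms)]
    if (last == "CHROMO") return("chromodomain_gain")
    if (last == "CYPA" && "RANBD" %in% doms) return("cypa_gain")
    if ("TM" %in% doms && "B30.2" %in% doms &&
          !("BBOX" %in% doms) && !("CC" %in% doms)) {
      return("ring_tm_b30.2")
    }
    "other_novel"
  }
  out <- do.call(rbind, lapply(split(novel, novel$architecture), function(g) {
    data.frame(
      architecture = g$architecture[1L],
      pattern = pattern_of(g$architecture[1L]),
      n_proteins = nrow(g),
      protein_ids = paste(sort(g$protein_id), collapse = ",")
    )
  }))
  rownames(out) <- NULL
  out
}

#' Pair truncated proteins with full-length co-orthologues ("like" variants)
#'
#' A protein lacking any class-defining C-terminal domain (a bare or partial
#' RBCC) is paired with its most sequence-similar full-architecture protein
#' when the pairwise identity reaches `threshold`; it is then flagged as a
#' "like" variant of that gene. Ties on identity are broken toward the
#' lexicographically smallest candidate id and noted in the output.
#'
#' @param calls data.frame of architecture calls.
#' @param sequence_similarity symmetric matrix of pairwise identities in
#'   `[0, 1]` with protein ids as dimnames.
#' @param threshold minimum identity for pairing (default 0.7).
#' @return data.frame with columns `truncated_id`, `partner_id`, `identity`,
#'   `tie` (logical); zero rows if nothing pairs.
#' @export
call_like_variants <- function(calls, sequence_similarity, threshold = 0.7) {
  m <- as.matrix(sequence_similarity)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)) ||
        any(m < 0 | m > 1)) {
    stop2("sequence_similarity must be a symmetric identity matrix in [0, 1]")
  }
  has_cterm <- vapply(
    strsplit(calls$architecture, ",", fixed = TRUE),
    function(d) length(intersect(d, CLASS_DOMAINS)) > 0L, logical(1)
  )
  is_trim <- calls$trim_class != "non-TRIM"
  truncated <- calls$protein_id[is_trim & !has_cterm]
  full <- calls$protein_id[is_trim & has_cterm]
  out <- data.frame(
    truncated_id = character(), partner_id = character(),
    identity = numeric(), tie = logical()
  )
  for (tid in truncated) {
    if (!tid %in% rownames(m)) next
    cand <- intersect(full, colnames(m))
    if (length(cand) == 0L) next
    sims <- m[tid, cand]
    best <- max(sims)
    if (best < threshold) next
    winners <- sort(cand[sims == best])
    out <- rbind(out, data.frame(
      truncated_id = tid, partner_id = winners[1L],
      identity = best, tie = length(winners) > 1L
    ))
  }
  rownames(out) <- NULL
  out
}

#' Read / write domain-annotation tables
#'
#' Tab-separated, columns `protein_id`, `domain`, `start`, `end`.
#'
#' @param path file path.
#' @return data.frame (for `read_domain_table`).
#' @export
read_domain_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("protein_id", "domain", "start", "end")
  if (!all(need %in% names(x))) {
    stop2("domain table must have columns: ", paste(need, collapse = ", "))
  }
  x
}

#' @rdname read_domain_table
#' @param domain_table data.frame to write.
#' @export
write_domain_table <- function(domain_table, path) {
  utils::write.table(domain_table, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
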