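.RANKS <- c("phylum", "class", "order", "family", "genus")

#' Read a taxonomy-labelled ASV count table
#'
#' Expects a TSV with a `taxon_id` column, a `lineage` column of
#' semicolon-delimited `rank:name` pairs (ranks among phylum, class, order,
#' family, genus; possibly incomplete), and one integer count column per
#' sample - the layout common amplicon pipelines export.
#'
#' @param file Path to the TSV.
#' @return An `asv_table`: list with `counts` (taxa x samples integer matrix)
#'   and `lineage` (character vector per taxon).
#' @export
readAsvTable <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("taxon_id", "lineage") %in% names(tab))) {
    stop("ASV table needs 'taxon_id' and 'lineage' columns")
  }
  scols <- setdiff(names(tab), c("taxon_id", "lineage"))
  counts <- as.matrix(tab[, scols, drop = FALSE])
  rownames(counts) <- tab$taxon_id
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  asvTable(counts, tab$lineage)
}

#' Construct an ASV table object from components
#' @param counts Taxa x samples non-negative integer matrix.
#' @param lineage Character vector of semicolon-delimited `rank:name` pairs,
#'   one per taxon.
#' @return An `asv_table` object.
#' @export
asvTable <- function(counts, lineage) {
  stopifnot(is.matrix(counts), nrow(counts) == length(lineage))
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, lineage = lineage), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d taxa x %d samples, %d reads total\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Read a copiotroph/oligotroph classification rule set
#'
#' @param file Path to a TSV with columns `rank`, `name`, `group`
#'   (`copiotroph` or `oligotroph`); `NULL` loads the packaged demonstration
#'   rule set (which mirrors the broad phylum/class memberships named in the
#'   amplicon literature and is not a reproduction of any published full
#'   criteria list).
#' @return A `classification_rules` data.frame; conflicting duplicate
#'   (rank, name) keys are dropped with a warning and such lineages classify
#'   as unassigned.
#' @export
classificationRules <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "copiotroph_rules.tsv",
                        package = "mimicsLitter", mustWork = TRUE)
  }
  rules <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("rank", "name", "group") %in% names(rules))) {
    stop("rule file needs columns rank, name, group")
  }
  if (!all(rules$rank %in% .RANKS)) {
    stop("ranks must be among: ", paste(.RANKS, collapse = ", "))
  }
  if (!all(rules$group %in% c("copiotroph", "oligotroph"))) {
    stop("groups must be 'copiotroph' or 'oligotroph'")
  }
  key <- paste(rules$rank, rules$name, sep = ":")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    conflict <- vapply(unique(dup), function(k) {
      length(unique(rules$group[key == k])) > 1
    }, logical(1))
    if (any(conflict)) {
      warning("conflicting rules dropped (affected lineages become unassigned): ",
              paste(names(conflict)[conflict], collapse = ", "))
      rules <- rules[!key %in% names(conflict)[conflict], , drop = FALSE]
    } else {
      rules <- rules[!duplicated(key), , drop = FALSE]
    }
  }
  class(rules) <- c("classification_rules", "data.frame")
  rules
}

#' Counts of classification rules by taxonomic rank
#' @param rules A [classificationRules()] table.
#' @return Named integer vector over the five ranks.
#' @export
ruleCountsByRank <- function(rules) {
  vapply(.RANKS, function(r) sum(rules$rank == r), integer(1))
}

.parseLineage <- function(lineage) {
  if (is.na(lineage) || !nzchar(lineage)) return(character())
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts[nzchar(trimws(parts))])
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed lineage: ", lineage)
  ranks <- vapply(kv, `[`, character(1), 1)
  if (!all(ranks %in% .RANKS)) {
    stop("malformed lineage (unknown rank): ", lineage)
  }
  setNames(vapply(kv, `[`, character(1), 2), ranks)
}

#' Classify one lineage as copiotroph, oligotroph or unassigned
#'
#' Rules are matched from genus up to phylum; the matching rule at the finest
#' rank wins. A lineage matching no rule is unassigned.
#'
#' @param lineage Semicolon-delimited `rank:name` string.
#' @param rules A [classificationRules()] table.
#' @return `"copiotroph"`, `"oligotroph"` or `"unassigned"`.
#' @export
classifyTaxa <- function(lineage, rules = classificationRules()) {
  if (length(lineage) > 1) {
    return(vapply(lineage, classifyTaxa, character(1), rules = rules,
                  USE.NAMES = FALSE))
  }
  lv <- .parseLineage(lineage)
  for (rank in rev(.RANKS)) {       # finest first
    if (!rank %in% names(lv)) next
    hit <- rules$group[rules$rank == rank & rules$name == lv[[rank]]]
    if (length(hit) == 1) return(hit)
  }
  "unassigned"
}

#' Rarefy a sample to fixed depth
#'
#' Subsamples reads without replacement to a common depth. Samples with fewer
#' total reads than the depth cannot be rarefied and are the caller's to drop
#' (see [sampleRatios()], which flags and drops them).
#'
#' @param sample_counts Non-negative integer vector of per-taxon counts.
#' @param depth Target depth (default 2447 reads).
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of the same length summing exactly to `depth`.
#' @export
rarefy <- function(sample_counts, depth = 2447, seed = NULL) {
  counts <- as.integer(sample_counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total < depth) {
    stop(sprintf("sample has %d reads, fewer than the rarefaction depth %d",
                 total, depth))
  }
  if (total == depth) return(setNames(counts, names(sample_counts)))
  out <- .withSeed(seed, {
    reads <- rep.int(seq_along(counts), counts)
    keep <- sample(reads, depth, replace = FALSE)
    tabulate(keep, nbins = length(counts))
  })
  setNames(as.integer(out), names(sample_counts))
}

#' Copiotroph:oligotroph ratio of a classified sample
#'
#' @param counts Per-taxon counts of one sample.
#' @param groups Classification per taxon, as from [classifyTaxa()].
#' @return Sum of copiotroph counts over sum of oligotroph counts; unassigned
#'   counts are excluded. Errors if the sample has no oligotroph reads.
#' @export
copiotrophOligotrophRatio <- function(counts, groups) {
  stopifnot(length(counts) == length(groups))
  co <- sum(counts[groups == "copiotroph"])
  ol <- sum(counts[groups == "oligotroph"])
  if (ol == 0) stop("undefined ratio: sample has no oligotroph reads")
  co / ol
}

#' Sensitivity of the ratio to the allocation of unassigned taxa
#'
#' Reallocates the unassigned reads `U` between the two groups: for a
#' copiotroph fraction `f`, the ratio becomes `(C + f U) / (O + (1 - f) U)`.
#'
#' @param counts Per-taxon counts of one sample.
#' @param groups Classification per taxon.
#' @param fractions Copiotroph allocation fractions (default 1.0 down to 0.0
#'   in steps of 0.1).
#' @return data.frame with `fraction` and `ratio`, monotone non-decreasing in
#'   `fraction`.
#' @export
unassignedSensitivity <- function(counts, groups,
                                  fractions = seq(1, 0, by = -0.1)) {
  co <- sum(counts[groups == "copiotroph"])
  ol <- sum(counts[groups == "oligotroph"])
  un <- sum(counts[groups == "unassigned"])
  if (ol == 0 && un == 0) stop("undefined ratio: no oligotroph reads")
  ratio <- (co + fractions * un) / (ol + (1 - fractions) * un)
  data.frame(fraction = fractions, ratio = ratio)
}

#' Per-sample ratios (with rarefaction and sensitivity sweep) for a table
#'
#' The full microbiome stage: rarefies every sample to the common depth
#' (dropping and reporting those below it), classifies each taxon by the
#' finest-rank rule, and returns per-sample copiotroph:oligotroph ratios plus
#' the unassigned-allocation sensitivity sweep.
#'
#' @param asv An `asv_table` from [readAsvTable()] / [asvTable()].
#' @param rules A [classificationRules()] table.
#' @param depth Rarefaction depth.
#' @param seed Integer seed; sample `i` is rarefied under `seed + i`.
#' @return List: `ratios` (data.frame sample/ratio/counts by group),
#'   `sensitivity` (long data.frame), `dropped` (samples below depth),
#'   `flagged` (samples with no oligotroph reads).
#' @export
sampleRatios <- function(asv, rules = classificationRules(), depth = 2447,
                         seed = 1L) {
  groups <- classifyTaxa(asv$lineage, rules)
  samples <- colnames(asv$counts)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(asv$counts)))
  res <- list(); sens <- list(); dropped <- character(); flagged <- character()
  for (i in seq_along(samples)) {
    counts <- asv$counts[, i]
    if (sum(counts) < depth) {
      dropped <- c(dropped, samples[i])
      next
    }
    rc <- rarefy(counts, depth, seed = seed + i)
    co <- sum(rc[groups == "copiotroph"])
    ol <- sum(rc[groups == "oligotroph"])
    un <- sum(rc[groups == "unassigned"])
    if (ol == 0) {
      flagged <- c(flagged, samples[i])
      next
    }
    res[[length(res) + 1L]] <- data.frame(
      sample = samples[i], ratio = co / ol, copiotroph = co, oligotroph = ol,
      unassigned = un, depth = sum(rc))
    sw <- unassignedSensitivity(rc, groups)
    sw$sample <- samples[i]
    sens[[length(sens) + 1L]] <- sw
  }
  list(ratios = if (length(res)) do.call(rbind, res) else NULL,
       sensitivity = if (length(sens)) do.call(rbind, sens) else NULL,
       dropped = dropped, flagged = flagged)
}
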