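#' Pair alignments of one read set against the two parental genomes
#'
#' Groups two alignment tables (the same reads mapped to each parental
#' assembly) by read id. Reads absent or unmapped on one side are treated as
#' unmapped on that side. Only primary alignments are paired; for duplicate
#' primary records of the same (read, mate) on one side, the first is kept.
#'
#' @param aln1,aln2 Alignment tables from \code{\link{read_sam}} for parental
#'   sides 1 and 2.
#' @return A data.frame with one row per (read_id, mate) unit and integer
#'   columns \code{idx1}, \code{idx2} holding row indices into \code{aln1} /
#'   \code{aln2} (\code{NA} when that side is missing or unmapped).
#' @export
pair_alignments <- function(aln1, aln2) {
  side_units <- function(aln) {
    keep <- which(aln$mapped & !aln$secondary)
    if (length(keep)) {
      key <- paste(aln$read_id[keep], aln$mate[keep], sep = "\r")
      keep <- keep[!duplicated(key)]
    }
    keep
  }
  k1 <- side_units(aln1)
  k2 <- side_units(aln2)
  key1 <- paste(aln1$read_id[k1], aln1$mate[k1], sep = "\r")
  key2 <- paste(aln2$read_id[k2], aln2$mate[k2], sep = "\r")
  # unmapped-everywhere reads still form units
  un1 <- which(!aln1$mapped)
  un2 <- which(!aln2$mapped)
  keyu <- unique(c(paste(aln1$read_id[un1], aln1$mate[un1], sep = "\r"),
                   paste(aln2$read_id[un2], aln2$mate[un2], sep = "\r")))
  keys <- unique(c(key1, key2, keyu))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(
    read_id = vapply(parts, `[[`, character(1), 1),
    mate = as.integer(vapply(parts, `[[`, character(1), 2)),
    idx1 = k1[match(keys, key1)],
    idx2 = k2[match(keys, key2)],
    stringsAsFactors = FALSE
  )
}

categorise <- function(log_odds, has1, has2, tie_margin, tie_tol = 1e-9) {
  ifelse(!has1 & !has2, "unmapped_both",
  ifelse(has1 & !has2, "unique_parent1",
  ifelse(!has1 & has2, "unique_parent2",
  ifelse(abs(log_odds) <= tie_margin + tie_tol, "ambiguous",
  ifelse(log_odds > 0, "parent1", "parent2")))))
}

#' Classify one read from its scored alignments on both sides
#'
#' @param side1,side2 Scored alignment rows for this read (possibly several
#'   mates) on parental side 1 / 2; \code{NULL} or an empty data.frame means
#'   unmapped on that side.
#' @param cfg A \code{\link{scoring_config}}; \code{tie_margin} sets the
#'   ambiguity band.
#' @return A one-row data.frame with \code{read_id}, \code{category},
#'   \code{log_odds}, \code{loglik1}, \code{loglik2}. For paired-end input
#'   only mates mapped on both sides contribute to the log-odds.
#' @export
classify_read <- function(side1, side2, cfg = scoring_config()) {
  rows <- function(x) if (is.null(x)) 0L else nrow(x)
  id <- if (rows(side1)) side1$read_id[1] else if (rows(side2))
    side2$read_id[1] else NA_character_
  has1 <- rows(side1) > 0 && any(side1$mapped)
  has2 <- rows(side2) > 0 && any(side2$mapped)
  ll1 <- NA_real_
  ll2 <- NA_real_
  lo <- NA_real_
  if (has1 && has2) {
    m1 <- side1$mate[side1$mapped]
    m2 <- side2$mate[side2$mapped]
    shared <- intersect(m1, m2)
    if (length(shared) == 0) shared <- unique(c(m1, m2)) # degenerate
    ll1 <- sum(side1$loglik[side1$mapped & side1$mate %in% shared])
    ll2 <- sum(side2$loglik[side2$mapped & side2$mate %in% shared])
    lo <- ll1 - ll2
  } else if (has1) {
    ll1 <- sum(side1$loglik[side1$mapped])
  } else if (has2) {
    ll2 <- sum(side2$loglik[side2$mapped])
  }
  data.frame(read_id = id,
             category = categorise(lo, has1, has2, cfg$tie_margin),
             log_odds = lo, loglik1 = ll1, loglik2 = ll2,
             stringsAsFactors = FALSE)
}

#' Classify a WGBS read set between two parental subgenomes
#'
#' The core read-sorting step: every read aligned to both parental
#' assemblies is scored on each side under the bisulfite-aware likelihood
#' (\code{\link{score_alignments}}) and assigned to the side with the higher
#' log-likelihood; placements within \code{tie_margin} of each other are
#' called ambiguous. Reads mapped on exactly one side are reported as
#' \code{unique_parent1}/\code{unique_parent2}, reads mapped on neither as
#' \code{unmapped_both}. For paired-end data the mate log-likelihoods are
#' summed over mates mapped on both sides.
#'
#' @param aln1,aln2 Alignment tables (or SAM file paths) for sides 1 and 2.
#' @param genome1,genome2 The two parental \code{genome_seq} objects.
#' @param cfg A \code{\link{scoring_config}}.
#' @param dedup Remove PCR/optical duplicates per side before scoring
#'   (default \code{TRUE}; see \code{\link{deduplicate_alignments}}).
#' @return An object of class \code{homeo_class}: a list with elements
#'   \code{table} (read_id, category, log_odds, loglik1, loglik2),
#'   \code{summary} (named category counts), \code{labels}, \code{cfg}, and
#'   the deduplicated scored alignment tables \code{aln1}, \code{aln2}.
#' @examples
#' sim <- simulate_reads(sim_config(genome_length = 2000, n_reads = 50,
#'                                  seed = 1))
#' cls <- classify_reads(sim$sam1, sim$sam2, sim$genome1, sim$genome2)
#' summary(cls)
#' @export
classify_reads <- function(aln1, aln2, genome1, genome2,
                           cfg = scoring_config(), dedup = TRUE) {
  if (is.character(aln1)) aln1 <- read_sam(aln1, genome1)
  if (is.character(aln2)) aln2 <- read_sam(aln2, genome2)
  if (dedup) {
    aln1 <- deduplicate_alignments(aln1)
    aln2 <- deduplicate_alignments(aln2)
  }
  aln1 <- score_alignments(aln1, genome1, cfg)
  aln2 <- score_alignments(aln2, genome2, cfg)
  units <- pair_alignments(aln1, aln2)
  if (nrow(units) == 0) {
    tab <- data.frame(read_id = character(0), category = character(0),
                      log_odds = numeric(0), loglik1 = numeric(0),
                      loglik2 = numeric(0), stringsAsFactors = FALSE)
  } else {
    # collapse mates to one classification unit per read_id
    ll1 <- ifelse(is.na(units$idx1), NA_real_, aln1$loglik[units$idx1])
    ll2 <- ifelse(is.na(units$idx2), NA_real_, aln2$loglik[units$idx2])
    both <- !is.na(units$idx1) & !is.na(units$idx2)
    agg <- function(v, keep) {
      x <- tapply(ifelse(keep, v, NA_real_), units$read_id, function(z) {
        if (all(is.na(z))) NA_real_ else sum(z, na.rm = TRUE)
      })
      as.numeric(x)
    }
    ids <- sort(unique(units$read_id))
    # per read: does any mate map on side 1 / side 2?
    any1 <- as.logical(tapply(!is.na(units$idx1), units$read_id, any))
    any2 <- as.logical(tapply(!is.na(units$idx2), units$read_id, any))
    # log-odds from mates mapped on both sides only
    s1 <- agg(ll1, both)
    s2 <- agg(ll2, both)
    # fall back to single-side sums for unique reads
    s1_all <- agg(ll1, !is.na(units$idx1))
    s2_all <- agg(ll2, !is.na(units$idx2))
    loglik1 <- ifelse(any1 & any2, s1, s1_all)
    loglik2 <- ifelse(any1 & any2, s2, s2_all)
    lo <- ifelse(any1 & any2, s1 - s2, NA_real_)
    # reads mapped on both sides but with no mate shared across sides:
    # no comparable evidence, call ambiguous
    lo[any1 & any2 & is.na(lo)] <- 0
    tab <- data.frame(read_id = ids,
                      category = categorise(lo, any1, any2, cfg$tie_margin),
                      log_odds = lo, loglik1 = loglik1, loglik2 = loglik2,
                      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
  }
  cats <- c("parent1", "parent2", "ambiguous", "unique_parent1",
            "unique_parent2", "unmapped_both")
  counts <- vapply(cats, function(cc) sum(tab$category == cc), integer(1))
  structure(list(table = tab, summary = counts,
                 labels = c(genome1$label, genome2$label), cfg = cfg,
                 aln1 = aln1, aln2 = aln2),
            class = "homeo_class")
}

#' @export
print.homeo_class <- function(x, ...) {
  cat("Subgenome read classification (", x$labels[1], " vs ", x$labels[2],
      ")\n", sep = "")
  cat("  reads classified:", nrow(x$table), "\n")
  for (nm in names(x$summary)) {
    cat(sprintf("  %-15s %d\n", nm, x$summary[[nm]]))
  }
  invisible(x)
}

#' Summarise a subgenome read classification
#'
#' @param object A \code{homeo_class} object.
#' @param ... Unused.
#' @return data.frame with category counts and fractions.
#' @method summary homeo_class
#' @export
summary.homeo_class <- function(object, ...) {
  n <- nrow(object$table)
  data.frame(category = names(object$summary),
             n = as.integer(object$summary),
             fraction = if (n > 0) as.integer(object$summary) / n else
               rep(NA_real_, length(object$summary)),
             stringsAsFactors = FALSE)
}

#' Write classification outputs to a directory
#'
#' Writes \code{classification.tsv} (one row per read),
#' \code{summary.tsv} (category counts), and per-(side, category) SAM files.
#'
#' @param cls A \code{homeo_class} object.
#' @param out_dir Output directory.
#' @return Character vector of the files written, invisibly.
#' @export
write_classification <- function(cls, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(out_dir, "classification.tsv")
  utils::write.table(cls$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  smp <- file.path(out_dir, "summary.tsv")
  utils::write.table(summary(cls), smp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p1 <- write_classified_sam(cls$aln1, cls$table, out_dir, prefix = "side1")
  p2 <- write_classified_sam(cls$aln2, cls$table, out_dir, prefix = "side2")
  invisible(c(tsv, smp, p1, p2))
}
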