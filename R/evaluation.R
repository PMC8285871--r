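#' Score a classification against known read origins
#'
#' Benchmark harness for the progenitor-as-allopolyploid design: reads whose
#' true parental origin is known are classified as if they were allopolyploid
#' reads, and the error rate is the number of reads assigned to the wrong
#' genome divided by the total number of uniquely mapped, deduplicated reads.
#' Ambiguous reads sit in the denominator but are never counted as wrong;
#' reads unique to one side count as assigned to that side.
#'
#' @param cls A \code{homeo_class} object or its \code{table} data.frame.
#' @param truth data.frame with columns \code{read_id} and \code{true_label}
#'   (values \code{"parent1"}/\code{"parent2"}), or a named character vector.
#' @param denominator \code{"unique_dedup"} (default: every classified read
#'   unit with at least one mapped side) or \code{"assigned"} (only reads
#'   assigned to a side).
#' @return List with \code{n_unique_dedup}, \code{n_correct}, \code{n_wrong},
#'   \code{n_ambiguous}, \code{error_rate}.
#' @export
evaluate_classification <- function(cls, truth,
                                    denominator = c("unique_dedup",
                                                    "assigned")) {
  denominator <- match.arg(denominator)
  tab <- if (inherits(cls, "homeo_class")) cls$table else cls
  if (is.data.frame(truth)) {
    tl <- truth$true_label
    names(tl) <- truth$read_id
    truth <- tl
  }
  tab <- tab[tab$category != "unmapped_both", , drop = FALSE]
  if (!all(tab$read_id %in% names(truth))) {
    stop("truth table is missing ",
         sum(!tab$read_id %in% names(truth)), " classified read id(s)")
  }
  tt <- truth[tab$read_id]
  assigned <- c(parent1 = "parent1", parent2 = "parent2",
                unique_parent1 = "parent1", unique_parent2 = "parent2",
                ambiguous = NA_character_)[tab$category]
  n_amb <- sum(is.na(assigned))
  n_correct <- sum(!is.na(assigned) & assigned == tt)
  n_wrong <- sum(!is.na(assigned) & assigned != tt)
  n_total <- nrow(tab)
  denom <- if (denominator == "unique_dedup") n_total else n_correct + n_wrong
  list(n_unique_dedup = n_total, n_correct = n_correct, n_wrong = n_wrong,
       n_ambiguous = n_amb,
       error_rate = if (denom > 0) n_wrong / denom else NA_real_)
}

#' Assign reads by the genome-concatenation baseline
#'
#' Emulates the standard approach of aligning against the two parental
#' assemblies concatenated into one reference: all candidate placements of a
#' read across both genomes (including secondary alignments) compete, and the
#' read is taken as uniquely mapped only when the best score strictly exceeds
#' every other candidate's (tolerance 1e-9). Ties are \code{not_unique} and
#' are excluded from the baseline's denominator, mirroring unique-mapping
#' filters. Candidates are scored with the same bisulfite-aware likelihood as
#' the classifier, which isolates the comparison from aligner idiosyncrasies.
#'
#' @param scored1,scored2 Scored alignment tables (all candidates, secondary
#'   included) against genomes 1 and 2; see \code{\link{score_alignments}}.
#' @param labels Length-2 character vector naming the two genomes.
#' @return data.frame with columns \code{read_id} and \code{assigned}
#'   (\code{labels[1]}, \code{labels[2]} or \code{"not_unique"}).
#' @export
concatenated_baseline <- function(scored1, scored2,
                                  labels = c("parent1", "parent2")) {
  cand <- rbind(
    data.frame(read_id = scored1$read_id, mate = scored1$mate,
               side = labels[1], loglik = scored1$loglik,
               mapped = scored1$mapped, secondary = scored1$secondary,
               stringsAsFactors = FALSE),
    data.frame(read_id = scored2$read_id, mate = scored2$mate,
               side = labels[2], loglik = scored2$loglik,
               mapped = scored2$mapped, secondary = scored2$secondary,
               stringsAsFactors = FALSE)
  )
  cand <- cand[cand$mapped & !is.na(cand$loglik), , drop = FALSE]
  ids <- unique(c(scored1$read_id, scored2$read_id))
  if (nrow(cand) == 0) {
    return(data.frame(read_id = ids,
                      assigned = rep("not_unique", length(ids)),
                      stringsAsFactors = FALSE))
  }
  # one candidate per (read, side): the mate-summed primary placement;
  # each secondary placement competes as its own candidate
  key <- paste(cand$read_id, cand$side, sep = "\r")
  primary_sum <- tapply(cand$loglik[!cand$secondary],
                        key[!cand$secondary], sum)
  cand_scores <- c(as.numeric(primary_sum),
                   cand$loglik[cand$secondary])
  cand_key <- c(names(primary_sum), key[cand$secondary])
  kparts <- strsplit(cand_key, "\r", fixed = TRUE)
  kread <- vapply(kparts, `[[`, character(1), 1)
  kside <- vapply(kparts, `[[`, character(1), 2)
  by_read <- split(seq_along(cand_scores), kread)
  assigned <- vapply(ids, function(id) {
    sel <- by_read[[id]]
    if (is.null(sel)) return("not_unique")
    sc <- cand_scores[sel]
    best <- which.max(sc)
    if (sum(sc >= sc[best] - 1e-9) > 1) "not_unique" else kside[sel][best]
  }, character(1))
  data.frame(read_id = ids, assigned = unname(assigned),
             stringsAsFactors = FALSE)
}

baseline_eval <- function(baseline, truth, labels = c("parent1", "parent2")) {
  if (is.data.frame(truth)) {
    tl <- truth$true_label
    names(tl) <- truth$read_id
    truth <- tl
  }
  uniq <- baseline[baseline$assigned != "not_unique", , drop = FALSE]
  tt <- truth[uniq$read_id]
  n_wrong <- sum(uniq$assigned != tt)
  list(n_unique = nrow(uniq), n_correct = sum(uniq$assigned == tt),
       n_wrong = n_wrong,
       error_rate = if (nrow(uniq) > 0) n_wrong / nrow(uniq) else NA_real_)
}

#' Compare read classification against the concatenated-genome baseline
#'
#' Runs both subgenome-assignment strategies on one truth-labelled fixture
#' (typically from \code{\link{simulate_reads}}) and reports, per method, the
#' number of reads in the denominator, correct / wrong / ambiguous counts,
#' the error rate, and the baseline-to-classifier error-rate ratio.
#'
#' @param sim A simulation fixture from \code{\link{simulate_reads}}, or a
#'   list with elements \code{sam1}, \code{sam2}, \code{genome1},
#'   \code{genome2}, \code{truth}.
#' @param cfg A \code{\link{scoring_config}}.
#' @return List with elements \code{table} (one row per method) and
#'   \code{error_ratio} (baseline error rate / classifier error rate).
#' @export
compare_methods <- function(sim, cfg = scoring_config()) {
  cls <- classify_reads(sim$sam1, sim$sam2, sim$genome1, sim$genome2, cfg)
  ev_cls <- evaluate_classification(cls, sim$truth)
  labels <- c("parent1", "parent2")
  bl <- concatenated_baseline(cls$aln1, cls$aln2, labels)
  ev_bl <- baseline_eval(bl, sim$truth, labels)
  tab <- data.frame(
    method = c("classification", "concatenated"),
    n_unique = c(ev_cls$n_unique_dedup, ev_bl$n_unique),
    n_correct = c(ev_cls$n_correct, ev_bl$n_correct),
    n_wrong = c(ev_cls$n_wrong, ev_bl$n_wrong),
    n_ambiguous = c(ev_cls$n_ambiguous, NA_integer_),
    error_rate = c(ev_cls$error_rate, ev_bl$error_rate),
    stringsAsFactors = FALSE
  )
  ratio <- if (!is.na(ev_cls$error_rate) && ev_cls$error_rate > 0) {
    ev_bl$error_rate / ev_cls$error_rate
  } else {
    NA_real_
  }
  list(table = tab, error_ratio = ratio, classification = cls)
}
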