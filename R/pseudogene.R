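## Putative-pseudogene classification: sequence-intrinsic motif and
## structure evidence calls a putative pseudogene outright; cohort-relative
## GC and length anomalies alone only raise suspicion.

#' Classify a record as functional / suspect / putative pseudogene
#'
#' `putative_pseudogene` when any 5.8S motif carries at least one mismatch,
#' or the ITS2 four-helix topology fails, or any 5.8S helix constraint
#' fails. Otherwise `suspect` when the total-region GC z-score against the
#' functional cohort falls below `gc_z_floor`, or the ITS1 length lies
#' outside the cohort min/max by more than `len_slack` nt. Otherwise
#' `functional`. Every trigger is recorded as evidence.
#'
#' @param comp One-row data.frame from [composition_report()].
#' @param motifs Named list of `motif_report` from [scan_58s_motifs()].
#' @param struct A [structure_report()].
#' @param cohort data.frame of composition reports for the
#'   functional-candidate cohort (required unless `use_gc_rule = FALSE`).
#' @param gc_z_floor GC z-score floor (default -2).
#' @param len_slack ITS1-length slack in nt (default 5).
#' @param use_gc_rule Disable the cohort-relative rules entirely.
#' @return List of class `pseudogene_verdict`: `id`, `status`, `evidence`
#'   (character vector of tagged findings), `parameters`.
#' @export
classify_its <- function(comp, motifs, struct, cohort = NULL,
                         gc_z_floor = -2, len_slack = 5, use_gc_rule = TRUE) {
  evidence <- character(0)
  for (m in names(motifs)) {
    if (motifs[[m]]$n_mismatches > 0L || motifs[[m]]$indel_flag)
      evidence <- c(evidence, sprintf(
        "motif_disruption(%s@%s)", m,
        paste(motifs[[m]]$mismatch_positions, collapse = ",")))
  }
  if (!struct$overall_its2_ok)
    evidence <- c(evidence, sprintf("its2_fold_fail(n_helices=%d,tggt=%s)",
                                    struct$its2_n_helices, struct$tggt_in_helix3))
  if (!struct$overall_58s_ok)
    evidence <- c(evidence, sprintf(
      "r58s_constraint_fail(%s)",
      paste(names(struct$r58s_constraints)[!struct$r58s_constraints], collapse = ",")))
  status <- if (length(evidence)) "putative_pseudogene" else "functional"
  if (status == "functional" && use_gc_rule) {
    if (is.null(cohort) || nrow(cohort) < 2L)
      stop("GC/length rules need a cohort of >= 2 functional reports; ",
           "supply 'cohort' or set use_gc_rule = FALSE")
    z <- (comp$total_gc - mean(cohort$total_gc)) / stats::sd(cohort$total_gc)
    if (is.finite(z) && z < gc_z_floor) {
      evidence <- c(evidence, sprintf("low_gc(z=%.2f)", z))
      status <- "suspect"
    }
    if (comp$its1_len < min(cohort$its1_len) - len_slack ||
        comp$its1_len > max(cohort$its1_len) + len_slack) {
      evidence <- c(evidence, sprintf("length_anomaly(its1=%d)", comp$its1_len))
      status <- "suspect"
    }
  }
  structure(list(id = comp$id, status = status, evidence = evidence,
                 parameters = list(gc_z_floor = gc_z_floor,
                                   len_slack = len_slack,
                                   use_gc_rule = use_gc_rule)),
            class = "pseudogene_verdict")
}

#' @export
print.pseudogene_verdict <- function(x, ...) {
  cat(sprintf("<pseudogene_verdict> %s: %s%s\n", x$id, x$status,
              if (length(x$evidence))
                paste0(" [", paste(x$evidence, collapse = "; "), "]") else ""))
  invisible(x)
}

#' Excess of CpG-deamination transitions against a functional template
#'
#' Counts aligned columns where the template holds the C of a CpG
#' dinucleotide (or the G preceded by C) and the query shows the
#' deamination transition (C->T, respectively G->A). The flag is raised
#' when such transitions make up more than half of all substitutions and
#' number at least `min_count`.
#'
#' @param seq,template Aligned rows of equal (gapped) length; `template`
#'   is the designated functional reference.
#' @param min_count Minimum transition count for the flag (default 3).
#' @return List: `count`, `n_substitutions`, `flag`.
#' @export
cpg_transition_excess <- function(seq, template, min_count = 3L) {
  cs <- strsplit(toupper(seq), "")[[1]]
  ct <- strsplit(toupper(template), "")[[1]]
  if (length(cs) != length(ct))
    stop("sequence and template must be aligned to the same length")
  acgt <- c("A", "C", "G", "T")
  cmp <- ct %in% acgt & cs %in% acgt
  subs <- which(cmp & ct != cs)
  # CpG context in the template, skipping gap columns
  tpos <- which(ct != "-")
  tchain <- ct[tpos]
  is_c_of_cg <- is_g_of_cg <- rep(FALSE, length(ct))
  if (length(tchain) > 1L) {
    cg <- tchain[-length(tchain)] == "C" & tchain[-1L] == "G"
    is_c_of_cg[tpos[c(cg, FALSE)]] <- TRUE
    is_g_of_cg[tpos[c(FALSE, cg)]] <- TRUE
  }
  deam <- subs[(is_c_of_cg[subs] & cs[subs] == "T") |
                 (is_g_of_cg[subs] & cs[subs] == "A")]
  count <- length(deam)
  n_sub <- length(subs)
  list(count = count, n_substitutions = n_sub,
       flag = n_sub > 0L && count / n_sub > 0.5 && count >= min_count)
}

#' Classify a whole set of records
#'
#' Runs delimitation, composition, motif scan and structure checks on
#' every record, then classifies each against the cohort of records whose
#' intrinsic (motif/structure) checks pass.
#'
#' @param records List of [its_record()].
#' @param ref Optional [annotated_reference()].
#' @param ... Passed to [classify_its()].
#' @return data.frame with columns `id`, `status`, `evidence`.
#' @export
classify_set <- function(records, ref = NULL, ...) {
  records <- as_record_list(records)
  if (is.null(ref)) {
    sr <- synthetic_reference()
    ref <- annotated_reference(sr$record, sr$annotation)
  }
  per <- lapply(records, function(r) {
    d <- delimit_its(r, ref)
    list(record = r,
         comp = composition_report(r, d$annotation),
         motifs = scan_58s_motifs(region_seq(r, d$annotation, "r58s")),
         struct = structure_report(r, d$annotation))
  })
  intrinsic_ok <- vapply(per, function(x) {
    x$struct$overall_its2_ok && x$struct$overall_58s_ok &&
      all(vapply(x$motifs, function(m) m$n_mismatches == 0L, logical(1)))
  }, logical(1))
  cohort <- do.call(rbind, lapply(per[intrinsic_ok], `[[`, "comp"))
  use_gc <- !is.null(cohort) && nrow(cohort) >= 2L
  verdicts <- lapply(per, function(x)
    classify_its(x$comp, x$motifs, x$struct, cohort = cohort,
                 use_gc_rule = use_gc, ...))
  data.frame(id = vapply(verdicts, `[[`, character(1), "id"),
             status = vapply(verdicts, `[[`, character(1), "status"),
             evidence = vapply(verdicts, function(v)
               paste(v$evidence, collapse = "; "), character(1)),
             stringsAsFactors = FALSE)
}
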