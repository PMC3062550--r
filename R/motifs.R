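## Conserved 5.8S motif scanning.

#' Scan a 5.8S sequence for one conserved motif
#'
#' The motif is slid ungapped along the sequence and the offset minimising
#' the Hamming distance to the canonical motif is reported (ties broken by
#' the left-most offset; `N` counts as a mismatch). When the best ungapped
#' match still exceeds `indel_ceiling` mismatches and a gapped local
#' alignment finds a better match containing a gap, `indel_flag` is set.
#'
#' @param r58s_seq 5.8S region sequence.
#' @param motif Motif name (`"M1"`, `"M2"`, `"M3"`) or a custom DNA string.
#' @param indel_ceiling Mismatch ceiling above which the gapped check runs
#'   (default 4).
#' @return List of class `motif_report`: `motif`, `canonical`,
#'   `best_start` (1-based offset in the 5.8S), `n_mismatches`,
#'   `mismatch_positions` (1-based within the motif, ascending),
#'   `mismatch_bases`, `indel_flag`.
#' @export
scan_motif <- function(r58s_seq, motif, indel_ceiling = 4L) {
  canon <- if (motif %in% names(its_motifs())) its_motifs()[[motif]] else toupper(motif)
  name <- if (motif %in% names(its_motifs())) motif else "custom"
  s <- toupper(r58s_seq)
  m <- nchar(canon)
  n <- nchar(s)
  if (n < m) stop("5.8S region shorter than motif ", name)
  sc <- strsplit(s, "")[[1]]
  mc <- strsplit(canon, "")[[1]]
  n_off <- n - m + 1L
  dist <- integer(n_off)
  for (t in seq_len(m)) {
    obs <- sc[seq.int(t, t + n_off - 1L)]
    dist <- dist + as.integer(obs != mc[t] | obs == "N")
  }
  best <- which.min(dist)  # leftmost among ties
  obs <- sc[best:(best + m - 1L)]
  mism <- which(obs != mc | obs == "N")
  indel_flag <- FALSE
  if (dist[best] > indel_ceiling) {
    # global in the motif, local in the 5.8S: the whole motif must align,
    # so a true indel shows up as a gap instead of being clipped away
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(canon),
      subject = Biostrings::DNAString(gsub("N", "A", s)),
      type = "global-local", substitutionMatrix = delimit_submat(),
      gapOpening = 2, gapExtension = 1)
    gapped_cols <- Biostrings::nindel(aln)
    has_gap <- sum(gapped_cols@insertion[, "WidthSum"]) +
      sum(gapped_cols@deletion[, "WidthSum"]) > 0
    mismatches_gapped <- Biostrings::nmismatch(aln)
    if (has_gap && mismatches_gapped < dist[best]) indel_flag <- TRUE
  }
  structure(list(motif = name, canonical = canon,
                 best_start = as.integer(best),
                 n_mismatches = as.integer(dist[best]),
                 mismatch_positions = as.integer(mism),
                 mismatch_bases = obs[mism],
                 indel_flag = indel_flag),
            class = "motif_report")
}

#' @export
print.motif_report <- function(x, ...) {
  cat(sprintf("<motif_report> %s @ %d: %d mismatch(es)%s%s\n",
              x$motif, x$best_start, x$n_mismatches,
              if (length(x$mismatch_positions))
                paste0(" at ", paste(x$mismatch_positions, collapse = ",")) else "",
              if (x$indel_flag) " [indel suspected]" else ""))
  invisible(x)
}

#' Scan a 5.8S sequence for all three conserved motifs
#'
#' @param r58s_seq 5.8S region sequence.
#' @param indel_ceiling See [scan_motif()].
#' @return Named list of `motif_report` for M1, M2, M3.
#' @export
scan_58s_motifs <- function(r58s_seq, indel_ceiling = 4L) {
  reps <- lapply(names(its_motifs()), function(m)
    scan_motif(r58s_seq, m, indel_ceiling))
  names(reps) <- names(its_motifs())
  reps
}

# Flatten motif reports to a table (one row per motif).
motif_reports_table <- function(reports, id = NA_character_) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(id = id, motif = r$motif, start = r$best_start,
               n_mismatches = r$n_mismatches,
               positions = paste(r$mismatch_positions, collapse = ","),
               indel_flag = r$indel_flag, stringsAsFactors = FALSE)))
}
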