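## Sub-region delimitation by pairwise alignment to an annotated reference.

# Substitution matrix over A/C/G/T/N: match +1, mismatch -1, N never a match.
delimit_submat <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", ] <- -1
  m[, "N"] <- -1
  m
}

#' Construct an annotated reference
#'
#' @param record An [its_record()].
#' @param annotation A [region_annotation()] valid for `record`.
#' @return Object of class `annotated_reference`.
#' @export
annotated_reference <- function(record, annotation) {
  if (!inherits(record, "its_record")) stop("'record' must be an its_record")
  if (!inherits(annotation, "region_annotation"))
    stop("'annotation' must be a region_annotation")
  if (annotation$its2[2] > nchar(record$sequence))
    stop("annotation exceeds reference length")
  structure(list(record = record, annotation = annotation),
            class = "annotated_reference")
}

#' Delimit ITS1, 5.8S and ITS2 in a record
#'
#' Aligns the annotated reference against the record (global in the
#' reference, local in the record, so extra flanking sequence on the record
#' is ignored; affine gaps, match +1 / mismatch -1 / gap open 4 / extend 1)
#' and maps the reference region boundaries onto record coordinates.
#' Boundary columns falling in record gaps are resolved toward the
#' conserved 5.8S; the inner boundaries `its1.end` and `its2.start` are
#' derived from the mapped 5.8S interval so the annotation is always
#' contiguous and ordered.
#'
#' @param record An [its_record()], at least 300 nt.
#' @param ref An `annotated_reference`; default [synthetic_reference()].
#' @param min_58s_identity Reliability floor: fraction identity over the
#'   aligned 5.8S region below which delimitation is refused (default 0.6).
#' @return List of class `delimitation` with `annotation`
#'   ([region_annotation()]), `score` (alignment score) and
#'   `identity_58s` (fraction).
#' @export
delimit_its <- function(record, ref = NULL, min_58s_identity = 0.6) {
  if (!inherits(record, "its_record")) stop("'record' must be an its_record")
  if (nchar(record$sequence) < 300L)
    stop("record '", record$id, "' shorter than 300 nt; not a full ITS amplicon")
  if (is.null(ref)) {
    sr <- synthetic_reference()
    ref <- annotated_reference(sr$record, sr$annotation)
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ref$record$sequence),
    subject = Biostrings::DNAString(record$sequence),
    type = "global-local",
    substitutionMatrix = delimit_submat(),
    gapOpening = 4, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sub_off <- Biostrings::start(Biostrings::subject(aln)) - 1L
  n_col <- length(pat)
  ref_pos <- cumsum(pat != "-")          # reference coordinate per column
  rec_pos <- cumsum(sub != "-") + sub_off  # record coordinate per column
  rec_gap <- sub == "-"

  an <- ref$annotation
  # identity over the reference 5.8S columns
  cols_58s <- which(ref_pos >= an$r58s[1] & ref_pos <= an$r58s[2] & pat != "-")
  id58 <- sum(pat[cols_58s] == sub[cols_58s] & pat[cols_58s] %in% c("A", "C", "G", "T")) /
    (an$r58s[2] - an$r58s[1] + 1L)
  if (id58 < min_58s_identity)
    stop(sprintf("delimitation unreliable for '%s': 5.8S identity %.3f below floor %.3f",
                 record$id, id58, min_58s_identity))

  # map a reference boundary to a record position; direction = +1 resolves
  # a gap rightward (toward the 5.8S for upstream boundaries), -1 leftward.
  map_boundary <- function(ref_b, direction) {
    col <- which(ref_pos == ref_b & pat != "-")[1]
    if (is.na(col)) stop("reference boundary outside alignment")
    while (col >= 1L && col <= n_col && rec_gap[col]) col <- col + direction
    if (col < 1L || col > n_col)
      stop("boundary maps outside record for '", record$id, "'")
    rec_pos[col]
  }
  r58_s <- map_boundary(an$r58s[1], +1L)
  r58_e <- map_boundary(an$r58s[2], -1L)
  its1_s <- min(map_boundary(an$its1[1], +1L), r58_s - 2L)
  its2_e <- max(map_boundary(an$its2[2], -1L), r58_e + 2L)
  annotation <- region_annotation(
    its1 = c(its1_s, r58_s - 1L),
    r58s = c(r58_s, r58_e),
    its2 = c(r58_e + 1L, its2_e),
    seq_length = nchar(record$sequence))
  structure(list(id = record$id, annotation = annotation,
                 score = Biostrings::score(aln), identity_58s = id58),
            class = "delimitation")
}

#' @export
print.delimitation <- function(x, ...) {
  cat(sprintf("<delimitation> %s (score %.1f, 5.8S identity %.3f)\n",
              x$id, x$score, x$identity_58s))
  print(x$annotation)
  invisible(x)
}

#' Delimit a set of records into a regions table
#'
#' @param records List of [its_record()].
#' @param ref,min_58s_identity See [delimit_its()].
#' @return data.frame with columns `id`, `its1_start`, `its1_end`,
#'   `r58s_start`, `r58s_end`, `its2_start`, `its2_end`, `score`.
#' @export
delimit_set <- function(records, ref = NULL, min_58s_identity = 0.6) {
  records <- as_record_list(records)
  if (is.null(ref)) {
    sr <- synthetic_reference()
    ref <- annotated_reference(sr$record, sr$annotation)
  }
  rows <- lapply(records, function(r) {
    d <- delimit_its(r, ref, min_58s_identity)
    a <- d$annotation
    data.frame(id = r$id,
               its1_start = a$its1[1], its1_end = a$its1[2],
               r58s_start = a$r58s[1], r58s_end = a$r58s[2],
               its2_start = a$its2[1], its2_end = a$its2[2],
               score = d$score, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

regions_row_to_annotation <- function(row) {
  region_annotation(c(row$its1_start, row$its1_end),
                    c(row$r58s_start, row$r58s_end),
                    c(row$its2_start, row$its2_end))
}
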