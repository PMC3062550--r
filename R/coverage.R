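## Read placement and per-position read-depth profiling along an ITS
## contig.

#' Place reads on a contig by best local alignment
#'
#' Each read is aligned locally to the contig on both strands (match +1 /
#' mismatch -1 / gap open 4 / extend 1) and placed at its best window when
#' the alignment identity reaches `min_identity` percent over at least
#' `min_len` aligned columns. Unplaced reads are listed.
#'
#' @param reads List of [its_record()].
#' @param contig An [its_record()] of length >= `min_len`.
#' @param min_identity Percent identity floor (default 90).
#' @param min_len Minimum aligned length in nt (default 50).
#' @return List of class `read_placements`: `placements` (data.frame
#'   `read`, `start`, `end`, `strand`, `identity`), `unplaced`
#'   (character), `contig_id`, `contig_length`.
#' @export
place_reads <- function(reads, contig, min_identity = 90, min_len = 50L) {
  if (!inherits(contig, "its_record")) stop("'contig' must be an its_record")
  if (nchar(contig$sequence) < min_len) stop("contig shorter than min_len")
  reads <- if (length(reads)) as_record_list(reads) else list()
  ctg <- Biostrings::DNAString(gsub("N", "A", contig$sequence))
  rows <- list(); unplaced <- character(0)
  for (rd in reads) {
    best <- NULL
    for (strand in c("+", "-")) {
      qs <- rd$sequence
      if (strand == "-")
        qs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(qs)))
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(gsub("N", "A", qs)), subject = ctg,
        type = "local", substitutionMatrix = delimit_submat(),
        gapOpening = 4, gapExtension = 1)
      if (is.null(best) || Biostrings::score(aln) > best$score)
        best <- list(aln = aln, strand = strand, score = Biostrings::score(aln))
    }
    aln <- best$aln
    ncol_aln <- nchar(as.character(Biostrings::alignedPattern(aln)))
    identity <- 100 * Biostrings::nmatch(aln) / ncol_aln
    s <- Biostrings::start(Biostrings::subject(aln))
    e <- Biostrings::end(Biostrings::subject(aln))
    if (identity >= min_identity && (e - s + 1L) >= min_len) {
      rows[[length(rows) + 1L]] <- data.frame(
        read = rd$id, start = s, end = e, strand = best$strand,
        identity = identity, stringsAsFactors = FALSE)
    } else {
      unplaced <- c(unplaced, rd$id)
    }
  }
  placements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read = character(0), start = integer(0), end = integer(0),
               strand = character(0), identity = numeric(0))
  structure(list(placements = placements, unplaced = unplaced,
                 contig_id = contig$id,
                 contig_length = nchar(contig$sequence)),
            class = "read_placements")
}

#' @export
print.read_placements <- function(x, ...) {
  cat(sprintf("<read_placements> %s: %d placed, %d unplaced\n",
              x$contig_id, nrow(x$placements), length(x$unplaced)))
  invisible(x)
}

#' Per-position read-depth profile
#'
#' @param placements A `read_placements` object, or a data.frame with
#'   `start`/`end` columns (then `contig_length` is required).
#' @param contig_length Contig length (taken from `placements` when it is
#'   a `read_placements`).
#' @return List of class `read_depth_profile`: `depth` (integer vector),
#'   `mean_rd`, `contig_id`, `contig_length`.
#' @export
depth_profile <- function(placements, contig_length = NULL) {
  contig_id <- NA_character_
  if (inherits(placements, "read_placements")) {
    contig_length <- placements$contig_length
    contig_id <- placements$contig_id
    placements <- placements$placements
  }
  if (is.null(contig_length)) stop("contig_length required")
  if (nrow(placements) &&
      (any(placements$start < 1L) || any(placements$end > contig_length) ||
       any(placements$start > placements$end)))
    stop("placement out of contig bounds")
  depth <- integer(contig_length)
  for (r in seq_len(nrow(placements))) {
    rg <- placements$start[r]:placements$end[r]
    depth[rg] <- depth[rg] + 1L
  }
  structure(list(depth = depth, mean_rd = sum(depth) / contig_length,
                 contig_id = contig_id, contig_length = contig_length),
            class = "read_depth_profile")
}

#' @export
print.read_depth_profile <- function(x, ...) {
  cat(sprintf("<read_depth_profile> %s: %d positions, mean RD %.2f\n",
              x$contig_id, x$contig_length, x$mean_rd))
  invisible(x)
}
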