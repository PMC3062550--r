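## Per-region composition statistics, identity matrices, nucleotide
## diversity.

#' GC content of a DNA string
#'
#' Computed over A/C/G/T only: `N` and gaps are excluded from both the
#' numerator and the denominator.
#'
#' @param seq DNA string (may be gapped).
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n_acgt <- sum(ch %in% c("A", "C", "G", "T"))
  if (n_acgt == 0L) stop("GC content undefined: no unambiguous bases")
  sum(ch %in% c("C", "G")) / n_acgt
}

#' Percent identity of two aligned rows
#'
#' Columns with `N` in either row, and gap-vs-gap columns, are excluded
#' from the comparison; gap-vs-base columns count as mismatches. The exact
#' fraction is returned; rounding to two decimals is presentation only.
#'
#' @param a,b Equal-length gapped rows.
#' @return Percent in `[0, 100]`.
#' @export
percent_identity <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("rows must have equal (aligned) length")
  keep <- !(ca == "N" | cb == "N") & !(ca == "-" & cb == "-")
  n_cmp <- sum(keep)
  if (n_cmp == 0L) stop("percent identity undefined: zero compared columns")
  100 * sum(ca[keep] == cb[keep]) / n_cmp
}

# Pairwise differences / compared sites with pairwise deletion of columns
# holding a gap or N in either row (the p-distance convention; note this
# differs from percent_identity, which scores gap-vs-base as a mismatch).
pairwise_p <- function(ca, cb) {
  keep <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  n <- sum(keep)
  if (n == 0L) return(c(p = NA_real_, n = 0))
  c(p = sum(ca[keep] != cb[keep]) / n, n = n)
}

#' Nucleotide diversity (pi) of an alignment
#'
#' Average over all unordered pairs of (pairwise differences / pairwise
#' compared sites), with pairwise deletion of gap/N columns.
#'
#' @param msa An [msa_block()] with at least two rows.
#' @return List of class `diversity_estimate`: `pi`, `n_sequences`,
#'   `n_sites` (alignment columns).
#' @export
nucleotide_diversity <- function(msa) {
  if (!inherits(msa, "msa_block")) stop("'msa' must be an msa_block")
  n <- length(msa$labels)
  if (n < 2L) stop("nucleotide diversity needs at least 2 sequences")
  ps <- c()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pr <- pairwise_p(msa$mat[i, ], msa$mat[j, ])
      if (pr[["n"]] == 0)
        stop("no compared sites for pair ", msa$labels[i], " / ", msa$labels[j])
      ps <- c(ps, pr[["p"]])
    }
  }
  structure(list(pi = mean(ps), n_sequences = n, n_sites = msa$n_col),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("<diversity_estimate> pi = %.5f (%d sequences, %d sites)\n",
              x$pi, x$n_sequences, x$n_sites))
  invisible(x)
}

#' Per-region composition report for one record
#'
#' @param record An [its_record()].
#' @param annotation A [region_annotation()] for the record.
#' @return One-row data.frame with length and GC per region
#'   (ITS1, 5.8S, ITS2 and total = `its1 start .. its2 end`).
#' @export
composition_report <- function(record, annotation) {
  reg <- function(region) region_seq(record, annotation, region)
  lens <- vapply(c("its1", "r58s", "its2", "total"), function(r) nchar(reg(r)), numeric(1))
  gcs <- vapply(c("its1", "r58s", "its2", "total"), function(r) gc_content(reg(r)), numeric(1))
  data.frame(id = record$id,
             its1_len = lens[["its1"]], r58s_len = lens[["r58s"]],
             its2_len = lens[["its2"]], total_len = lens[["total"]],
             its1_gc = gcs[["its1"]], r58s_gc = gcs[["r58s"]],
             its2_gc = gcs[["its2"]], total_gc = gcs[["total"]],
             stringsAsFactors = FALSE)
}

#' Pairwise percent-identity matrix for an alignment
#'
#' @param msa An [msa_block()].
#' @return Symmetric matrix (diagonal 100) with row/column names.
#' @export
identity_matrix <- function(msa) {
  if (!inherits(msa, "msa_block")) stop("'msa' must be an msa_block")
  n <- length(msa$labels)
  m <- matrix(100, n, n, dimnames = list(msa$labels, msa$labels))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- percent_identity(msa$rows[i], msa$rows[j])
      }
    }
  }
  m
}
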