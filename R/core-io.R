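#' Construct an ITS record
#'
#' An `its_record` holds one ITS1-5.8S-ITS2 amplicon (or read) together with
#' its provenance. Sequences are normalised on construction: lower case is
#' upper-cased, `U` is mapped to `T`, and any IUPAC ambiguity code other
#' than `N` is mapped to `N` with a warning. `N` never counts as a match, a
#' GC base, or a pairable base anywhere downstream.
#'
#' @param id Unique sequence label.
#' @param sequence DNA string.
#' @param source One of `"direct"`, `"clone"`, `"consensus"`, `"read"`.
#' @param meta Named list of free-form metadata (accession code, genome
#'   label such as A/B/S/T, section label).
#' @return An object of class `its_record` with elements `id`, `sequence`,
#'   `source`, `meta`.
#' @export
its_record <- function(id, sequence, source = c("direct", "clone", "consensus", "read"),
                       meta = list()) {
  source <- match.arg(source)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("'sequence' must be a single string")
  sequence <- normalize_dna(sequence, id = id)
  if (!nzchar(sequence)) stop("empty sequence for record '", id, "'")
  structure(list(id = id, sequence = sequence, source = source, meta = meta),
            class = "its_record")
}

#' @export
print.its_record <- function(x, ...) {
  cat(sprintf("<its_record> %s [%s] %d nt\n", x$id, x$source, nchar(x$sequence)))
  invisible(x)
}

# Upper-case, U->T, ambiguity codes (other than N) -> N with a warning.
normalize_dna <- function(sequence, id = "?") {
  s <- toupper(sequence)
  s <- gsub("U", "T", s, fixed = TRUE)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad)) {
    if (grepl("[^ACGTNRYSWKMBDHV.-]", s))
      stop("record '", id, "' contains non-IUPAC characters: ",
           paste(unique(strsplit(gsub("[ACGTNRYSWKMBDHV.-]", "", s), "")[[1]]), collapse = ""))
    warning("record '", id, "': ambiguity codes mapped to N (",
            paste(unique(strsplit(bad, "")[[1]]), collapse = ""), ")")
    s <- gsub("[RYSWKMBDHV.-]", "N", s)
  }
  s
}

#' Read ITS records from a FASTA file
#'
#' Accepts both line-wrapped and single-line FASTA. Duplicate identifiers
#' and empty sequences are errors naming the offending entry.
#'
#' @param path Path to a FASTA file.
#' @param source Source tag applied to every record (see [its_record()]).
#' @return List of `its_record`, in file order.
#' @export
read_its_fasta <- function(path, source = "direct") {
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  head_lines <- head_lines[nzchar(trimws(head_lines))]
  if (length(head_lines) == 0L) stop("malformed FASTA (empty file): ", path)
  if (!startsWith(head_lines[[1L]], ">"))
    stop("malformed FASTA (no '>' header on first entry): ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  empt <- ids[Biostrings::width(ss) == 0L]
  if (length(empt))
    stop("empty sequence for FASTA entries: ", paste(empt, collapse = ", "))
  seqs <- as.character(ss)
  mapply(function(i, s) its_record(i, s, source = source),
         ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write ITS records to FASTA
#'
#' Output is wrapped at 60 columns.
#'
#' @param records List of `its_record`.
#' @param path Output path.
#' @export
write_its_fasta <- function(records, path) {
  records <- as_record_list(records)
  ss <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(ss) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

as_record_list <- function(records) {
  if (inherits(records, "its_record")) return(list(records))
  if (!is.list(records) || !all(vapply(records, inherits, logical(1), "its_record")))
    stop("expected an its_record or a list of its_record")
  ids <- vapply(records, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate record ids: ", paste(dup, collapse = ", "))
  records
}

#' Region annotation for an ITS record
#'
#' 1-based inclusive intervals of ITS1, 5.8S and ITS2 within a sequence.
#' Intervals must be ordered and non-overlapping
#' (`its1[2] < r58s[1] <= r58s[2] < its2[1]`).
#'
#' @param its1,r58s,its2 Integer vectors `c(start, end)`.
#' @param seq_length Optional sequence length used to bound-check.
#' @return Object of class `region_annotation`.
#' @export
region_annotation <- function(its1, r58s, its2, seq_length = NULL) {
  iv <- function(x, nm) {
    x <- as.integer(x)
    if (length(x) != 2L || any(is.na(x)) || x[1] > x[2] || x[1] < 1L)
      stop("invalid interval for ", nm)
    x
  }
  its1 <- iv(its1, "its1"); r58s <- iv(r58s, "r58s"); its2 <- iv(its2, "its2")
  if (!(its1[2] < r58s[1] && r58s[2] < its2[1]))
    stop("regions must be ordered: its1 < 5.8S < its2")
  if (!is.null(seq_length) && its2[2] > seq_length)
    stop("annotation exceeds sequence length")
  structure(list(its1 = its1, r58s = r58s, its2 = its2),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("<region_annotation> ITS1 %d-%d | 5.8S %d-%d | ITS2 %d-%d\n",
              x$its1[1], x$its1[2], x$r58s[1], x$r58s[2], x$its2[1], x$its2[2]))
  invisible(x)
}

#' Extract an annotated sub-region from a record
#'
#' @param record An `its_record` (or plain sequence string).
#' @param annotation A `region_annotation`.
#' @param region One of `"its1"`, `"r58s"`, `"its2"`, `"total"`. `"total"`
#'   spans from the start of ITS1 to the end of ITS2.
#' @return Sub-sequence string.
#' @export
region_seq <- function(record, annotation, region = c("its1", "r58s", "its2", "total")) {
  region <- match.arg(region)
  s <- if (inherits(record, "its_record")) record$sequence else record
  rg <- if (region == "total") c(annotation$its1[1], annotation$its2[2]) else annotation[[region]]
  substr(s, rg[1], rg[2])
}

#' Construct a multiple sequence alignment block
#'
#' @param labels Ordered identifiers.
#' @param rows Equal-length gapped sequence strings (gap = `-`).
#' @return Object of class `msa_block` with a character matrix `mat`
#'   (one row per sequence) besides `labels` and `rows`.
#' @export
msa_block <- function(labels, rows) {
  if (length(labels) != length(rows)) stop("labels and rows differ in length")
  if (length(unique(labels)) != length(labels)) stop("duplicate labels in MSA")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("all MSA rows must have equal length")
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  rownames(mat) <- labels
  structure(list(labels = labels, rows = toupper(rows), mat = mat, n_col = w),
            class = "msa_block")
}

#' @export
print.msa_block <- function(x, ...) {
  cat(sprintf("<msa_block> %d sequences x %d columns\n", length(x$labels), x$n_col))
  invisible(x)
}

#' Remove gaps from an aligned row
#' @param row Gapped sequence string.
#' @return Ungapped sequence.
#' @export
ungap <- function(row) gsub("-", "", row, fixed = TRUE)

## ---- Newick I/O -------------------------------------------------------

newick_reserved <- function(labels) grepl("[][():;,' \t]", labels)

#' Write a phylogenetic tree to Newick
#'
#' Branch lengths are written at full precision and internal-node labels
#' (bootstrap supports) are preserved. Labels containing Newick-reserved
#' characters are single-quoted.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  labs <- tree$tip.label
  bad <- newick_reserved(labs)
  if (any(grepl("'", labs, fixed = TRUE)))
    stop("tip labels may not contain single quotes: ",
         paste(labs[grepl("'", labs, fixed = TRUE)], collapse = ", "))
  placeholder <- sprintf("ITSPROFILERTIP%06d", seq_along(labs))
  tr2 <- tree
  tr2$tip.label <- ifelse(bad, placeholder, labs)
  txt <- ape::write.tree(tr2, digits = 12)
  for (i in which(bad))
    txt <- sub(placeholder[i], paste0("'", labs[i], "'"), txt, fixed = TRUE)
  writeLines(txt, path)
  invisible(path)
}

#' Read a Newick tree
#'
#' Understands the single-quoted labels emitted by [write_newick()].
#'
#' @param path Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  m <- gregexpr("'[^']*'", txt)[[1]]
  quoted <- character(0)
  if (m[1] != -1L) {
    quoted <- regmatches(txt, gregexpr("'[^']*'", txt))[[1]]
    for (i in seq_along(quoted))
      txt <- sub(quoted[i], sprintf("ITSPROFILERTIP%06d", i), txt, fixed = TRUE)
  }
  tree <- ape::read.tree(text = txt)
  if (length(quoted)) {
    for (i in seq_along(quoted)) {
      raw <- substr(quoted[i], 2L, nchar(quoted[i]) - 1L)
      tree$tip.label[tree$tip.label == sprintf("ITSPROFILERTIP%06d", i)] <- raw
    }
  }
  tree
}

# Internal seeded-RNG helper: evaluate `expr` under `seed` without
# disturbing the caller's RNG stream. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
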