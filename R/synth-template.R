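## Designed synthetic ITS template. This is the package's stand-in for an
## annotated real reference (the study organisms' amplicons and the
## annotated rice ITS used for boundary delimitation are not shipped):
## every structural feature a functional plant ITS is screened for is
## present by construction, with known coordinates.

# Fixed ITS1 (219 nt, GC 56%, 18 CpG sites) and partial 18S/26S flanks
# (60 nt each). Generated once from a seeded draw and frozen as literals.
ITS1_TEMPLATE <- paste0(
  "GCTTCGGGTGATTAGGACGCTACTATCGGTGGCCGACACAGGTGGCCATCCGTTGTTGTG",
  "AATAATCGAACAGAACCCTATTTACAGGCCTATCCAGCCCCCGATGCCTACCGAAAAGGT",
  "GCCGCAGGTCTGCCGGGAGTACAGACGTCGCGTACCGTGAATAGGACACGTAGTAATAAT",
  "ATGCGCCCTCCCGCAGTACGTGCCACACTGGAGGCTGGA")
FLANK5_TEMPLATE <- "CTGCGACCGTCCCTCCTTTCGGATCGGGAAGCAAGGAGAGTAACAGTATGTCTTTCCAAT"
FLANK3_TEMPLATE <- "GATTTAGGGCAACCCCGCTTATACATACCGCCACGCGGTATGTGCTCCAGGTGTCGATTT"

# Window deleted by the Australimusa-like 41-bp ITS1 deletion operator,
# 1-based within ITS1.
ITS1_DEL41 <- c(100L, 140L)

#' Canonical 5.8S motif and helix-constraint definitions
#'
#' The three conserved angiosperm 5.8S motifs:
#' M1 `CGATGAAGAACGTAGC` (16 nt), M2 `GAATTGCAGAATCC` (14 nt),
#' M3 `TTTGAACGCA` (10 nt).
#'
#' @return Named list of motif strings.
#' @export
its_motifs <- function() {
  list(M1 = "CGATGAAGAACGTAGC",
       M2 = "GAATTGCAGAATCC",
       M3 = "TTTGAACGCA")
}

#' 5.8S helix base-pairing constraints
#'
#' Constraint `(i, j, k)` for a helix means positions `i..i+k-1` pair with
#' `j..j-k+1` respectively (1-based within the 5.8S region). Helix B8 is
#' given as two stacked constraints B8a and B8b.
#'
#' @return data.frame with columns `helix`, `i`, `j`, `k`.
#' @export
helix_constraints <- function() {
  data.frame(
    helix = c("B4", "B5", "B6", "B7", "B8a", "B8b"),
    i = c(38L, 41L, 62L, 103L, 112L, 119L),
    j = c(98L, 54L, 89L, 111L, 135L, 128L),
    k = c(3L, 3L, 3L, 3L, 4L, 3L),
    stringsAsFactors = FALSE)
}

# Positions (within 5.8S) constrained by helix_constraints().
constrained_58s_positions <- function() {
  hc <- helix_constraints()
  unique(unlist(lapply(seq_len(nrow(hc)), function(r) {
    t <- seq_len(hc$k[r]) - 1L
    c(hc$i[r] + t, hc$j[r] - t)
  })))
}

# Motif placements within the designed 5.8S (1-based start offsets).
R58S_MOTIF_STARTS <- c(M1 = 34L, M2 = 71L, M3 = 98L)

# Build the designed 155-nt 5.8S: exact M1/M2/M3 at realistic offsets and
# all six helix constraints satisfiable by construction. Free positions
# carry a fixed near-50% GC filler.
build_58s_template <- function() {
  s <- strsplit(paste(rep("CAGTGCAT", 20L), collapse = ""), "")[[1]][1:155]
  put <- function(s, start, str) {
    ch <- strsplit(str, "")[[1]]
    s[start + seq_along(ch) - 1L] <- ch
    s
  }
  mot <- its_motifs()
  for (m in names(mot)) s <- put(s, R58S_MOTIF_STARTS[[m]], mot[[m]])
  # Partner bases completing the constrained pairs not already fixed by a
  # motif (M1 supplies the 5' strands of B4/B5; M3 supplies position 98 of
  # B4 and the 5' strand of B7).
  partners <- c(
    "96" = "T", "97" = "T",                      # B4 3' (98 = T from M1/M3)
    "52" = "T", "53" = "T", "54" = "C",          # B5 3'
    "62" = "G", "63" = "C", "64" = "A",          # B6 5'
    "87" = "T", "88" = "G", "89" = "C",          # B6 3'
    "109" = "C", "110" = "G", "111" = "T",       # B7 3'
    "112" = "G", "113" = "G", "114" = "A", "115" = "C",  # B8a 5'
    "132" = "G", "133" = "T", "134" = "C", "135" = "C",  # B8a 3'
    "119" = "G", "120" = "C", "121" = "T",       # B8b 5'
    "126" = "A", "127" = "G", "128" = "C")       # B8b 3'
  s[as.integer(names(partners))] <- unname(partners)
  paste(s, collapse = "")
}

# Stem sequences of the four designed ITS2 hairpin cassettes. Chosen by a
# seeded design search so that maximum-pairing folding with stacking
# tie-breaking recovers the intended four-helix topology, and keeps
# recovering it under substitutions at every mutable (linker/loop)
# position (validated exhaustively for single hits and by simulation for
# multiple hits).
ITS2_STEMS <- c("GAGGAGACACGATCA",  # helix I
                "CCGCCCGGGGCCTCC",  # helix II (split 7+8 around the bulge)
                "CTGTTTGCCCCTGTT",  # helix III
                "GTCGCGGATGTGTGG")  # helix IV

# Designed ITS2 (211 nt): four hairpin cassettes separated by A-linkers.
# Helix II carries a T|T internal loop (the pyrimidine-pyrimidine bulge);
# the loop of cassette III carries TGGT. Returns the sequence plus
# ground-truth coordinates (1-based within ITS2): cassette spans and the
# mutable (structurally neutral) positions.
build_its2_template <- function() {
  rc <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  linker <- strrep("A", 13L)
  c2a <- substr(ITS2_STEMS[2], 1L, 7L)
  c2b <- substr(ITS2_STEMS[2], 8L, 15L)
  cass <- c(
    paste0(ITS2_STEMS[1], "AAAAAA", rc(ITS2_STEMS[1])),
    paste0(c2a, "T", c2b, "AAAAAA", rc(c2b), "T", rc(c2a)),
    paste0(ITS2_STEMS[3], "ATGGTA", rc(ITS2_STEMS[3])),
    paste0(ITS2_STEMS[4], "AAAAAA", rc(ITS2_STEMS[4])))
  seq <- paste0(linker, cass[1], linker, cass[2], linker, cass[3], linker,
                cass[4], linker)
  off <- nchar(linker)
  spans <- list()
  pos <- off
  for (i in 1:4) {
    w <- nchar(cass[i])
    spans[[i]] <- c(pos + 1L, pos + w)
    pos <- pos + w + off
  }
  # mutable = the five linkers plus the loop A positions (the TGGT and the
  # bulge pyrimidines stay frozen); everything else is structural core
  lens <- c(13L, nchar(cass[1]), 13L, nchar(cass[2]), 13L, nchar(cass[3]),
            13L, nchar(cass[4]), 13L)
  starts <- cumsum(c(1L, lens[-9]))
  link_pos <- unlist(lapply(c(1L, 3L, 5L, 7L, 9L), function(i) starts[i] + 0:12))
  loop_pos <- c(starts[2] + 15L + 0:5,          # loop I
                starts[4] + 16L + 0:5,          # loop II
                starts[6] + 15L + c(0L, 5L),    # loop III A's around TGGT
                starts[8] + 15L + 0:5)          # loop IV
  mutable <- sort(c(link_pos, loop_pos))
  list(seq = seq, cassettes = spans, mutable = mutable,
       core = setdiff(seq_len(nchar(seq)), mutable))
}

#' The packaged synthetic annotated reference
#'
#' A designed ITS1-5.8S-ITS2 amplicon with partial 18S/26S flanks and known
#' region boundaries, used as the default delimitation reference. It is a
#' documented synthetic stand-in for an annotated real ITS reference
#' sequence: region lengths (ITS1 219 nt, 5.8S 155 nt, ITS2 211 nt; total
#' 585 nt) lie inside the ranges reported for Musaceae, the 5.8S carries
#' exact copies of the M1/M2/M3 motifs and satisfies all six helix
#' constraints, and the ITS2 folds into a four-helix topology with TGGT in
#' helix III and a pyrimidine-pyrimidine bulge in helix II.
#'
#' @return List with elements `record` ([its_record()]) and `annotation`
#'   ([region_annotation()]).
#' @export
synthetic_reference <- function() {
  its2 <- build_its2_template()
  seqs <- c(FLANK5_TEMPLATE, ITS1_TEMPLATE, build_58s_template(), its2$seq,
            FLANK3_TEMPLATE)
  lens <- nchar(seqs)
  starts <- cumsum(c(1L, lens[-5]))
  ann <- region_annotation(
    its1 = c(starts[2], starts[2] + lens[2] - 1L),
    r58s = c(starts[3], starts[3] + lens[3] - 1L),
    its2 = c(starts[4], starts[4] + lens[4] - 1L),
    seq_length = sum(lens))
  rec <- its_record("synthetic_reference", paste(seqs, collapse = ""),
                    source = "consensus",
                    meta = list(note = "designed synthetic ITS reference"))
  list(record = rec, annotation = ann)
}
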