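## Secondary-structure screening. The thermodynamic folding used in the
## wider literature is replaced here by deterministic maximum base-pair
## (Nussinov-style) folding: the screening surface is topology and
## constraint satisfiability, not free energies.

#' Fold an ITS2 sequence by maximum nested base pairing
#'
#' Dynamic-programming maximum-cardinality nested pairing over the
#' canonical pair set (AT, GC and GT wobble; `N` never pairs) with a
#' minimum hairpin loop of 3 unpaired nucleotides and a deterministic
#' traceback. Helices are maximal stacks of pairs; stacks separated by
#' bulges/internal loops of at most 2 unpaired nucleotides per strand are
#' merged into one helix, and helices shorter than 3 pairs are discarded.
#'
#' @param its2_seq DNA string, length >= 40.
#' @param max_n_frac Refuse to fold when the N fraction exceeds this
#'   (default 0.2).
#' @return List of class `fold_result`: `pairs` (2-column matrix, i < j),
#'   `helices` (list of pair matrices in 5' order), `score` (number of
#'   pairs), `n` (sequence length).
#' @export
fold_its2 <- function(its2_seq, max_n_frac = 0.2) {
  s <- toupper(its2_seq)
  n <- nchar(s)
  if (n < 40L) stop("sequence shorter than 40 nt; not a plausible ITS2")
  if (mean(strsplit(s, "")[[1]] == "N") > max_n_frac)
    stop("more than ", round(100 * max_n_frac), "% N; refusing to fold")
  pairs <- .nussinov_pairs(s, 3L)
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(pairs = pairs, helices = group_helices(pairs),
                 score = nrow(pairs), n = n),
            class = "fold_result")
}

# Group sorted pairs into helices: consecutive pairs (i,j), (i',j') belong
# together when i'-i <= 3 and j-j' <= 3 (stacked, or separated by <= 2
# unpaired nt per strand). Runs of < 3 pairs are not helices.
group_helices <- function(pairs, min_run = 3L, max_gap = 3L) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(list())
  ord <- order(pairs[, 1])
  pairs <- pairs[ord, , drop = FALSE]
  groups <- list()
  cur <- pairs[1, , drop = FALSE]
  for (r in seq_len(nrow(pairs))[-1]) {
    prev <- cur[nrow(cur), ]
    now <- pairs[r, ]
    if (now[1] - prev[1] <= max_gap && prev[2] - now[2] <= max_gap &&
        now[2] < prev[2]) {
      cur <- rbind(cur, now)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- pairs[r, , drop = FALSE]
    }
  }
  groups[[length(groups) + 1L]] <- cur
  groups <- Filter(function(g) nrow(g) >= min_run, groups)
  groups[order(vapply(groups, function(g) min(g[, 1]), numeric(1)))]
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %d nt, %d pairs, %d helices\n",
              x$n, x$score, length(x$helices)))
  invisible(x)
}

#' Dot-bracket string for a fold
#' @param fold A `fold_result`.
#' @return Dot-bracket notation string.
#' @export
dot_bracket <- function(fold) {
  db <- rep(".", fold$n)
  if (nrow(fold$pairs)) {
    db[fold$pairs[, 1]] <- "("
    db[fold$pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

#' Check ITS2 four-helix topology
#'
#' Helices are numbered I-IV in 5'->3' order of their 5' strands. Only
#' helices of at least `min_helix_pairs` pairs take part in the numbering:
#' ITS2 cassette stems are >= 5 bp in functional spacers, while incidental
#' 3-4 pair runs arise easily between unpaired linkers under
#' maximum-pairing folding and carry no topological signal. The conserved
#' TGGT must occur within the helix-III span (stem plus loop); the
#' helix-II pyrimidine-pyrimidine bulge is an internal loop inside helix
#' II with exactly one unpaired pyrimidine (C/T) on each strand.
#'
#' @param fold `fold_result` computed on `its2_seq`.
#' @param its2_seq The folded sequence.
#' @param min_helix_pairs Minimum stacked pairs for a helix to count
#'   toward the I-IV numbering (default 5).
#' @return List with `its2_n_helices`, `tggt_in_helix3`,
#'   `pyr_pyr_bulge_helix2`, `overall_its2_ok`
#'   (= 4 helices and TGGT present).
#' @export
its2_topology <- function(fold, its2_seq, min_helix_pairs = 5L) {
  s <- toupper(its2_seq)
  hx <- Filter(function(h) nrow(h) >= min_helix_pairs, fold$helices)
  nh <- length(hx)
  tggt <- FALSE
  bulge <- FALSE
  if (nh >= 3L) {
    h3 <- hx[[3L]]
    span <- substr(s, min(h3[, 1]), max(h3[, 2]))
    tggt <- grepl("TGGT", span, fixed = TRUE)
  }
  if (nh >= 2L) {
    h2 <- hx[[2L]]
    ch <- strsplit(s, "")[[1]]
    if (nrow(h2) >= 2L) {
      for (r in seq_len(nrow(h2) - 1L)) {
        a <- h2[r, ]; b <- h2[r + 1L, ]
        if (b[1] - a[1] == 2L && a[2] - b[2] == 2L) {
          up <- ch[a[1] + 1L]; dn <- ch[b[2] + 1L]
          if (up %in% c("C", "T") && dn %in% c("C", "T")) bulge <- TRUE
        }
      }
    }
  }
  list(its2_n_helices = nh, tggt_in_helix3 = tggt,
       pyr_pyr_bulge_helix2 = bulge,
       overall_its2_ok = (nh == 4L) && tggt)
}

#' Check 5.8S helix-constraint satisfiability
#'
#' For each constraint `(i, j, k)` of [helix_constraints()], every
#' prescribed pair `(i+t, j-t)`, `t in 0..k-1`, must be canonical
#' (AT/GC/GT, orientation-free). The result depends only on the 18
#' constrained positions.
#'
#' @param r58s_seq 5.8S region sequence; must reach the largest
#'   constrained position (135 nt).
#' @return Named logical vector, one entry per helix (B4..B8b), plus
#'   attribute `overall` (all TRUE).
#' @export
check_58s_constraints <- function(r58s_seq) {
  s <- strsplit(toupper(r58s_seq), "")[[1]]
  hc <- helix_constraints()
  if (length(s) < max(hc$j))
    stop("5.8S too short for constraint check (", length(s), " < ", max(hc$j),
         " nt); truncation is itself pseudogene evidence")
  ok_pair <- function(a, b)
    paste(a, b) %in% c("A T", "T A", "G C", "C G", "G T", "T G")
  res <- vapply(seq_len(nrow(hc)), function(r) {
    t <- seq_len(hc$k[r]) - 1L
    all(mapply(ok_pair, s[hc$i[r] + t], s[hc$j[r] - t]))
  }, logical(1))
  names(res) <- hc$helix
  attr(res, "overall") <- all(res)
  res
}

#' Full structure report for one delimited record
#'
#' Combines [fold_its2()], [its2_topology()] and [check_58s_constraints()].
#' A 5.8S too short for the constraint check yields `overall_58s_ok =
#' FALSE` with all helix entries FALSE rather than an error, so truncated
#' pseudogenes flow into classification.
#'
#' @param record An [its_record()].
#' @param annotation A [region_annotation()] for the record.
#' @return List of class `structure_report` with the ITS2 topology fields,
#'   `r58s_constraints` (named logical), `overall_its2_ok`,
#'   `overall_58s_ok`.
#' @export
structure_report <- function(record, annotation) {
  its2 <- region_seq(record, annotation, "its2")
  r58s <- region_seq(record, annotation, "r58s")
  topo <- if (nchar(its2) >= 40L) {
    its2_topology(fold_its2(its2), its2)
  } else {
    list(its2_n_helices = 0L, tggt_in_helix3 = FALSE,
         pyr_pyr_bulge_helix2 = FALSE, overall_its2_ok = FALSE)
  }
  cons <- tryCatch(check_58s_constraints(r58s), error = function(e) {
    res <- rep(FALSE, nrow(helix_constraints()))
    names(res) <- helix_constraints()$helix
    attr(res, "overall") <- FALSE
    attr(res, "note") <- conditionMessage(e)
    res
  })
  structure(list(id = record$id,
                 its2_n_helices = topo$its2_n_helices,
                 tggt_in_helix3 = topo$tggt_in_helix3,
                 pyr_pyr_bulge_helix2 = topo$pyr_pyr_bulge_helix2,
                 r58s_constraints = cons,
                 overall_its2_ok = topo$overall_its2_ok,
                 overall_58s_ok = isTRUE(attr(cons, "overall"))),
            class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat(sprintf("<structure_report> %s: ITS2 %d helices (TGGT %s, bulge %s) %s; 5.8S %s\n",
              x$id, x$its2_n_helices, x$tggt_in_helix3, x$pyr_pyr_bulge_helix2,
              if (x$overall_its2_ok) "OK" else "FAIL",
              if (x$overall_58s_ok) "OK"
              else paste0("FAIL (", paste(names(x$r58s_constraints)[!x$r58s_constraints],
                                          collapse = ","), ")")))
  invisible(x)
}
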