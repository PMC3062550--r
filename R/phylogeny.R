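## Distance-based phylogeny: p / Jukes-Cantor distances, Saitou-Nei
## neighbour joining with deterministic tie-breaking, nonparametric
## bootstrap, midpoint rooting and genome-constitution assignment.

#' p-distance of two aligned rows
#'
#' Differences / compared sites with pairwise deletion of gap/N columns.
#'
#' @param a,b Equal-length gapped rows.
#' @return Fraction in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("rows must have equal (aligned) length")
  pr <- pairwise_p(ca, cb)
  if (pr[["n"]] == 0) stop("zero compared sites")
  pr[["p"]]
}

#' Jukes-Cantor correction of a p-distance
#'
#' `d = -(3/4) log(1 - 4 p / 3)`; strictly increasing on `[0, 0.75)`.
#'
#' @param p p-distance(s) in `[0, 0.75)`.
#' @return Corrected distance(s).
#' @export
jc_distance <- function(p) {
  if (any(p < 0 | p >= 0.75))
    stop("Jukes-Cantor distance undefined for p >= 0.75 (saturation)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Distance matrix from an alignment
#'
#' @param msa An [msa_block()].
#' @param model `"p"` (uncorrected) or `"jc"` (Jukes-Cantor).
#' @param max_p Optional ceiling substituted for saturated pairs
#'   (p >= 0.75) under the JC model; by default saturation is an error.
#' @return List of class `its_dist`: `labels`, `matrix`, `model`.
#' @export
distance_matrix <- function(msa, model = c("jc", "p"), max_p = NULL) {
  model <- match.arg(model)
  if (!inherits(msa, "msa_block")) stop("'msa' must be an msa_block")
  n <- length(msa$labels)
  m <- matrix(0, n, n, dimnames = list(msa$labels, msa$labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pr <- pairwise_p(msa$mat[i, ], msa$mat[j, ])
      if (pr[["n"]] == 0)
        stop("zero compared sites for pair ", msa$labels[i], "/", msa$labels[j])
      p <- pr[["p"]]
      if (model == "jc") {
        if (p >= 0.75) {
          if (is.null(max_p)) stop("saturated pair (p >= 0.75): ",
                                   msa$labels[i], "/", msa$labels[j])
          p <- max_p
        }
        m[i, j] <- m[j, i] <- jc_distance(p)
      } else {
        m[i, j] <- m[j, i] <- p
      }
    }
  }
  structure(list(labels = msa$labels, matrix = m, model = model),
            class = "its_dist")
}

#' @export
print.its_dist <- function(x, ...) {
  cat(sprintf("<its_dist> %d labels, model %s\n", length(x$labels), x$model))
  invisible(x)
}

as_its_dist <- function(x, model = "p") {
  if (inherits(x, "its_dist")) return(x)
  if (inherits(x, "dist")) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- colnames(x) <- paste0("t", seq_len(nrow(x)))
    return(structure(list(labels = rownames(x), matrix = x, model = model),
                     class = "its_dist"))
  }
  stop("cannot interpret distance input")
}

#' Neighbour-joining tree (Saitou-Nei)
#'
#' Classical NJ with Q-matrix pair selection. Ties in Q are broken
#' deterministically by the lexicographically smallest pair of subtree
#' labels (each subtree represented by its smallest leaf label). Negative
#' branch lengths are clamped to zero and the clamped deficit reported via
#' a message. The result is unrooted (root trifurcation).
#'
#' @param dm An `its_dist` (or plain symmetric labelled matrix / `dist`).
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as_its_dist(dm)
  D <- dm$matrix
  if (!isTRUE(all.equal(D, t(D))) || any(!is.finite(D)))
    stop("distance matrix must be symmetric and finite")
  labels <- dm$labels
  n <- length(labels)
  if (n < 3L) stop("neighbour joining needs at least 3 taxa")

  # node bookkeeping: tips 1..n (ape numbering), internals allocated later
  next_internal <- n + 2L  # n+1 reserved for the final root
  active <- seq_len(n)     # ape node ids
  rep_lab <- labels        # smallest leaf label per active subtree
  edges <- matrix(integer(0), 0, 2)
  elen <- numeric(0)
  Dm <- D
  idx <- seq_len(n)        # row/col of Dm per active node
  clamped <- 0

  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    len <- unname(len)
    if (len < 0) { clamped <<- clamped + (-len); len <- 0 }
    elen <<- c(elen, len)
  }

  while (length(active) > 3L) {
    N <- length(active)
    r <- rowSums(Dm)
    Q <- (N - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      ls <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(ls, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- Dm[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (N - 2))
    bj <- dij - bi
    u <- next_internal; next_internal <- next_internal + 1L
    add_edge(u, active[i], bi)
    add_edge(u, active[j], bj)
    dnew <- (Dm[i, ] + Dm[j, ] - dij) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    new_lab <- min(rep_lab[c(i, j)])
    rep_lab <- c(rep_lab[keep], new_lab)
    active <- c(active[keep], u)
  }

  # final trifurcation at the root (node n+1)
  root <- n + 1L
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  add_edge(root, active[1], (d12 + d13 - d23) / 2)
  add_edge(root, active[2], (d12 + d23 - d13) / 2)
  add_edge(root, active[3], (d13 + d23 - d12) / 2)
  if (clamped > 1e-8)
    message(sprintf("neighbor_joining: clamped negative branch lengths (total deficit %.4g)", clamped))

  # renumber internals so the root is n+1 and internals are contiguous
  internal_ids <- unique(edges[, 1])
  internal_ids <- c(root, setdiff(internal_ids, root))
  remap <- stats::setNames(seq_along(internal_ids) + n, internal_ids)
  e2 <- edges
  e2[, 1] <- remap[as.character(edges[, 1])]
  over <- edges[, 2] > n
  e2[over, 2] <- remap[as.character(edges[over, 2])]
  tree <- structure(list(edge = e2, edge.length = elen, tip.label = labels,
                         Nnode = length(internal_ids)), class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

#' Bootstrap supports for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' pseudoreplicate, and annotates each internal node of the original tree
#' with the percentage of replicates containing its bipartition. Seeded
#' and reproducible.
#'
#' @param msa An [msa_block()] with at least 4 rows.
#' @param n_replicates Number of pseudoreplicates (default 1000).
#' @param seed Integer seed.
#' @param model Distance model, `"jc"` or `"p"`.
#' @param max_p Saturation ceiling passed to [distance_matrix()]
#'   (default 0.74 so odd pseudoreplicates never abort a run).
#' @return The NJ tree on the full alignment with `node.label` set to
#'   bootstrap percentages.
#' @export
bootstrap_support <- function(msa, n_replicates = 1000L, seed = 1L,
                              model = "jc", max_p = 0.74) {
  if (!inherits(msa, "msa_block")) stop("'msa' must be an msa_block")
  if (length(msa$labels) < 4L) stop("bootstrap needs >= 4 sequences")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  main <- neighbor_joining(distance_matrix(msa, model = model, max_p = max_p))
  L <- msa$n_col
  boots <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      sub <- msa$mat[, cols, drop = FALSE]
      rows <- apply(sub, 1L, paste, collapse = "")
      suppressMessages(
        neighbor_joining(distance_matrix(msa_block(msa$labels, rows),
                                         model = model, max_p = max_p)))
    })
  })
  class(boots) <- "multiPhylo"
  counts <- suppressWarnings(
    ape::prop.clades(main, boots, rooted = FALSE))
  counts[is.na(counts)] <- 0
  main$node.label <- as.character(round(100 * counts / n_replicates, 1))
  main
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Rooted tree.
#' @export
midpoint_root <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0)
    stop("midpoint rooting needs non-zero branch lengths")
  phangorn::midpoint(tree)
}

#' Assign genome constitution to query ITS types
#'
#' Each query is aligned into the labelled reference alignment and
#' assigned the genome label of the reference group with the smallest
#' mean distance (Jukes-Cantor by default). The margin between the best
#' and second-best group means is reported, and assignments with margin
#' below `ambiguity_floor` are flagged ambiguous.
#'
#' @param query_types List of [its_record()] (e.g. type consensuses).
#' @param reference_msa [msa_block()] of reference sequences.
#' @param reference_labels Named character vector mapping reference id ->
#'   genome label (A/B/S/T/...); every reference id must be covered.
#' @param model `"jc"` or `"p"`.
#' @param ambiguity_floor Margin floor (default 0.005).
#' @return data.frame: `query`, `genome`, `margin`, `ambiguous`, and one
#'   `mean_<label>` column per genome.
#' @export
assign_genome <- function(query_types, reference_msa, reference_labels,
                          model = "jc", ambiguity_floor = 0.005) {
  query_types <- as_record_list(query_types)
  if (!inherits(reference_msa, "msa_block")) stop("'reference_msa' must be an msa_block")
  missing_lab <- setdiff(reference_msa$labels, names(reference_labels))
  if (length(missing_lab))
    stop("references without genome label: ", paste(missing_lab, collapse = ", "))
  genomes <- sort(unique(unname(reference_labels[reference_msa$labels])))
  ref_mat <- reference_msa$mat
  rows <- lapply(query_types, function(q) {
    qm <- matrix(strsplit(q$sequence, "")[[1]], nrow = 1L,
                 dimnames = list(q$id, NULL))
    merged <- merge_profiles(ref_mat, qm)
    qrow <- merged[nrow(merged), ]
    ds <- vapply(seq_len(nrow(ref_mat)), function(i) {
      p <- pairwise_p(merged[i, ], qrow)[["p"]]
      if (model == "jc") jc_distance(min(p, 0.74)) else p
    }, numeric(1))
    means <- vapply(genomes, function(g)
      mean(ds[reference_labels[reference_msa$labels] == g]), numeric(1))
    ord <- order(means)
    margin <- if (length(means) > 1L) means[ord[2]] - means[ord[1]] else Inf
    out <- data.frame(query = q$id, genome = genomes[ord[1]],
                      margin = margin, ambiguous = margin < ambiguity_floor,
                      stringsAsFactors = FALSE)
    for (g in genomes) out[[paste0("mean_", g)]] <- means[[g]]
    out
  })
  do.call(rbind, rows)
}
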