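## Seeded synthetic-data generator. The generator emulates the
## statistical structure of a Musaceae-style ITS study: several divergent
## functional ITS templates per lineage, pseudogenised derivatives (CpG
## deamination, motif disruption, structure breakage, a 41-bp ITS1
## deletion), clone libraries with low per-base error, hybrid accessions
## mixing parental types, and shotgun-style reads over an ITS contig.

# Default lineage: A/B/S/T genomes plus Rhodochlamys-, Australimusa- and
# Ensete-like outgroups, with per-edge per-site substitution probabilities
# at the few-percent ITS divergences typical within the family.
DEFAULT_LINEAGE <- paste0(
  "(((A:0.010,S:0.010):0.008,(Rhodochlamys:0.012,B:0.020):0.005):0.015,",
  "(T:0.008,Australimusa:0.008):0.015,Ensete:0.045);")

#' Synthetic-study specification
#'
#' Bundles every knob of the generator with defaults inside the ranges
#' reported for real Musaceae ITS data: ITS1 219 nt (216-223), 5.8S 155 nt
#' (154-155), ITS2 211 nt (205-227), clone libraries of 15-85 members with
#' per-base error around 1/600, and few-percent between-lineage
#' divergence.
#'
#' @param seed Integer seed; every downstream draw is derived from it.
#' @param lineage Newick string with per-edge per-site substitution
#'   probabilities.
#' @param r58s_rate_factor Relative substitution rate of unconstrained
#'   5.8S positions (default 0.2; motif and helix-constraint positions
#'   never mutate in functional templates).
#' @param flank_rate_factor Relative rate of the 18S/26S flanks (0.1).
#' @param clone_error Per-base clone error rate (default 1/600).
#' @param n_clones Default clone-library size (default 15).
#' @param read_len,read_coverage,read_error Read-simulation defaults.
#' @param pseudo_cpg_rate Per-CpG-site deamination probability used by
#'   [pseudogenize()] defaults (default 0.3).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, lineage = DEFAULT_LINEAGE,
                           r58s_rate_factor = 0.2, flank_rate_factor = 0.1,
                           clone_error = 1 / 600, n_clones = 15L,
                           read_len = 150L, read_coverage = 20,
                           read_error = 0.005, pseudo_cpg_rate = 0.3) {
  structure(list(seed = as.integer(seed), lineage = lineage,
                 r58s_rate_factor = r58s_rate_factor,
                 flank_rate_factor = flank_rate_factor,
                 clone_error = clone_error, n_clones = as.integer(n_clones),
                 read_len = as.integer(read_len),
                 read_coverage = read_coverage, read_error = read_error,
                 pseudo_cpg_rate = pseudo_cpg_rate),
            class = "synthetic_spec")
}

# Per-position substitution-rate multipliers over the full reference
# record: ITS1 fully neutral, ITS2 neutral only outside the designed
# stems/bulge/TGGT core, 5.8S neutral outside motifs and constrained
# positions at a reduced rate, flanks nearly frozen.
template_rate_mask <- function(spec = synthetic_spec()) {
  sr <- synthetic_reference()
  an <- sr$annotation
  L <- nchar(sr$record$sequence)
  rate <- numeric(L)
  rate[an$its1[1]:an$its1[2]] <- 1
  # 5.8S neutral positions
  mot <- its_motifs()
  protected <- unlist(lapply(names(mot), function(m)
    R58S_MOTIF_STARTS[[m]] + seq_len(nchar(mot[[m]])) - 1L))
  protected <- unique(c(protected, constrained_58s_positions()))
  neutral58 <- setdiff(seq_len(an$r58s[2] - an$r58s[1] + 1L), protected)
  rate[an$r58s[1] + neutral58 - 1L] <- spec$r58s_rate_factor
  # ITS2 neutral = designed A linkers/loops
  its2 <- build_its2_template()
  rate[an$its2[1] + its2$mutable - 1L] <- 1
  rate[seq_len(an$its1[1] - 1L)] <- spec$flank_rate_factor
  rate[(an$its2[2] + 1L):L] <- spec$flank_rate_factor
  rate
}

mutate_seq <- function(chars, site_prob) {
  hit <- which(stats::runif(length(chars)) < site_prob & chars %in% c("A", "C", "G", "T"))
  for (i in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[i])
    chars[i] <- alt[sample.int(3L, 1L)]
  }
  chars
}

# Mutate under purifying selection on ITS2 secondary structure: linker
# substitutions that happen to destroy the four-helix topology are
# reverted (compensatory selection keeps functional paralogs fold-able;
# this is also what makes the generator's functional templates functional
# by construction).
mutate_functional <- function(chars, site_prob, annotation) {
  out <- mutate_seq(chars, site_prob)
  rg <- annotation$its2[1]:annotation$its2[2]
  its2 <- paste(out[rg], collapse = "")
  topo <- its2_topology(fold_its2(its2), its2)
  if (!(topo$overall_its2_ok && topo$pyr_pyr_bulge_helix2)) {
    out[rg] <- chars[rg]
  }
  out
}

#' Generate functional ITS templates along a lineage tree
#'
#' The designed reference evolves along the lineage by independent
#' per-site substitutions (all substitutions equiprobable, matching the
#' Jukes-Cantor distances used downstream); functionally constrained
#' positions (5.8S motifs and helix pairs, ITS2 stems, bulge and TGGT)
#' never mutate, so every template is functional by construction.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return List of class `synthetic_templates`: `records` (named list of
#'   [its_record()], one per lineage leaf), `annotation` (shared
#'   [region_annotation()]), `tree` (the lineage [ape::phylo]),
#'   `rate_mask`.
#' @export
generate_templates <- function(spec = synthetic_spec(), seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  tree <- ape::read.tree(text = spec$lineage)
  if (any(tree$edge.length < 0 | tree$edge.length >= 0.75))
    stop("lineage substitution probabilities must lie in [0, 0.75)")
  sr <- synthetic_reference()
  rate <- template_rate_mask(spec)
  root_chars <- strsplit(sr$record$sequence, "")[[1]]
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root_node]] <- root_chars
  with_seed(seed, {
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      seqs[[child]] <- mutate_functional(seqs[[parent]],
                                         ord$edge.length[e] * rate,
                                         sr$annotation)
    }
  })
  records <- lapply(seq_len(n_tip), function(i) {
    its_record(tree$tip.label[i], paste(seqs[[i]], collapse = ""),
               source = "consensus",
               meta = list(genome = tree$tip.label[i], synthetic = TRUE))
  })
  names(records) <- tree$tip.label
  structure(list(records = records, annotation = sr$annotation, tree = tree,
                 rate_mask = rate),
            class = "synthetic_templates")
}

# Transition partner used for targeted motif/constraint hits.
transition <- c(A = "G", G = "A", C = "T", T = "C")

# Designated 5.8S helix-breaking substitutions (position within 5.8S,
# replacement base); positions avoid the M1-M3 motifs so a helix break
# never doubles as a motif hit.
helix_break_map <- function() {
  data.frame(helix = c("B4", "B5", "B6", "B7", "B8a", "B8b"),
             pos = c(97L, 53L, 62L, 110L, 113L, 120L),
             base = c("G", "G", "A", "C", "T", "A"),
             stringsAsFactors = FALSE)
}

#' Pseudogenise a functional template
#'
#' Applies any combination of: CpG deamination in ITS1 at rate
#' `cpg_rate` (C->T on the C of CpG, G->A on the G), targeted transition
#' substitutions inside the 5.8S motifs (`motif_hits`, e.g.
#' `list(M1 = c(11, 16))`), designated 5.8S helix-constraint-breaking
#' substitutions (`helix_breaks`, e.g. `"B4"`), disruption of the fourth
#' ITS2 stem (`its2_break`), and the 41-bp ITS1 deletion
#' (`its1_del41`). With all defaults off the template is returned
#' unchanged.
#'
#' @param template An [its_record()] derived from the designed reference.
#' @param annotation Its [region_annotation()].
#' @param cpg_rate Per-CpG-site deamination probability (default 0).
#' @param motif_hits Named list motif -> positions within the motif.
#' @param helix_breaks Character vector of helix names (B4..B8b).
#' @param its2_break Logical; disrupt helix IV.
#' @param its1_del41 Logical; apply the 41-bp ITS1 block deletion.
#' @param id Id for the derived record (default `<template>_psi`).
#' @param seed Optional seed for the CpG draw.
#' @return List: `record`, `annotation` (shifted if a deletion was
#'   applied), `truth` (list of injected defects).
#' @export
pseudogenize <- function(template, annotation, cpg_rate = 0,
                         motif_hits = list(), helix_breaks = character(0),
                         its2_break = FALSE, its1_del41 = FALSE,
                         id = paste0(template$id, "_psi"), seed = NULL) {
  chars <- strsplit(template$sequence, "")[[1]]
  truth <- list(cpg_sites = integer(0), motif_hits = motif_hits,
                helix_breaks = helix_breaks, its2_break = its2_break,
                its1_del41 = its1_del41)

  if (length(motif_hits)) {
    mot <- its_motifs()
    for (m in names(motif_hits)) {
      if (!m %in% names(mot)) stop("unknown motif: ", m)
      pos <- motif_hits[[m]]
      if (any(pos < 1L | pos > nchar(mot[[m]])))
        stop("motif hit positions outside ", m)
      abs_pos <- annotation$r58s[1] - 1L + R58S_MOTIF_STARTS[[m]] + pos - 1L
      if (!all(chars[abs_pos] == strsplit(mot[[m]], "")[[1]][pos]))
        stop("template does not carry the canonical ", m,
             " at the designed offset; cannot inject hits")
      chars[abs_pos] <- transition[chars[abs_pos]]
    }
  }
  if (length(helix_breaks)) {
    hb <- helix_break_map()
    unknown <- setdiff(helix_breaks, hb$helix)
    if (length(unknown)) stop("unknown helix: ", paste(unknown, collapse = ","))
    for (h in helix_breaks) {
      row <- hb[hb$helix == h, ]
      chars[annotation$r58s[1] - 1L + row$pos] <- row$base
    }
  }
  if (its2_break) {
    its2 <- build_its2_template()
    c4 <- its2$cassettes[[4]]
    # replace a contiguous 9-nt block of the cassette-IV 5' stem: the
    # leftover <= 3-pair stubs fall below the helix significance floor
    kill <- c4[1] + 3:11
    chars[annotation$its2[1] - 1L + kill] <- "A"
  }
  if (cpg_rate > 0) {
    i1 <- annotation$its1
    its1_chars <- chars[i1[1]:i1[2]]
    cg <- which(its1_chars[-length(its1_chars)] == "C" & its1_chars[-1L] == "G")
    hits <- with_seed(seed, {
      h <- integer(0)
      for (s in cg) {
        if (stats::runif(1) < cpg_rate) h <- c(h, s)        # C -> T
        if (stats::runif(1) < cpg_rate) h <- c(h, -(s + 1L)) # G -> A
      }
      h
    })
    for (s in hits) {
      if (s > 0) chars[i1[1] - 1L + s] <- "T"
      else chars[i1[1] - 1L - s] <- "A"
    }
    truth$cpg_sites <- hits
  }
  new_ann <- annotation
  if (its1_del41) {
    del <- (annotation$its1[1] - 1L + ITS1_DEL41[1]):(annotation$its1[1] - 1L + ITS1_DEL41[2])
    chars <- chars[-del]
    w <- length(del)
    new_ann <- region_annotation(
      its1 = c(annotation$its1[1], annotation$its1[2] - w),
      r58s = annotation$r58s - w,
      its2 = annotation$its2 - w,
      seq_length = length(chars))
  }
  rec <- its_record(id, paste(chars, collapse = ""), source = template$source,
                    meta = c(template$meta, list(pseudogene = TRUE)))
  list(record = rec, annotation = new_ann, truth = truth)
}

#' Simulate a clone library
#'
#' Clones are drawn from the templates either by fixed `counts` or by
#' `weights` (multinomial), then per-base substitution errors are applied:
#' i.i.d. at rate `error_rate`, or exactly `errors_per_clone` uniformly
#' placed substitutions per clone when that is given.
#'
#' @param templates List of [its_record()].
#' @param n_clones Library size (15-85 in the emulated study).
#' @param error_rate Per-base error probability (<= 0.01).
#' @param weights Mixture weights, summing to 1.
#' @param counts Fixed per-template counts (overrides `weights`).
#' @param errors_per_clone Exact error count per clone (overrides
#'   `error_rate`).
#' @param seed Integer seed.
#' @param accession Prefix for clone ids.
#' @return List: `clones` (list of [its_record()]), `truth` (data.frame
#'   `clone`, `template`).
#' @export
simulate_clones <- function(templates, n_clones = 15L, error_rate = 1 / 600,
                            weights = NULL, counts = NULL,
                            errors_per_clone = NULL, seed = 1L,
                            accession = "acc") {
  templates <- as_record_list(templates)
  k <- length(templates)
  if (is.null(counts)) {
    if (is.null(weights)) weights <- rep(1 / k, k)
    if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  } else {
    if (length(counts) != k || sum(counts) != n_clones)
      stop("'counts' must have one entry per template and sum to n_clones")
  }
  if (error_rate > 0.01) stop("error_rate above 1% is not a clone library")
  with_seed(seed, {
    assign_idx <- if (!is.null(counts)) {
      rep(seq_len(k), counts)
    } else {
      sample.int(k, n_clones, replace = TRUE, prob = weights)
    }
    clones <- vector("list", n_clones)
    for (i in seq_len(n_clones)) {
      chars <- strsplit(templates[[assign_idx[i]]]$sequence, "")[[1]]
      if (!is.null(errors_per_clone)) {
        pos <- sample.int(length(chars), errors_per_clone)
        for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      } else {
        chars <- mutate_seq(chars, error_rate)
      }
      clones[[i]] <- its_record(sprintf("%s_clone%03d", accession, i),
                                paste(chars, collapse = ""), source = "clone",
                                meta = list(accession = accession))
    }
    list(clones = clones,
         truth = data.frame(
           clone = vapply(clones, `[[`, character(1), "id"),
           template = vapply(templates, `[[`, character(1), "id")[assign_idx],
           stringsAsFactors = FALSE))
  })
}

#' Simulate shotgun-style reads over a contig
#'
#' Uniform start positions on both strands with i.i.d. substitution
#' errors; the number of reads is `round(coverage * L / read_len)` so the
#' expected mean read depth equals `coverage`.
#'
#' @param contig An [its_record()].
#' @param coverage Target mean depth (> 0).
#' @param read_len Read length (< contig length).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return List: `reads` (list of [its_record()]), `truth` (data.frame
#'   `read`, `start`, `end`, `strand`).
#' @export
simulate_reads <- function(contig, coverage = 20, read_len = 150L,
                           error_rate = 0.005, seed = 1L) {
  if (coverage <= 0) stop("coverage must be > 0")
  L <- nchar(contig$sequence)
  if (read_len > L) stop("read_len exceeds contig length")
  n_reads <- max(1L, as.integer(round(coverage * L / read_len)))
  with_seed(seed, {
    starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    reads <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      chars <- strsplit(substr(contig$sequence, starts[i], starts[i] + read_len - 1L),
                        "")[[1]]
      chars <- mutate_seq(chars, error_rate)
      s <- paste(chars, collapse = "")
      if (strands[i] == "-")
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      reads[[i]] <- its_record(sprintf("%s_read%05d", contig$id, i), s,
                               source = "read")
    }
    list(reads = reads,
         truth = data.frame(
           read = vapply(reads, `[[`, character(1), "id"),
           start = starts, end = starts + read_len - 1L, strand = strands,
           stringsAsFactors = FALSE))
  })
}

#' Seeded functional/pseudogene benchmark cohort
#'
#' Generates `n_each` functional records (lineage templates plus light
#' within-lineage divergence) and `n_each` pseudogenised derivatives, each
#' carrying one or two randomly drawn intrinsic defects (motif hits from
#' the described repertoire, a helix-constraint break, or an ITS2 stem
#' disruption), CpG deamination, and occasionally the 41-bp ITS1
#' deletion. Truth labels are returned for sensitivity/specificity
#' scoring.
#'
#' @param n_each Records per class (default 50).
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return List: `records`, `truth` (data.frame `id`, `pseudogene`).
#' @export
simulate_pseudogene_cohort <- function(n_each = 50L, spec = synthetic_spec(),
                                       seed = spec$seed) {
  tmpl <- generate_templates(spec, seed = seed)
  an <- tmpl$annotation
  leaves <- tmpl$records
  motif_menu <- list(list(M1 = c(11L, 16L)), list(M1 = 12L),
                     list(M2 = c(9L, 14L)), list(M3 = c(7L, 8L)))
  helix_menu <- helix_break_map()$helix
  with_seed(seed + 1L, {
    func <- lapply(seq_len(n_each), function(i) {
      base <- leaves[[((i - 1L) %% length(leaves)) + 1L]]
      chars <- mutate_functional(strsplit(base$sequence, "")[[1]],
                                 0.005 * tmpl$rate_mask, an)
      its_record(sprintf("func%03d", i), paste(chars, collapse = ""),
                 source = "consensus", meta = base$meta)
    })
    pseudo <- lapply(seq_len(n_each), function(i) {
      base <- leaves[[((i - 1L) %% length(leaves)) + 1L]]
      kind <- sample(c("motif", "helix", "its2", "motif+helix"), 1L)
      mh <- if (kind %in% c("motif", "motif+helix"))
        motif_menu[[sample.int(length(motif_menu), 1L)]] else list()
      hb <- if (kind %in% c("helix", "motif+helix"))
        sample(helix_menu, 1L) else character(0)
      ps <- pseudogenize(base, an, cpg_rate = spec$pseudo_cpg_rate,
                         motif_hits = mh, helix_breaks = hb,
                         its2_break = (kind == "its2"),
                         its1_del41 = stats::runif(1) < 0.2,
                         id = sprintf("psi%03d", i))
      ps$record
    })
    records <- c(func, pseudo)
    list(records = records,
         truth = data.frame(
           id = vapply(records, `[[`, character(1), "id"),
           pseudogene = rep(c(FALSE, TRUE), each = n_each),
           stringsAsFactors = FALSE))
  })
}
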