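## End-to-end orchestration: delimit -> stats -> motifs -> fold ->
## classify -> type -> tree -> assign, plain files plus a JSON run
## manifest.

#' Write the packaged demo dataset
#'
#' Emits the synthetic default study into a directory: lineage templates
#' (`templates.fa` + `labels.tsv`), one polymorphic clone library
#' (`clones_<acc>.fa`), a hybrid accession library mixing two parental
#' types, and shotgun reads over one template contig.
#'
#' @param dir Output directory (created if missing).
#' @param spec A [synthetic_spec()].
#' @param seed Overrides `spec$seed`.
#' @return Invisibly, the list of written paths.
#' @export
write_demo_fixtures <- function(dir, spec = synthetic_spec(), seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tmpl <- generate_templates(spec, seed = seed)
  paths <- c(templates = file.path(dir, "templates.fa"),
             labels = file.path(dir, "labels.tsv"),
             clones = file.path(dir, "clones_ACC1.fa"),
             hybrid = file.path(dir, "clones_HYB1.fa"),
             reads = file.path(dir, "reads.fa"),
             contig = file.path(dir, "contig.fa"))
  write_its_fasta(unname(tmpl$records), paths["templates"])
  utils::write.table(
    data.frame(id = names(tmpl$records), genome = names(tmpl$records)),
    paths["labels"], sep = "\t", quote = FALSE, row.names = FALSE)
  # heterogeneous diploid: one functional + one pseudogenised paralog
  ps <- pseudogenize(tmpl$records$A, tmpl$annotation,
                     motif_hits = list(M1 = c(11L, 16L)),
                     cpg_rate = spec$pseudo_cpg_rate,
                     id = "A_psi", seed = seed + 11L)
  lib1 <- simulate_clones(list(tmpl$records$A, ps$record),
                          n_clones = spec$n_clones,
                          counts = c(ceiling(spec$n_clones / 2),
                                     floor(spec$n_clones / 2)),
                          error_rate = spec$clone_error,
                          seed = seed + 2L, accession = "ACC1")
  write_its_fasta(lib1$clones, paths["clones"])
  # hybrid accession: A- and B-derived types
  lib2 <- simulate_clones(list(tmpl$records$A, tmpl$records$B),
                          n_clones = spec$n_clones,
                          counts = c(ceiling(spec$n_clones / 2),
                                     floor(spec$n_clones / 2)),
                          error_rate = spec$clone_error,
                          seed = seed + 3L, accession = "HYB1")
  write_its_fasta(lib2$clones, paths["hybrid"])
  rds <- simulate_reads(tmpl$records$T, coverage = spec$read_coverage,
                        read_len = spec$read_len,
                        error_rate = spec$read_error, seed = seed + 4L)
  write_its_fasta(rds$reads, paths["reads"])
  write_its_fasta(tmpl$records$T, paths["contig"])
  invisible(as.list(paths))
}

pipeline_config_defaults <- function() {
  list(seed = 1L, min_58s_identity = 0.6, min_type_identity = 99.0,
       min_members = 2L, bootstrap = 100L, model = "jc",
       min_read_identity = 90, min_read_len = 50L)
}

#' Read a key=value pipeline configuration file
#'
#' Plain-text `key = value` lines (\code{#} comments allowed); numeric
#' values are coerced. Unknown keys are kept verbatim.
#'
#' @param path Config file.
#' @return Named list merged over [pipeline_config_defaults()][run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  cfg <- pipeline_config_defaults()
  for (l in lines) {
    kv <- strsplit(l, "\\s*=\\s*")[[1]]
    val <- kv[2]
    num <- suppressWarnings(as.numeric(val))
    cfg[[kv[1]]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' Run the full ITS profiling pipeline on a directory
#'
#' Expects the file layout of [write_demo_fixtures()] (a `templates.fa`
#' plus `labels.tsv` reference panel, zero or more `clones_*.fa`
#' libraries, optionally `reads.fa` + `contig.fa`) and writes
#' `regions.tsv`, `composition.tsv`, `motifs.tsv`, `structure.tsv`,
#' `verdicts.tsv`, `types.fa`, `tree.nwk`, `assignments.tsv`, `rd.tsv`
#' and a JSON `manifest.json` with config, seed and file hashes into
#' `outdir`. Deterministic stages reproduce identical hashes on rerun.
#'
#' @param indir Input directory.
#' @param outdir Output directory (default `<indir>/out`).
#' @param config Named list overriding the defaults (seed, thresholds,
#'   bootstrap replicates), or a path to a `key = value` file.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(indir, outdir = file.path(indir, "out"), config = list()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(pipeline_config_defaults(), config)
  if (!dir.exists(indir)) stop("input directory does not exist: ", indir)
  tpath <- file.path(indir, "templates.fa")
  if (!file.exists(tpath))
    stop("no templates.fa in ", indir, "; nothing to run")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  templates <- stage("read", read_its_fasta(tpath, source = "consensus"))
  regions <- stage("delimit",
                   delimit_set(templates, min_58s_identity = cfg$min_58s_identity))
  utils::write.table(regions, file.path(outdir, "regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  anns <- lapply(seq_len(nrow(regions)), function(i)
    regions_row_to_annotation(regions[i, ]))
  comp <- stage("stats", do.call(rbind, Map(composition_report, templates, anns)))
  utils::write.table(comp, file.path(outdir, "composition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  mot <- stage("motifs", do.call(rbind, Map(function(r, a)
    motif_reports_table(scan_58s_motifs(region_seq(r, a, "r58s")), id = r$id),
    templates, anns)))
  utils::write.table(mot, file.path(outdir, "motifs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  struct <- stage("fold", Map(structure_report, templates, anns))
  struct_df <- do.call(rbind, lapply(struct, function(s)
    data.frame(id = s$id, its2_n_helices = s$its2_n_helices,
               tggt = s$tggt_in_helix3, bulge = s$pyr_pyr_bulge_helix2,
               its2_ok = s$overall_its2_ok, r58s_ok = s$overall_58s_ok)))
  utils::write.table(struct_df, file.path(outdir, "structure.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  verdicts <- stage("classify", classify_set(templates))
  utils::write.table(verdicts, file.path(outdir, "verdicts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  clone_files <- list.files(indir, pattern = "^clones_.*\\.fa$", full.names = TRUE)
  all_types <- list()
  for (cf in clone_files) {
    acc <- sub("^clones_(.*)\\.fa$", "\\1", basename(cf))
    clones <- stage("type", read_its_fasta(cf, source = "clone"))
    msa <- stage("type", align_its_set(clones))
    ts <- stage("type", cluster_its_types(msa, cfg$min_type_identity,
                                          cfg$min_members, accession = acc))
    all_types <- c(all_types, lapply(ts$types, `[[`, "consensus"))
  }
  if (length(all_types))
    write_its_fasta(all_types, file.path(outdir, "types.fa"))

  ref_msa <- stage("tree", align_its_set(templates))
  tree <- stage("tree", if (length(templates) >= 4L)
    bootstrap_support(ref_msa, n_replicates = cfg$bootstrap,
                      seed = cfg$seed, model = cfg$model)
    else neighbor_joining(distance_matrix(ref_msa, model = cfg$model)))
  write_newick(midpoint_root(tree), file.path(outdir, "tree.nwk"))

  lab_path <- file.path(indir, "labels.tsv")
  if (length(all_types) && file.exists(lab_path)) {
    labs <- utils::read.table(lab_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    labels <- stats::setNames(labs$genome, labs$id)
    asg <- stage("assign", assign_genome(all_types, ref_msa, labels,
                                         model = cfg$model))
    utils::write.table(asg, file.path(outdir, "assignments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  rpath <- file.path(indir, "reads.fa"); cpath <- file.path(indir, "contig.fa")
  if (file.exists(rpath) && file.exists(cpath)) {
    contig <- read_its_fasta(cpath, source = "consensus")[[1]]
    reads <- read_its_fasta(rpath, source = "read")
    pl <- stage("rd", place_reads(reads, contig, cfg$min_read_identity,
                                  cfg$min_read_len))
    prof <- stage("rd", depth_profile(pl))
    utils::write.table(
      data.frame(position = seq_along(prof$depth), depth = prof$depth),
      file.path(outdir, "rd.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }

  outputs <- list.files(outdir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(config = cfg, seed = cfg$seed,
                   inputs = as.list(tools::md5sum(
                     list.files(indir, full.names = TRUE, pattern = "\\.(fa|tsv)$"))),
                   outputs = as.list(tools::md5sum(outputs)),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
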