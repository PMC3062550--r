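make_reports <- function(record, annotation) {
  list(comp = composition_report(record, annotation),
       motifs = scan_58s_motifs(region_seq(record, annotation, "r58s")),
       struct = structure_report(record, annotation))
}

fake_cohort <- function(n = 10, gc_mean = 0.5, gc_sd = 0.01, its1_len = 219L) {
  data.frame(id = paste0("c", seq_len(n)),
             its1_len = its1_len, total_gc = gc_mean + gc_sd * scale(seq_len(n))[, 1])
}

test_that("clean records are functional, intrinsic defects are putative pseudogenes", {
  sr <- ref_fixture()
  rp <- make_reports(sr$record, sr$annotation)
  cohort <- rbind(rp$comp, rp$comp, rp$comp)
  v <- classify_its(rp$comp, rp$motifs, rp$struct, cohort)
  expect_equal(v$status, "functional")
  expect_length(v$evidence, 0)

  ps <- pseudogenize(sr$record, sr$annotation,
                     motif_hits = list(M2 = c(9L, 14L)), helix_breaks = "B4")
  rp2 <- make_reports(ps$record, ps$annotation)
  v2 <- classify_its(rp2$comp, rp2$motifs, rp2$struct, cohort)
  expect_equal(v2$status, "putative_pseudogene")
  expect_true(any(grepl("motif_disruption\\(M2@9,14\\)", v2$evidence)))
  expect_true(any(grepl("r58s_constraint_fail\\(B4\\)", v2$evidence)))
})

test_that("cohort-relative anomalies alone only raise suspicion", {
  sr <- ref_fixture()
  rp <- make_reports(sr$record, sr$annotation)
  gc_here <- rp$comp$total_gc
  low_gc_cohort <- fake_cohort(10, gc_mean = gc_here + 0.05, gc_sd = 0.01)
  v <- classify_its(rp$comp, rp$motifs, rp$struct, low_gc_cohort)
  expect_equal(v$status, "suspect")
  expect_true(any(grepl("low_gc", v$evidence)))

  short_cohort <- fake_cohort(10, gc_mean = gc_here, gc_sd = 0.05, its1_len = 300L)
  v2 <- classify_its(rp$comp, rp$motifs, rp$struct, short_cohort)
  expect_equal(v2$status, "suspect")
  expect_true(any(grepl("length_anomaly", v2$evidence)))

  expect_error(classify_its(rp$comp, rp$motifs, rp$struct, cohort = NULL),
               "cohort")
  v3 <- classify_its(rp$comp, rp$motifs, rp$struct, use_gc_rule = FALSE)
  expect_equal(v3$status, "functional")
})

test_that("verdicts are monotone in injected defects", {
  sr <- ref_fixture()
  rank <- c(functional = 0, suspect = 1, putative_pseudogene = 2)
  cohort <- rbind(make_reports(sr$record, sr$annotation)$comp)[rep(1, 3), ]
  status_of <- function(...) {
    ps <- pseudogenize(sr$record, sr$annotation, ...)
    rp <- make_reports(ps$record, ps$annotation)
    classify_its(rp$comp, rp$motifs, rp$struct, cohort)$status
  }
  base <- status_of()
  one <- status_of(motif_hits = list(M1 = 12L))
  two <- status_of(motif_hits = list(M1 = 12L), helix_breaks = "B6")
  three <- status_of(motif_hits = list(M1 = 12L), helix_breaks = "B6",
                     its2_break = TRUE)
  expect_true(rank[base] <= rank[one])
  expect_true(rank[one] <= rank[two])
  expect_true(rank[two] <= rank[three])
})

test_that("CpG transition counting matches hand-checked cases", {
  expect_equal(cpg_transition_excess("ATGT", "ACGT")$count, 1L)
  r <- cpg_transition_excess("ACGT", "ACGT")
  expect_equal(r$count, 0L)
  expect_false(r$flag)
  # template with 10 CpG sites, deamination at 6 of them, no other change
  template <- paste(rep("CGAAT", 10), collapse = "")
  ch <- strsplit(template, "")[[1]]
  hit_sites <- c(1, 6, 11, 16, 21, 26)
  ch[hit_sites] <- "T"
  r2 <- cpg_transition_excess(paste(ch, collapse = ""), template)
  expect_equal(r2$count, 6L)
  expect_true(r2$flag)
  # G-side deamination, template gaps skipped in CpG context
  expect_equal(cpg_transition_excess("ACAT", "ACGT")$count, 1L)
  expect_equal(cpg_transition_excess("AC-AT", "AC-GT")$count, 1L)
  expect_error(cpg_transition_excess("ACG", "ACGT"), "aligned")
})

test_that("classify_set recovers injected truth on a small cohort", {
  sr <- ref_fixture()
  recs <- list(
    its_record("f1", sr$record$sequence),
    its_record("f2", sr$record$sequence),
    its_record("f3", sr$record$sequence),
    pseudogenize(sr$record, sr$annotation, motif_hits = list(M1 = c(11L, 16L)),
                 id = "p1")$record,
    pseudogenize(sr$record, sr$annotation, helix_breaks = "B7",
                 id = "p2")$record)
  v <- classify_set(recs)
  expect_equal(v$status[v$id %in% c("f1", "f2", "f3")], rep("functional", 3))
  expect_equal(v$status[v$id %in% c("p1", "p2")], rep("putative_pseudogene", 2))
})
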