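test_that("zero divergence reproduces the root at every leaf", {
  spec <- synthetic_spec(seed = 5, lineage = "((a:0,b:0):0,c:0,d:0);")
  tm <- generate_templates(spec)
  root <- synthetic_reference()$record$sequence
  for (r in tm$records) expect_equal(r$sequence, root)
})

test_that("observed ITS1 divergence sits inside the binomial envelope", {
  p <- 0.05
  spec <- synthetic_spec(seed = 6,
                         lineage = sprintf("(x:%f,y:0,z:0);", p))
  tm <- generate_templates(spec)
  an <- tm$annotation
  a <- strsplit(region_seq(tm$records$x, an, "its1"), "")[[1]]
  b <- strsplit(region_seq(tm$records$z, an, "its1"), "")[[1]]
  n <- length(a)
  k <- sum(a != b)
  ci <- qbinom(c(0.0005, 0.9995), n, p)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("default templates are functional with intact landmarks", {
  tm <- templates_fixture()
  an <- tm$annotation
  for (r in tm$records) {
    mots <- scan_58s_motifs(region_seq(r, an, "r58s"))
    expect_true(all(vapply(mots, function(m) m$n_mismatches == 0L, logical(1))),
                label = r$id)
    st <- structure_report(r, an)
    expect_true(st$overall_its2_ok && st$overall_58s_ok, label = r$id)
  }
  expect_error(generate_templates(synthetic_spec(lineage = "(a:0.9,b:0,c:0);")),
               "0.75")
})

test_that("the pseudogenising operators are exact and composable", {
  sr <- ref_fixture()
  # no-op call returns the input sequence
  id0 <- pseudogenize(sr$record, sr$annotation)
  expect_equal(id0$record$sequence, sr$record$sequence)
  expect_equal(unclass(id0$annotation), unclass(sr$annotation), ignore_attr = TRUE)
  # 41-bp ITS1 deletion: 585-nt region becomes 544
  del <- pseudogenize(sr$record, sr$annotation, its1_del41 = TRUE)
  expect_equal(nchar(region_seq(del$record, del$annotation, "total")), 544L)
  expect_equal(nchar(del$record$sequence), nchar(sr$record$sequence) - 41L)
  # requesting hits on a motif the template no longer carries errors
  ps <- pseudogenize(sr$record, sr$annotation, motif_hits = list(M1 = c(11L, 16L)))
  expect_error(pseudogenize(ps$record, ps$annotation,
                            motif_hits = list(M1 = 11L)), "canonical")
  # CpG deamination lowers ITS1 GC and is flagged by the transition counter
  cp <- pseudogenize(sr$record, sr$annotation, cpg_rate = 0.8, seed = 3)
  its1_t <- region_seq(sr$record, sr$annotation, "its1")
  its1_p <- region_seq(cp$record, cp$annotation, "its1")
  expect_lt(gc_content(its1_p), gc_content(its1_t))
  flag <- cpg_transition_excess(its1_p, its1_t)
  expect_true(flag$flag)
  expect_equal(flag$count, flag$n_substitutions)
})

test_that("clone simulation follows counts, weights and error models", {
  sr <- ref_fixture()
  x <- its_record("x", sr$record$sequence)
  lib0 <- simulate_clones(list(x), n_clones = 5, error_rate = 0, seed = 1)
  expect_true(all(vapply(lib0$clones, function(c) c$sequence == x$sequence,
                         logical(1))))
  expect_error(simulate_clones(list(x), weights = c(0.5), n_clones = 5), "sum")
  expect_error(simulate_clones(list(x), counts = 4, n_clones = 5), "counts")
  expect_error(simulate_clones(list(x), error_rate = 0.05), "1%")
  # i.i.d. error count over many clones matches the binomial expectation
  lib <- simulate_clones(list(x), n_clones = 400, error_rate = 1 / 600, seed = 2)
  L <- nchar(x$sequence)
  errs <- vapply(lib$clones, function(c)
    sum(strsplit(c$sequence, "")[[1]] != strsplit(x$sequence, "")[[1]]),
    numeric(1))
  total <- sum(errs)
  ci <- qbinom(c(0.0005, 0.9995), 400 * L, 1 / 600)
  expect_gte(total, ci[1]); expect_lte(total, ci[2])
  # exact-error mode places exactly one substitution
  lib1 <- simulate_clones(list(x), n_clones = 10, errors_per_clone = 1, seed = 3)
  errs1 <- vapply(lib1$clones, function(c)
    sum(strsplit(c$sequence, "")[[1]] != strsplit(x$sequence, "")[[1]]),
    numeric(1))
  expect_equal(errs1, rep(1, 10))
})

test_that("read simulation respects its contracts", {
  sr <- ref_fixture()
  ctg <- its_record("ctg", sr$record$sequence)
  one <- simulate_reads(ctg, coverage = 1, read_len = nchar(ctg$sequence),
                        error_rate = 0, seed = 4)
  expect_length(one$reads, 1L)
  exact <- simulate_reads(ctg, coverage = 3, read_len = 100, error_rate = 0, seed = 5)
  for (i in seq_along(exact$reads)) {
    s <- exact$reads[[i]]$sequence
    if (exact$truth$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(s, substr(ctg$sequence, exact$truth$start[i], exact$truth$end[i]))
  }
  rd <- simulate_reads(ctg, coverage = 20, read_len = 150, error_rate = 0.005, seed = 6)
  prof <- depth_profile(rd$truth, contig_length = nchar(ctg$sequence))
  expect_gt(prof$mean_rd, 17); expect_lt(prof$mean_rd, 23)
  expect_error(simulate_reads(ctg, coverage = 0), "coverage")
  expect_error(simulate_reads(ctg, read_len = 10000), "read_len")
})

test_that("identical seeds give byte-identical synthetic output", {
  a <- generate_templates(synthetic_spec(seed = 9))
  b <- generate_templates(synthetic_spec(seed = 9))
  expect_identical(lapply(a$records, `[[`, "sequence"),
                   lapply(b$records, `[[`, "sequence"))
  l1 <- simulate_clones(list(a$records$A), n_clones = 15, seed = 10)
  l2 <- simulate_clones(list(b$records$A), n_clones = 15, seed = 10)
  expect_identical(lapply(l1$clones, `[[`, "sequence"),
                   lapply(l2$clones, `[[`, "sequence"))
  r1 <- simulate_reads(a$records$A, seed = 11)
  r2 <- simulate_reads(b$records$A, seed = 11)
  expect_identical(lapply(r1$reads, `[[`, "sequence"),
                   lapply(r2$reads, `[[`, "sequence"))
  # and the generator does not disturb the caller's RNG stream
  set.seed(123); x <- runif(1)
  set.seed(123); invisible(generate_templates(synthetic_spec(seed = 9)))
  expect_identical(runif(1), x)
})
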