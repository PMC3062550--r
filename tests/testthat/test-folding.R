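test_that("simple folds are exact", {
  # single hairpin: GGG AAAA CCC has a unique 3-pair optimum; pad to the
  # 40-nt length floor with unpairable A/C filler on both sides
  seq <- paste0(strrep("A", 15), "GGGAAAACCC", strrep("A", 15))
  f <- fold_its2(seq)
  expect_equal(f$score, 3L)
  expect_equal(f$pairs[, 2] + f$pairs[, 1],
               rep(41, 3))  # (16,25),(17,24),(18,23)
  expect_equal(length(f$helices), 1L)
  f0 <- fold_its2(strrep("A", 50))
  expect_equal(f0$score, 0L)
  expect_equal(length(f0$helices), 0L)
})

test_that("fold score equals the exhaustive maximum on short random sequences", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(5:14, 1)
    s <- random_dna(n)
    expect_equal(nrow(itsprofiler:::.nussinov_pairs(s, 3L)), max_pairs_brute(s),
                 label = s)
  }
})

test_that("folding is deterministic", {
  set.seed(22)
  s <- random_dna(80)
  f1 <- fold_its2(s); f2 <- fold_its2(s)
  expect_identical(f1$pairs, f2$pairs)
})

test_that("N handling: never pairs, heavy N refuses to fold", {
  f <- fold_its2(paste0(strrep("A", 18), "GNG", strrep("A", 4), "CNC", strrep("A", 18)))
  ch <- strsplit(dot_bracket(f), "")[[1]]
  expect_equal(ch[c(20, 27)], c(".", "."))  # the N positions stay unpaired
  expect_error(fold_its2(paste0(strrep("N", 30), strrep("A", 30))), "refusing")
})

test_that("the designed ITS2 shows the four-helix topology with its landmarks", {
  sr <- ref_fixture()
  its2 <- region_seq(sr$record, sr$annotation, "its2")
  f <- fold_its2(its2)
  topo <- its2_topology(f, its2)
  expect_equal(topo$its2_n_helices, 4L)
  expect_true(topo$tggt_in_helix3)
  expect_true(topo$pyr_pyr_bulge_helix2)
  expect_true(topo$overall_its2_ok)
  # helices come out in 5'->3' cassette order
  spans <- build_its2_template()$cassettes
  hx <- Filter(function(h) nrow(h) >= 5, f$helices)
  for (k in 1:4) {
    expect_gte(min(hx[[k]][, 1]), spans[[k]][1])
    expect_lte(max(hx[[k]][, 2]), spans[[k]][2])
  }
})

test_that("topology landmarks respond to targeted edits", {
  sr <- ref_fixture()
  its2 <- region_seq(sr$record, sr$annotation, "its2")
  # TGGT -> TGCT kills the helix III landmark
  mut <- sub("TGGT", "TGCT", its2, fixed = TRUE)
  topo <- its2_topology(fold_its2(mut), mut)
  expect_false(topo$tggt_in_helix3)
  # removing cassette IV leaves a three-helix spacer
  spans <- build_its2_template()$cassettes
  trunc <- paste0(substr(its2, 1, spans[[3]][2]), strrep("A", 13))
  topo3 <- its2_topology(fold_its2(trunc), trunc)
  expect_equal(topo3$its2_n_helices, 3L)
  expect_false(topo3$overall_its2_ok)
  # the pseudogenising stem-IV break does the same in place
  ps <- pseudogenize(sr$record, sr$annotation, its2_break = TRUE)
  its2b <- region_seq(ps$record, ps$annotation, "its2")
  expect_lt(its2_topology(fold_its2(its2b), its2b)$its2_n_helices, 4L)
})

test_that("5.8S helix constraints pass on the design and fail pair by pair", {
  sr <- ref_fixture()
  r58 <- region_seq(sr$record, sr$annotation, "r58s")
  res <- check_58s_constraints(r58)
  expect_true(all(res))
  # breaking one prescribed pair flips exactly the targeted helix
  hc <- helix_constraints()
  ch0 <- strsplit(r58, "")[[1]]
  ch <- ch0
  ch[38] <- "C"  # (38, 98) becomes C:T, non-canonical
  res2 <- check_58s_constraints(paste(ch, collapse = ""))
  expect_false(res2[["B4"]])
  expect_true(all(res2[setdiff(hc$helix, "B4")]))
  expect_error(check_58s_constraints(substr(r58, 1, 130)), "too short")
})

test_that("constraint checks depend only on the constrained positions", {
  sr <- ref_fixture()
  r58 <- region_seq(sr$record, sr$annotation, "r58s")
  res0 <- check_58s_constraints(r58)
  cons <- itsprofiler:::constrained_58s_positions()
  free <- setdiff(seq_len(nchar(r58)), cons)
  set.seed(23)
  for (i in 1:20) {
    ch <- strsplit(r58, "")[[1]]
    hit <- sample(free, 5)
    ch[hit] <- sample(c("A", "C", "G", "T"), 5, replace = TRUE)
    expect_equal(check_58s_constraints(paste(ch, collapse = "")), res0)
  }
})
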