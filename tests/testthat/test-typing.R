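test_that("progressive alignment handles identity and single indels", {
  s <- random_dna(320)
  m <- align_its_set(list(its_record("a", s), its_record("b", s)))
  expect_equal(m$n_col, 320)
  expect_false(any(grepl("-", m$rows, fixed = TRUE)))
  # one deleted base -> exactly one gap column
  ch <- strsplit(s, "")[[1]]
  m2 <- align_its_set(list(its_record("a", s),
                           its_record("b", paste(ch[-150], collapse = ""))))
  expect_equal(m2$n_col, 320)
  expect_equal(sum(strsplit(m2$rows[["b"]], "")[[1]] == "-"), 1L)
  expect_equal(ungap(m2$rows[["a"]]), s)
})

test_that("alignment round-trips clone libraries and ignores input order", {
  tm <- templates_fixture()
  lib <- simulate_clones(list(tm$records$A), n_clones = 10,
                         error_rate = 0.002, seed = 31, accession = "rt")
  m <- align_its_set(lib$clones)
  expect_gte(m$n_col, nchar(tm$records$A$sequence))
  for (cl in lib$clones)
    expect_equal(ungap(m$rows[[cl$id]]), cl$sequence)
  m2 <- align_its_set(rev(lib$clones))
  expect_identical(m2$rows, m$rows)
})

test_that("uniform libraries collapse to a single type", {
  s <- random_dna(400)
  recs <- lapply(1:6, function(i) its_record(paste0("c", i), s, source = "clone"))
  ts <- cluster_its_types(align_its_set(recs), accession = "one")
  expect_length(ts$types, 1L)
  expect_equal(ts$types[[1]]$support, 6L)
  expect_equal(ts$types[[1]]$consensus$sequence, s)
})

test_that("three well-separated templates give three types matching a Hamming oracle", {
  set.seed(41)
  base <- random_dna(600)
  tpls <- list(base,
               mutate_string(base, sample(600, 12), sample(c("A", "C", "G", "T"), 12, TRUE)),
               mutate_string(base, sample(600, 24), sample(c("A", "C", "G", "T"), 24, TRUE)))
  tpls <- lapply(seq_along(tpls), function(i)
    its_record(paste0("T", i), tpls[[i]], source = "consensus"))
  lib <- simulate_clones(tpls, n_clones = 20, counts = c(7, 7, 6),
                         errors_per_clone = 1, seed = 55, accession = "tri")
  msa <- align_its_set(lib$clones)
  ts <- cluster_its_types(msa, accession = "tri")
  expect_length(ts$types, 3L)
  # brute-force nearest-template assignment agrees for every clone
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (ty in ts$types) {
    for (member in ty$members) {
      cl <- lib$clones[[which(lib$truth$clone == member)]]
      d <- vapply(tpls, function(t) ham(cl$sequence, t$sequence), numeric(1))
      truth_tpl <- lib$truth$template[lib$truth$clone == member]
      expect_equal(paste0("T", which.min(d)), truth_tpl)
      expect_equal(ty$consensus$sequence,
                   tpls[[which.min(d)]]$sequence)
    }
  }
})

test_that("type count is invariant to clone order and consensus is idempotent", {
  tm <- templates_fixture()
  an <- tm$annotation
  x <- its_record("X", region_seq(tm$records$A, an, "total"), source = "consensus")
  y <- its_record("Y", region_seq(tm$records$B, an, "total"), source = "consensus")
  lib <- simulate_clones(list(x, y), n_clones = 12, counts = c(6, 6),
                         errors_per_clone = 1, seed = 77, accession = "ord")
  ts1 <- cluster_its_types(align_its_set(lib$clones), accession = "ord")
  set.seed(1)
  ts2 <- cluster_its_types(align_its_set(sample(lib$clones)), accession = "ord")
  expect_equal(length(ts1$types), length(ts2$types))
  # re-cluster each consensus with its members: it joins its own type
  for (ty in ts1$types) {
    members <- lib$clones[vapply(lib$clones, function(c) c$id %in% ty$members, logical(1))]
    again <- cluster_its_types(
      align_its_set(c(members, list(ty$consensus))), accession = "re")
    home <- Filter(function(t) ty$consensus$id %in% t$members, again$types)
    expect_length(home, 1L)
    expect_setequal(home[[1]]$members, c(ty$members, ty$consensus$id))
  }
})

test_that("singletons are absorbed and thresholds validated", {
  set.seed(61)
  base <- random_dna(400)
  far <- mutate_string(base, sample(400, 30), sample(c("A", "C", "G", "T"), 30, TRUE))
  recs <- c(lapply(1:5, function(i) its_record(paste0("m", i), base, source = "clone")),
            list(its_record("lone", far, source = "clone")))
  ts <- cluster_its_types(align_its_set(recs), accession = "sing")
  expect_length(ts$types, 1L)
  expect_true("lone" %in% ts$absorbed_singletons)
  expect_error(cluster_its_types(align_its_set(recs), min_type_identity = 80),
               "90")
})
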