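test_that("p-distance uses pairwise deletion of gaps and N", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(p_distance(a, b), 0.1)
  # hand count: columns 1 (gap) and 4 (N) drop; 1 diff over 2 sites
  expect_equal(p_distance("-CGN", "ACTT"), 0.5)
  expect_error(p_distance("---", "AAA"), "zero compared")
})

test_that("Jukes-Cantor correction matches the closed form and its domain", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.1), -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_equal(round(jc_distance(0.1), 6), 0.107326)
  expect_true(is.finite(jc_distance(0.74)))
  expect_error(jc_distance(0.75), "saturation")
  p <- seq(0, 0.74, by = 0.01)
  expect_true(all(diff(jc_distance(p)) > 0))
})

test_that("neighbour joining solves the three-taxon case in closed form", {
  m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(m)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("neighbour joining is exact on additive matrices", {
  set.seed(71)
  for (i in 1:10) {
    g <- ape::unroot(ape::rtree(sample(4:8, 1), br = function(k) runif(k, 0.1, 1)))
    D <- ape::cophenetic.phylo(g)
    tr <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(tr, g), 0)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("degenerate and invalid matrices are handled", {
  m <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  tr <- suppressMessages(neighbor_joining(m))
  term <- tr$edge.length[tr$edge[, 2] <= 4]
  expect_equal(term, rep(term[1], 4))  # all terminal branches equal
  bad <- m; bad[1, 2] <- 5
  expect_error(neighbor_joining(bad), "symmetric")
  nan <- m; nan[1, 2] <- nan[2, 1] <- NaN
  expect_error(neighbor_joining(nan), "finite")
  expect_error(neighbor_joining(m[1:2, 1:2]), "at least 3")
})

test_that("bootstrap supports are seeded, bounded and reproducible", {
  set.seed(72)
  base <- strsplit(random_dna(300), "")[[1]]
  sep <- sample(300, 30)
  other <- base
  other[sep] <- vapply(base[sep], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "x")
  rows <- c(
    lapply(1:3, function(i) {
      r <- base; p <- sample(setdiff(1:300, sep), 3)
      for (q in p) r[q] <- sample(setdiff(c("A", "C", "G", "T"), r[q]), 1)
      paste(r, collapse = "")
    }),
    lapply(1:3, function(i) {
      r <- other; p <- sample(setdiff(1:300, sep), 3)
      for (q in p) r[q] <- sample(setdiff(c("A", "C", "G", "T"), r[q]), 1)
      paste(r, collapse = "")
    }))
  msa <- msa_block(c("a1", "a2", "a3", "b1", "b2", "b3"), unlist(rows))
  t1 <- bootstrap_support(msa, n_replicates = 100, seed = 5)
  t2 <- bootstrap_support(msa, n_replicates = 100, seed = 5)
  expect_identical(t1$node.label, t2$node.label)
  sup <- as.numeric(t1$node.label)
  expect_true(all(sup >= 0 & sup <= 100))
  expect_error(bootstrap_support(msa, n_replicates = 0), "n_replicates")
})

test_that("midpoint rooting follows the longest path and is idempotent", {
  # symmetric quartet: root lands mid central edge, two equal-depth sides
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  r <- midpoint_root(ape::unroot(tr))
  dep <- ape::node.depth.edgelength(r)
  expect_equal(max(dep[1:4]) , 2)
  expect_true(ape::is.rooted(r))
  # caterpillar with one long terminal branch: root sits on that branch
  cat_tr <- ape::unroot(ape::read.tree(
    text = "(((a:0.1,b:0.1):0.1,c:0.1):0.1,d:5);"))
  r2 <- midpoint_root(cat_tr)
  root_children <- r2$edge[r2$edge[, 1] == ape::Ntip(r2) + 1, 2]
  expect_true(which(r2$tip.label == "d") %in% root_children)
  r3 <- midpoint_root(r2)
  expect_equal(phangorn::RF.dist(ape::unroot(r2), ape::unroot(r3)), 0)
  expect_equal(sort(ape::node.depth.edgelength(r3)[1:4]),
               sort(ape::node.depth.edgelength(r2)[1:4]), tolerance = 1e-9)
  zero <- tr; zero$edge.length[] <- 0
  expect_error(midpoint_root(zero), "non-zero")
})

test_that("genome assignment places identical and hybrid-derived queries", {
  tm <- templates_fixture()
  refs <- list(); labels <- c()
  set.seed(73)
  for (g in c("A", "B", "S", "T")) {
    for (k in 1:2) {
      seqv <- itsprofiler:::mutate_seq(
        strsplit(tm$records[[g]]$sequence, "")[[1]], 0.002)
      id <- sprintf("%s_ref%d", g, k)
      refs[[id]] <- its_record(id, paste(seqv, collapse = ""), source = "consensus")
      labels[id] <- g
    }
  }
  ref_msa <- align_its_set(refs)
  # a query equal to a reference goes to that reference's genome
  q0 <- its_record("q0", refs[["S_ref1"]]$sequence, source = "consensus")
  a0 <- assign_genome(list(q0), ref_msa, labels)
  expect_equal(a0$genome, "S")
  expect_gt(a0$margin, 0)
  # hybrid with one A-derived and one B-derived type
  qa <- its_record("qa", paste(itsprofiler:::mutate_seq(
    strsplit(tm$records$A$sequence, "")[[1]], 0.003), collapse = ""))
  qb <- its_record("qb", paste(itsprofiler:::mutate_seq(
    strsplit(tm$records$B$sequence, "")[[1]], 0.003), collapse = ""))
  ah <- assign_genome(list(qa, qb), ref_msa, labels)
  expect_equal(ah$genome, c("A", "B"))
  expect_error(assign_genome(list(q0), ref_msa, labels[-1]), "without genome label")
})
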