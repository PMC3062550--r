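# Shared fixtures and independent oracles. Everything is built in code;
# expensive shared objects are computed once per test run.

ref_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_reference()
    cache
  }
})

templates_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_templates(synthetic_spec(seed = 11))
    cache
  }
})

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

make_msa <- function(...) {
  rows <- c(...)
  msa_block(paste0("s", seq_along(rows)), rows)
}

mutate_string <- function(s, positions, bases) {
  ch <- strsplit(s, "")[[1]]
  ch[positions] <- bases
  paste(ch, collapse = "")
}

# Independent maximum nested pairing oracle: plain recursion on the first
# position of the interval (no shared code with the package's DP).
can_pair_r <- function(a, b) {
  paste(a, b) %in% c("A T", "T A", "G C", "C G", "G T", "T G")
}
max_pairs_brute <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (can_pair_r(ch[i], ch[k]))
        best <- max(best, 1L + rec(i + 1, k - 1) + if (k < j) rec(k + 1, j) else 0L)
    }
    best
  }
  rec(1L, length(ch))
}

# Brute-force Hamming scan oracle for motif placement.
min_hamming_offset <- function(seq, motif) {
  sc <- strsplit(seq, "")[[1]]
  mc <- strsplit(motif, "")[[1]]
  m <- length(mc)
  d <- vapply(seq_len(length(sc) - m + 1), function(o) {
    obs <- sc[o:(o + m - 1)]
    sum(obs != mc | obs == "N")
  }, integer(1))
  list(offset = which.min(d), dist = min(d))
}
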