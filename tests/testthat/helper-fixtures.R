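# shared fixtures: a small encoding scheme keeps per-test decode work light
small_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- del_scheme(n_r1 = 4L, n_acid = 6L,
                                             codon_length = 6L,
                                             min_hamming = 3L, seed = 42L)
    cache
  }
})

make_fp <- function(bits, len = 64L) {
  structure(list(bits = as.integer(sort(bits)), length = as.integer(len)),
            class = "fingerprint")
}

# independent oracle for base-pair maximization: exhaustive backtracking over
# all nested pairings (no dynamic programming shared with the implementation)
brute_max_pairs <- function(sequence, min_hairpin = 3L) {
  s <- strsplit(sequence, "")[[1]]
  ok <- function(a, b) paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (j - i < min_hairpin + 1L) return(0L)
    best <- rec(i + 1L, j)                       # i unpaired
    for (k in (i + min_hairpin + 1L):j) {
      if (ok(s[i], s[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  if (length(s) < 2L) return(0L)
  rec(1L, length(s))
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
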