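# Independent oracles and fixture generators used across the suite. All are
# deliberately naive/brute-force implementations, kept separate from the
# package's own code paths.

rand_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# exhaustive recursion over all edit sequences (no memoization): the
# definitional oracle for edit distance on tiny strings
ed_recursive <- function(x, y) {
  if (nchar(x) == 0) return(nchar(y))
  if (nchar(y) == 0) return(nchar(x))
  cost <- if (substr(x, 1, 1) == substr(y, 1, 1)) 0L else 1L
  tx <- substr(x, 2, nchar(x)); ty <- substr(y, 2, nchar(y))
  min(ed_recursive(tx, ty) + cost,
      ed_recursive(tx, y) + 1L,
      ed_recursive(x, ty) + 1L)
}

# full-matrix DP with out-of-band cells pinned to +Inf: the reference for
# the rolling-row banded kernel
banded_full_matrix <- function(x, y, b) {
  n <- nchar(x); m <- nchar(y)
  beff <- max(b, abs(n - m))
  D <- matrix(Inf, n + 1, m + 1)
  for (i in 0:n) for (j in 0:m) {
    if (abs(i - j) > beff) next
    if (i == 0) { D[1, j + 1] <- j; next }
    if (j == 0) { D[i + 1, 1] <- i; next }
    cost <- if (substr(x, i, i) == substr(y, j, j)) 0 else 1
    D[i + 1, j + 1] <- min(D[i, j] + cost, D[i, j + 1] + 1, D[i + 1, j] + 1)
  }
  D[n + 1, m + 1]
}

# brute-force window enumeration (dedup at the end) for shingle sets
shingles_brute <- function(seq, w) {
  L <- nchar(seq)
  out <- character(0)
  for (i in seq_len(L - w + 1)) out <- c(out, substr(seq, i, i + w - 1))
  sort(unique(out))
}

# all strings of length 0..max_len over an alphabet
all_strings <- function(max_len, alphabet = c("A", "T")) {
  out <- ""
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

random_shingle_set <- function(n_items, w) {
  items <- unique(replicate(n_items, rand_seq(w)))
  privspq:::new_shingle_set(sort(items), w)
}

# random boolean circuit over the package's gate kinds, for exhaustive
# garbled-vs-plain equivalence checks
random_circuit <- function(n_gen, n_eval, n_gates) {
  cb <- privspq:::cb_new(n_gen + n_eval)
  last <- n_gen + n_eval
  for (i in seq_len(n_gates)) {
    kind <- sample(1:4, 1)
    a <- sample(last, 1)
    if (kind == 4L) privspq:::cb_gate(cb, kind, a)
    else {
      b <- sample(setdiff(seq_len(last), a), 1)
      privspq:::cb_gate(cb, kind, a, b)
    }
    last <- cb$nw
  }
  # outputs: the last few wires
  outs <- seq.int(max(n_gen + n_eval + 1L, cb$nw - 2L), cb$nw)
  privspq:::new_boolean_circuit(cb, list(generator = seq_len(n_gen),
                                         evaluator = n_gen + seq_len(n_eval)),
                                outs)
}

toy_dataset <- function(n, len, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed(sequence_dataset(
    vapply(seq_len(n), function(i) rand_seq(len), character(1)),
    sprintf("rec%03d", seq_len(n))))
}

# project a ranked_result onto its comparable data columns
rr_df <- function(r) {
  data.frame(rank = r$rank, record_id = r$record_id,
             score = as.numeric(r$score), stringsAsFactors = FALSE)
}
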