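# Garbled-circuit engine: gate-level semantics, oblivious transfer, the
# banded edit-distance circuit compiler, and the end-to-end secure protocol.

gc_run <- function(circuit, gen_bits, eval_bits, seed = 1, free_xor = FALSE,
                   audit = FALSE) {
  g <- garble(circuit, seed, free_xor = free_xor)
  active <- list()
  for (i in seq_along(circuit$input_wires$generator)) {
    w <- circuit$input_wires$generator[i]
    active[[as.character(w)]] <- privspq:::gc_label(g, w, gen_bits[i] == 1)
  }
  for (i in seq_along(circuit$input_wires$evaluator)) {
    w <- circuit$input_wires$evaluator[i]
    active[[as.character(w)]] <- privspq:::gc_label(g, w, eval_bits[i] == 1)
  }
  evaluate(g, active, audit = audit)
}

test_that("a single garbled AND gate realizes the truth table", {
  cb <- privspq:::cb_new(2)
  out <- privspq:::cb_gate(cb, 1L, 1L, 2L)  # AND
  circ <- privspq:::new_boolean_circuit(
    cb, list(generator = 1L, evaluator = 2L), out)
  for (a in 0:1) for (b in 0:1)
    expect_equal(gc_run(circ, a, b)$value, a * b, info = paste(a, b))
})

test_that("a garbled NOT gate inverts its input", {
  cb <- privspq:::cb_new(2)
  out <- privspq:::cb_gate(cb, 4L, 2L)      # NOT on the evaluator wire
  circ <- privspq:::new_boolean_circuit(
    cb, list(generator = 1L, evaluator = 2L), out)
  expect_equal(gc_run(circ, 0, 0)$value, 1)
  expect_equal(gc_run(circ, 0, 1)$value, 0)
})

test_that("random circuits: garbled evaluation equals plaintext evaluation exhaustively", {
  set.seed(51)
  for (rep in 1:10) {
    n_gen <- sample(1:3, 1); n_eval <- sample(1:3, 1)
    circ <- random_circuit(n_gen, n_eval, n_gates = 8)
    for (assign in 0:(2^(n_gen + n_eval) - 1)) {
      bits <- as.integer(intToBits(assign))[seq_len(n_gen + n_eval)]
      gb <- bits[seq_len(n_gen)]
      eb <- bits[n_gen + seq_len(n_eval)]
      want <- privspq:::eval_circuit_plain(circ, gb, eb)
      expect_equal(gc_run(circ, gb, eb, seed = rep)$value, want)
      expect_equal(gc_run(circ, gb, eb, seed = rep, free_xor = TRUE)$value, want)
    }
  }
})

test_that("a garbled ripple adder adds: 5 + 9 = 14 on 4 bits", {
  circ <- privspq:::cc_adder_circuit(4)
  to_bits <- function(v) as.integer(intToBits(v))[1:4]
  expect_equal(gc_run(circ, to_bits(5), to_bits(9))$value, 14)
  for (i in 1:10) {
    u <- sample(0:7, 1); v <- sample(0:7, 1)
    expect_equal(gc_run(circ, to_bits(u), to_bits(v))$value, u + v)
  }
})

test_that("oblivious transfer delivers exactly the chosen message", {
  m0 <- charToRaw("0000000000000000"); m1 <- charToRaw("1111111111111111")
  expect_identical(oblivious_transfer(list(m0, m1), 0, seed = 2), m0)
  expect_identical(oblivious_transfer(list(m0, m1), 1, seed = 2), m1)
  expect_error(oblivious_transfer(list(m0, m1[1:8]), 0, seed = 2),
               "equal length")
  # sender's view is structurally independent of the choice bit
  ch0 <- channel(); ch1 <- channel()
  oblivious_transfer(list(m0, m1), 0, ch0, seed = 7)
  oblivious_transfer(list(m0, m1), 1, ch1, seed = 7)
  sizes <- function(ch, who) lengths(lapply(Filter(function(e) e$sender == who,
                                                   transcript(ch)), `[[`, "bytes"))
  expect_identical(sizes(ch0, "data_owner"), sizes(ch1, "data_owner"))
})

test_that("banded circuit compiler matches the plaintext kernel through garbling", {
  sd <- secure_banded_distance("ATGC", "ATGG", band_spec(1), seed = 5)
  expect_equal(sd$distance, 1)
  expect_equal(secure_banded_distance("AAA", "AAA", band_spec(0), seed = 5)$distance, 0)
  set.seed(52)
  for (i in 1:15) {
    lx <- sample(1:12, 1); ly <- sample(1:12, 1)
    x <- rand_seq(lx); y <- rand_seq(ly)
    b <- sample(c(0, 1, 3), 1)
    expect_equal(secure_banded_distance(x, y, band_spec(b), seed = i)$distance,
                 banded_edit_distance(x, y, band_spec(b)),
                 info = paste(x, y, b))
  }
  # full band reproduces the exact edit distance
  for (i in 1:10) {
    x <- rand_seq(5); y <- rand_seq(5)
    expect_equal(secure_banded_distance(x, y, band_spec(5), seed = i)$distance,
                 edit_distance(x, y))
  }
})

test_that("free-XOR garbling changes no output of the secure protocol", {
  set.seed(53)
  for (i in 1:8) {
    x <- rand_seq(sample(2:10, 1)); y <- rand_seq(sample(2:10, 1))
    b <- sample(0:3, 1)
    d0 <- secure_banded_distance(x, y, band_spec(b), seed = i)$distance
    d1 <- secure_banded_distance(x, y, band_spec(b), seed = i,
                                 free_xor = TRUE)$distance
    expect_equal(d1, d0)
  }
})

test_that("exactly one garbled row decrypts per gate during evaluation", {
  set.seed(54)
  x <- rand_seq(8); y <- rand_seq(8)
  sd <- secure_banded_distance(x, y, band_spec(2), seed = 3, audit = TRUE)
  counts <- sd$audit_rows[sd$audit_rows >= 0]
  expect_gt(length(counts), 100)
  expect_true(all(counts == 1))
})

test_that("label secrecy: the transcript reveals one label per evaluator wire at most", {
  set.seed(55)
  x <- rand_seq(6); y <- rand_seq(6)
  ch <- channel()
  sd <- secure_banded_distance(x, y, band_spec(1), channel = ch, seed = 8,
                               audit = TRUE)
  bytes <- transcript_bytes(ch)
  tables <- transcript(ch)[[1]]$bytes
  for (w in sd$evaluator_wires) {
    for (v in c(FALSE, TRUE)) {
      lab <- privspq:::gc_label(sd$garbled, w, v)
      hits <- grepRaw(lab, bytes, fixed = TRUE, all = TRUE)
      # neither evaluator-wire label may cross the wire in the clear:
      # the chosen one is OT-encrypted, the other never leaves the generator
      # (spurious 16-byte coincidences inside ciphertexts would be 2^-128)
      expect_length(hits, 0)
    }
  }
  # generator labels: exactly the active one is sent, never its complement
  circ <- sd$garbled$circuit
  gen_wires <- circ$input_wires$generator
  xb <- privspq:::nucleotide_bits(x)
  for (i in seq_along(gen_wires)) {
    inactive <- privspq:::gc_label(sd$garbled, gen_wires[i], xb[i] != 1L)
    expect_length(grepRaw(inactive, bytes, fixed = TRUE, all = TRUE), 0)
    active <- privspq:::gc_label(sd$garbled, gen_wires[i], xb[i] == 1L)
    expect_gte(length(grepRaw(active, bytes, fixed = TRUE, all = TRUE)), 1)
  }
})

test_that("corrupted garbled tables raise an integrity error", {
  circ <- compile_banded_ed_circuit(4, 4, band_spec(1))
  g <- garble(circ, seed = 6)
  active <- list()
  xb <- privspq:::nucleotide_bits("ATGC"); yb <- privspq:::nucleotide_bits("ATGG")
  for (i in seq_along(circ$input_wires$generator))
    active[[as.character(circ$input_wires$generator[i])]] <-
      privspq:::gc_label(g, circ$input_wires$generator[i], xb[i] == 1)
  for (i in seq_along(circ$input_wires$evaluator))
    active[[as.character(circ$input_wires$evaluator[i])]] <-
      privspq:::gc_label(g, circ$input_wires$evaluator[i], yb[i] == 1)
  expect_equal(evaluate(g, active)$value, 1)
  g$tables <- as.raw(bitwXor(as.integer(g$tables), 255L))  # flip every byte
  expect_error(evaluate(g, active), "integrity error")
})

test_that("circuit text serialization round trips", {
  circ <- compile_banded_ed_circuit(3, 4, band_spec(1))
  path <- withr::local_tempfile(fileext = ".txt")
  write_circuit(circ, path)
  back <- read_circuit(path)
  expect_equal(back$gates, circ$gates)
  expect_equal(back$n_wires, circ$n_wires)
  expect_equal(back$input_wires, circ$input_wires)
  expect_equal(back$output_bits, circ$output_bits)
})

test_that("garbling rejects structurally invalid circuits", {
  circ <- compile_banded_ed_circuit(3, 3, band_spec(1))
  bad <- circ
  bad$gates[1, "out"] <- bad$input_wires$generator[1]
  expect_error(garble(bad, seed = 1), "structural error")
})
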