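# Private set intersection: DH commutative blinding and the salted-hash
# baseline. Tests run on the reduced-strength 512-bit group for speed; the
# protocol logic is group-independent.

test_that("both PSI protocols return exactly the plaintext intersection", {
  r <- shingle_set("CAACATAGCAAC", 4)
  o <- privspq:::new_shingle_set(sort(c("AACA", "GGGG")), 4L)
  expect_identical(psi_dh(r, o, seed = 1, group = "modp512")$intersection$items,
                   "AACA")
  expect_identical(psi_naive_hash(r, o, seed = 1)$intersection$items, "AACA")

  disj <- privspq:::new_shingle_set(c("GGGG", "TTTT"), 4L)
  expect_length(psi_dh(r, disj, seed = 1, group = "modp512")$intersection$items, 0)
  expect_length(psi_naive_hash(r, disj, seed = 1)$intersection$items, 0)

  set.seed(21)
  for (i in 1:25) {
    a <- random_shingle_set(sample(1:15, 1), 5)
    b <- random_shingle_set(sample(1:15, 1), 5)
    truth <- sort(intersect(a$items, b$items))
    expect_identical(psi_dh(a, b, seed = i, group = "modp512")$intersection$items,
                     truth)
    expect_identical(psi_naive_hash(a, b, seed = i)$intersection$items, truth)
  }
})

test_that("large sets with a planted shared core intersect exactly", {
  set.seed(22)
  shared <- unique(replicate(100, rand_seq(10)))
  only_a <- setdiff(unique(replicate(450, rand_seq(10))), shared)
  only_b <- setdiff(unique(replicate(450, rand_seq(10))), c(shared, only_a))
  a <- privspq:::new_shingle_set(sort(c(shared, only_a)), 10L)
  b <- privspq:::new_shingle_set(sort(c(shared, only_b)), 10L)
  truth <- sort(intersect(a$items, b$items))
  expect_identical(psi_dh(a, b, seed = 5, group = "modp512")$intersection$items,
                   truth)
  expect_identical(sort(shared), truth)
})

test_that("DH transcript never carries an owner shingle in the clear", {
  set.seed(23)
  a <- random_shingle_set(10, 6)
  b <- random_shingle_set(10, 6)
  ch <- channel()
  res <- psi_dh(a, b, channel = ch, seed = 3, group = "modp512")
  bytes <- transcript_bytes(ch)
  for (item in b$items)
    expect_length(grepRaw(charToRaw(item), bytes, fixed = TRUE, all = TRUE), 0)
  for (item in a$items)
    expect_length(grepRaw(charToRaw(item), bytes, fixed = TRUE, all = TRUE), 0)
  expect_identical(res$learned_by, "data_owner")
  expect_true(res$secure)
})

test_that("PSI results are seed-deterministic; seeds change transcripts only", {
  set.seed(24)
  a <- random_shingle_set(8, 5); b <- random_shingle_set(8, 5)
  ch1 <- channel(); ch2 <- channel(); ch3 <- channel()
  r1 <- psi_dh(a, b, ch1, seed = 11, group = "modp512")
  r2 <- psi_dh(a, b, ch2, seed = 11, group = "modp512")
  r3 <- psi_dh(a, b, ch3, seed = 12, group = "modp512")
  expect_identical(r1$intersection, r2$intersection)
  expect_identical(transcript_bytes(ch1), transcript_bytes(ch2))
  expect_identical(r1$intersection, r3$intersection)
  expect_false(identical(transcript_bytes(ch1), transcript_bytes(ch3)))
})

test_that("mismatched shingle widths abort the protocol", {
  a <- shingle_set("ACGTACG", 3)
  b <- shingle_set("ACGTACG", 4)
  expect_error(psi_dh(a, b, seed = 1), "abort.*width mismatch")
  expect_error(psi_naive_hash(a, b, seed = 1), "abort.*width mismatch")
})

test_that("naive-hash PSI is flagged insecure and is brute-forceable", {
  set.seed(25)
  a <- random_shingle_set(12, 4)
  b <- random_shingle_set(12, 4)
  ch <- channel()
  res <- psi_naive_hash(a, b, channel = ch, seed = 9)
  expect_false(res$secure)
  expect_match(res$insecurity_note, "brute")

  # the attack: enumerate all 4^4 shingles, hash with the public salt,
  # and recover the researcher's entire set from the transcript
  entries <- transcript(ch)
  salt <- entries[[1]]$bytes
  sent <- privspq:::unpack_blobs(entries[[2]]$bytes)
  sent_hex <- vapply(sent, function(x) paste(as.character(x), collapse = ""),
                     character(1))
  space <- apply(do.call(expand.grid, rep(list(c("A","C","G","T")), 4)), 1,
                 paste, collapse = "")
  dict <- vapply(space, function(s) {
    paste(as.character(privspq:::.cpp_sha256(c(salt, charToRaw(s)))), collapse = "")
  }, character(1))
  recovered <- sort(names(dict)[match(sent_hex, dict)])
  expect_identical(recovered, a$items)
})

test_that("channel delivers in order and dumps an auditable transcript", {
  ch <- channel()
  privspq:::ch_send(ch, "researcher", as.raw(1:3), "m1")
  privspq:::ch_send(ch, "data_owner", as.raw(9), "m2")
  privspq:::ch_send(ch, "researcher", as.raw(4:5), "m3")
  expect_identical(privspq:::ch_recv(ch, "data_owner"), as.raw(1:3))
  expect_identical(privspq:::ch_recv(ch, "researcher"), as.raw(9))
  expect_identical(privspq:::ch_recv(ch, "data_owner"), as.raw(4:5))
  expect_error(privspq:::ch_recv(ch, "data_owner"), "abort.*position")
  path <- withr::local_tempfile(fileext = ".log")
  dump_transcript(ch, path)
  expect_length(readLines(path), 3)
})
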