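# Sequence data model, FASTA/TSV I/O and the synthetic generator.

test_that("FASTA read/write round trip is the identity on valid datasets", {
  d <- sequence_dataset(c(a1 = "ATGCATGC", a2 = "ATGG", a3 = "T"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(d, path)
  expect_identical(read_fasta(path)$records, d$records)

  # wrapped sequences (>80 columns) survive the round trip
  long <- sequence_dataset(setNames(paste(rep("ACGT", 60), collapse = ""), "big"))
  write_fasta(long, path)
  expect_identical(read_fasta(path)$records, long$records)
})

test_that("FASTA parsing enforces format and alphabet", {
  two <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ATGC", ">s2", "ATGG"), two)
  d <- read_fasta(two)
  expect_equal(n_records(d), 2)
  expect_identical(unname(d$records), c("ATGC", "ATGG"))

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_equal(n_records(read_fasta(empty)), 0)

  withN <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ATNC"), withN)
  expect_error(read_fasta(withN), "alphabet error.*s1")

  noheader <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ATGC", ">s2", "ATGG"), noheader)
  expect_error(read_fasta(noheader), "parse error at line 1")
})

test_that("ids with whitespace are written up to the first whitespace", {
  d <- sequence_dataset("ATGC", ids = "rec one extra")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(d, path)
  expect_identical(names(read_fasta(path)$records), "rec")
})

test_that("dataset constructor validates ids and alphabet", {
  expect_error(sequence_dataset(c(x = "ATGC", x = "A")), "duplicate")
  expect_error(sequence_dataset(setNames("ATGC", "")), "non-empty")
  expect_error(sequence_dataset(c(ok = "ACGU")), "alphabet error")
  expect_equal(length_range(sequence_dataset(c(a = "AC", b = "ACGTA"))), c(2, 5))
})

test_that("frequency TSV round trip and validation", {
  ft <- allele_freq_table(rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_table(ft, path)
  back <- read_frequency_table(path)
  expect_equal(back$probs, ft$probs)
  expect_equal(n_sites(back), 2)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("site\tA\tC\tG\tT", "1\t0.5\t0.5\t0.5\t0.5"), bad)
  expect_error(read_frequency_table(bad), "site 1.*sum")
  writeLines(c("site\tA\tC\tG\tT", "1\t1.5\t-0.5\t0\t0"), bad)
  expect_error(read_frequency_table(bad), "negative")
  writeLines(c("site\tA\tC\tG", "1\t1\t0\t0"), bad)
  expect_error(read_frequency_table(bad), "header")
})

test_that("degenerate frequencies generate constant sequences", {
  ft <- allele_freq_table(matrix(rep(c(1, 0, 0, 0), each = 5), 5, 4))
  gen <- generate_dataset(ft, 3, 0, seed = 1)
  expect_identical(unname(gen$dataset$records), rep("AAAAA", 3))
  expect_equal(n_records(gen$queries), 0)
})

test_that("generator output has the requested shape and is seed-deterministic", {
  ft <- simulate_frequency_table(40, seed = 9)
  g1 <- generate_dataset(ft, 20, 5, seed = 123)
  g2 <- generate_dataset(ft, 20, 5, seed = 123)
  g3 <- generate_dataset(ft, 20, 5, seed = 124)
  expect_identical(g1, g2)
  expect_false(identical(g1$dataset$records, g3$dataset$records))
  expect_equal(n_records(g1$dataset), 20)
  expect_equal(n_records(g1$queries), 5)
  expect_true(all(nchar(g1$dataset$records) == 40))
})

test_that("per-site sampling matches the frequency table (uniform case)", {
  m <- 20; n <- 10000
  ft <- allele_freq_table(matrix(0.25, m, 4))
  gen <- generate_dataset(ft, n, 0, seed = 77)
  chars <- do.call(rbind, strsplit(gen$dataset$records, ""))
  se <- sqrt(0.25 * 0.75 / n)
  for (nuc in c("A", "C", "G", "T")) {
    freq <- colMeans(chars == nuc)
    # binomial calibration: with 20 sites x 4 nucleotides, a correct sampler
    # keeps ~99.7% of estimates inside 3 SE; demand at least 90% inside 3 SE
    # and every one inside 5 SE
    expect_gte(mean(abs(freq - 0.25) < 3 * se), 0.9)
    expect_true(all(abs(freq - 0.25) < 5 * se))
  }
})

test_that("generator does not consume or disturb the global RNG", {
  set.seed(555)
  before <- .Random.seed
  ft <- simulate_frequency_table(10, seed = 1)
  invisible(generate_dataset(ft, 3, 1, seed = 2))
  expect_identical(.Random.seed, before)
})

test_that("perturb_lengths bounds, identity and reproducibility", {
  d <- sequence_dataset(c(r1 = "ACGTACGTAC", r2 = "ACGT"))
  expect_identical(perturb_lengths(d, 0, seed = 1), d)
  p1 <- perturb_lengths(d, 6, seed = 42)
  p2 <- perturb_lengths(d, 6, seed = 42)
  expect_identical(p1, p2)
  expect_identical(names(p1$records), names(d$records))
  expect_true(all(abs(nchar(p1$records) - nchar(d$records)) <= 6))
})
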