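# The query engine: ranking with ties, the three query modes, the joined
# cascade and the accuracy metric.

test_that("exact top-k ranks the query's twin first and is order-invariant", {
  d <- sequence_dataset(c(r1 = "ATGCATGC", r2 = "ATGCATGG", r3 = "TTTTTTTT",
                          r4 = "ATGCATGC"))
  te <- topk_exact(d, "ATGCATGG", query_spec(1))
  expect_identical(te$record_id[1], "r2")
  expect_equal(te$score[1], 0)
  perm <- sequence_dataset(unname(d$records[c(3, 1, 4, 2)]),
                           names(d$records)[c(3, 1, 4, 2)])
  expect_setequal(returned_set(topk_exact(perm, "ATGCATGG", query_spec(1))),
                  returned_set(te))
})

test_that("ties at rank k expand the returned set", {
  # distances to query: r1=0, r2=1, r3=2, r4=2, r5=4 -> top-3 returns 4 records
  d <- sequence_dataset(c(r1 = "AAAA", r2 = "AAAT", r3 = "AATT", r4 = "TAAG",
                          r5 = "TTTT"))
  te <- topk_exact(d, "AAAA", query_spec(3))
  expect_equal(nrow(te), 4)
  expect_true(tie_expanded(te))
  expect_setequal(returned_set(te), c("r1", "r2", "r3", "r4"))
  # deterministic secondary ordering by record id among the tied pair
  expect_identical(te$record_id[3:4], c("r3", "r4"))
})

test_that("the tie-aware accuracy metric reproduces its worked example", {
  rep <- accuracy(c("1000", "1010", "505", "1101"),
                  c("1000", "1010", "505", "202"))
  expect_equal(rep$n_tp, 3)
  expect_equal(rep$n_fn, 1)
  expect_equal(rep$accuracy, 0.75)
  expect_equal(accuracy(c("a", "b"), c("a", "b"))$accuracy, 1)
  expect_equal(accuracy(c("a", "b"), c("x", "y"))$accuracy, 0)
  expect_error(accuracy(character(0), "a"), "empty truth")
})

test_that("shingle/PSI ranking orders records by intersection match count", {
  q <- "ACGTTGCAATCCGGATTAAC"
  qs <- shingle_set(q, 4)$items
  expect_length(qs, 17)  # every 4-window of q is distinct
  # rec_hi shares 10 of the query's 4-shingles, rec_lo only 9
  d <- sequence_dataset(c(rec_hi = substr(q, 1, 13), rec_lo = substr(q, 1, 12)))
  r <- topk_approx1(d, q, query_spec(2, w = 4))
  expect_identical(r$record_id, c("rec_hi", "rec_lo"))
  expect_equal(r$score, c(10, 9))

  # a record equal to the query attains the maximum possible match count
  d2 <- sequence_dataset(c(self = q, other = substr(q, 1, 8)))
  r2 <- topk_approx1(d2, q, query_spec(1, w = 4))
  expect_identical(r2$record_id[1], "self")
  expect_equal(r2$score[1], 17)
})

test_that("approx1 over a real protocol equals the plaintext-count pipeline", {
  ft <- simulate_frequency_table(120, seed = 3)
  gen <- generate_dataset(ft, 25, 1, seed = 4)
  q <- unname(gen$queries$records[1])
  base <- topk_approx1(gen$dataset, q, query_spec(5), psi_protocol = "plaintext")
  dh <- topk_approx1(gen$dataset, q, query_spec(5), psi_protocol = "dh",
                     seed = 2, group = "modp512")
  nv <- topk_approx1(gen$dataset, q, query_spec(5), psi_protocol = "naive",
                     seed = 2)
  expect_equal(rr_df(base), rr_df(dh))
  expect_equal(rr_df(base), rr_df(nv))
  expect_false(attr(nv, "psi")$secure)
})

test_that("banded ranking: secure and plaintext variants agree; wide band = exact", {
  ft <- simulate_frequency_table(12, seed = 6)
  gen <- generate_dataset(ft, 5, 1, seed = 7)
  q <- unname(gen$queries$records[1])
  spec <- query_spec(2, band = band_spec(2))
  plain <- topk_approx2(gen$dataset, q, spec, use_secure = FALSE)
  secure <- topk_approx2(gen$dataset, q, spec, use_secure = TRUE, seed = 9)
  expect_equal(rr_df(plain), rr_df(secure))

  wide <- topk_approx2(gen$dataset, q, query_spec(2, band = band_spec(12)))
  exact <- topk_exact(gen$dataset, q, query_spec(2))
  expect_equal(rr_df(wide), rr_df(exact))

  single <- sequence_dataset(c(only = "ACGT"))
  r1 <- topk_approx2(single, "ACGG", query_spec(1, band = band_spec(1)))
  expect_identical(returned_set(r1), "only")
})

test_that("joined cascade: survivor arithmetic, containment, degeneration", {
  ft <- simulate_frequency_table(150, seed = 11)
  gen <- generate_dataset(ft, 60, 1, seed = 12)
  q <- unname(gen$queries$records[1])

  j <- topk_joined(gen$dataset, q, query_spec(4, c = 5))
  expect_length(attr(j, "stage1_survivors"), 20)   # t = c * k
  expect_true(all(returned_set(j) %in% attr(j, "stage1_survivors")))

  # c large enough that t = n: equals approx2 on the full dataset
  jfull <- topk_joined(gen$dataset, q, query_spec(4, c = 15))
  afull <- topk_approx2(gen$dataset, q, query_spec(4))
  expect_equal(rr_df(jfull), rr_df(afull))

  expect_error(topk_joined(gen$dataset, q, query_spec(10, c = 7)),
               "exceeds the dataset size")
})

test_that("joined containment holds across seeds and parameters", {
  for (s in 1:6) {
    ft <- simulate_frequency_table(100, seed = s)
    gen <- generate_dataset(ft, 40, 1, seed = s + 100)
    q <- unname(gen$queries$records[1])
    k <- sample(2:5, 1); cc <- sample(2:4, 1)
    j <- topk_joined(gen$dataset, q, query_spec(k, c = cc))
    expect_length(attr(j, "stage1_survivors"), k * cc)
    expect_true(all(returned_set(j) %in% attr(j, "stage1_survivors")))
  }
})

test_that("query_spec enforces the t = c * k relation and validates inputs", {
  qs <- query_spec(10, c = 5)
  expect_equal(qs$t, 50)
  expect_error(query_spec(0), "positive")
  expect_error(query_spec(3, c = 0), "positive")
})
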