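# The Similar Patients Query engine: exact baseline, the two approximations,
# the joined two-stage cascade, and the tie-aware accuracy (top-k recall)
# metric.

#' Query specification for a Similar Patients Query
#'
#' Bundles the tunable parameters of a top-k query: `k` (result size), the
#' cascade factor `c` with `t = c * k` (how many stage-1 survivors the joined
#' mode passes to the banded re-ranking), the shingle width `w`, and the
#' band. Defaults follow the package's benchmark-style settings: `c = 5`,
#' `b = 5`, and `w` chosen per query length via [optimal_w()] when left
#' `NULL`.
#'
#' @param k positive integer: number of records to retrieve.
#' @param c positive integer cascade factor (`t = c * k`).
#' @param w shingle width, or `NULL` to use `optimal_w(query length)`.
#' @param band a [band_spec()].
#' @param mode one of `"exact"`, `"approx1"`, `"approx2"`, `"joined"`.
#' @return An object of class `query_spec` with fields `k, c, t, w, band,
#'   mode`.
#' @export
query_spec <- function(k, c = 5L, w = NULL, band = band_spec(5L),
                       mode = c("exact", "approx1", "approx2", "joined")) {
  k <- as.integer(k); c <- as.integer(c)
  if (length(k) != 1 || is.na(k) || k < 1) stopf("k must be a positive integer")
  if (length(c) != 1 || is.na(c) || c < 1) stopf("c must be a positive integer")
  stopifnot(inherits(band, "band_spec"))
  if (!is.null(w)) {
    w <- as.integer(w)
    if (w < 1) stopf("shingle width w must be >= 1")
  }
  structure(list(k = k, c = c, t = k * c, w = w, band = band,
                 mode = match.arg(mode)),
            class = "query_spec")
}

#' @export
print.query_spec <- function(x, ...) {
  cat(sprintf("<query_spec> mode = %s, k = %d, c = %d (t = %d), w = %s, b = %d\n",
              x$mode, x$k, x$c, x$t,
              if (is.null(x$w)) "auto" else as.character(x$w), x$band$b))
  invisible(x)
}

# Tie-aware ranking: order by score (and record id for determinism), return
# the top-k expanded so that every record tied with the rank-k score is
# included.
rank_with_ties <- function(record_ids, scores, k, decreasing) {
  stopifnot(length(record_ids) == length(scores))
  n <- length(record_ids)
  if (k > n) stopf("k = %d exceeds the number of candidate records (%d)", k, n)
  ord <- order(if (decreasing) -scores else scores, record_ids)
  cutoff <- scores[ord[k]]
  keep <- if (decreasing) scores >= cutoff else scores <= cutoff
  sel <- ord[keep[ord]]
  res <- data.frame(rank = seq_along(sel), record_id = record_ids[sel],
                    score = scores[sel], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(res, class = c("ranked_result", "data.frame"),
            k = k, tie_expanded = length(sel) > k,
            direction = if (decreasing) "descending" else "ascending")
}

#' Components of a ranked query result
#'
#' `returned_set` gives the unordered set of record ids a ranked result
#' returns (at least `k` ids; more when records tie with the rank-k score);
#' `tie_expanded` says whether such expansion happened.
#'
#' @param x a ranked result as returned by [topk_exact()] and friends.
#' @return `returned_set`: character vector of ids; `tie_expanded`: logical.
#' @export
returned_set <- function(x) {
  stopifnot(inherits(x, "ranked_result"))
  x$record_id
}

#' @rdname returned_set
#' @export
tie_expanded <- function(x) {
  stopifnot(inherits(x, "ranked_result"))
  attr(x, "tie_expanded")
}

#' @export
print.ranked_result <- function(x, ...) {
  cat(sprintf("<ranked_result> top-%d (%s scores)%s\n", attr(x, "k"),
              attr(x, "direction"),
              if (attr(x, "tie_expanded")) sprintf(", tie-expanded to %d", nrow(x)) else ""))
  print.data.frame(head(as.data.frame(x), 15))
  if (nrow(x) > 15) cat(sprintf("  ... and %d more\n", nrow(x) - 15))
  invisible(x)
}

#' Exact top-k Similar Patients Query
#'
#' Ranks all records by exact [edit_distance()] to the query, ascending, with
#' deterministic secondary ordering by record id and tie expansion at rank
#' `k` (every record tied with the rank-k distance is returned). This is the
#' plaintext ground truth the approximations are measured against.
#'
#' @param dataset a non-empty [sequence_dataset()].
#' @param query query sequence (string or one-record dataset).
#' @param spec a [query_spec()].
#' @return A `ranked_result` with ascending `score` = exact edit distance.
#' @export
topk_exact <- function(dataset, query, spec) {
  stopifnot(inherits(spec, "query_spec"))
  dm <- distance_matrix(dataset, query, method = "exact")
  rank_with_ties(dm$record_id, dm$distance, spec$k, decreasing = FALSE)
}

#' Approximation 1: shingle/PSI top-k query
#'
#' The researcher's query shingle set is intersected once with the data
#' owner's union shingle database through a private set intersection; the
#' owner then counts, locally and per record, how many of that record's
#' shingles fall in the intersection, and ranks records by descending match
#' count (tie expansion at rank `k`, id tie-break).
#'
#' @inheritParams topk_exact
#' @param psi_protocol `"dh"` (secure), `"naive"` (salted-hash baseline,
#'   insecure) or `"plaintext"` (no protocol — direct set intersection; the
#'   fast mode for experiments; identical output by construction).
#' @param seed integer seed for protocol secrets.
#' @param group DH group name for `psi_protocol = "dh"`.
#' @return A `ranked_result` with descending `score` = shingle match count;
#'   attribute `psi` carries the [psi_dh()] / [psi_naive_hash()] result when
#'   a protocol was run.
#' @export
topk_approx1 <- function(dataset, query, spec,
                         psi_protocol = c("plaintext", "dh", "naive"),
                         seed = 1L, group = c("modp2048", "modp512")) {
  stopifnot(inherits(spec, "query_spec"))
  psi_protocol <- match.arg(psi_protocol)
  q <- query_residues(query)
  w <- spec$w %||% optimal_w(nchar(q))
  db <- build_shingle_db(dataset, w)
  query_sh <- shingle_set(q, w)
  owner_union <- new_shingle_set(db$union, w)
  psi <- switch(psi_protocol,
    plaintext = NULL,
    dh = psi_dh(query_sh, owner_union, seed = seed, group = match.arg(group)),
    naive = psi_naive_hash(query_sh, owner_union, seed = seed))
  inter <- if (is.null(psi)) intersect(query_sh$items, db$union)
           else psi$intersection$items
  counts <- vapply(db$per_record, function(items) sum(items %in% inter),
                   integer(1))
  res <- rank_with_ties(names(counts), unname(counts), spec$k,
                        decreasing = TRUE)
  attr(res, "psi") <- psi
  attr(res, "w") <- w
  res
}

#' Approximation 2: banded-edit-distance top-k query
#'
#' Ranks records by [banded_edit_distance()] to the query, ascending, tie
#' expansion at rank `k`. With `use_secure = TRUE` every per-record distance
#' is computed through the garbled-circuit protocol
#' ([secure_banded_distance()]); the plaintext kernel and the secure
#' protocol return identical distances, so the rankings are identical — the
#' flag only changes who gets to see what.
#'
#' @inheritParams topk_exact
#' @param use_secure compute each distance inside a garbled circuit.
#' @param seed integer seed (secure path only).
#' @param group DH group for the oblivious transfers (secure path only).
#' @return A `ranked_result` with ascending `score` = banded distance.
#' @export
topk_approx2 <- function(dataset, query, spec, use_secure = FALSE, seed = 1L,
                         group = c("modp512", "modp2048")) {
  stopifnot(inherits(spec, "query_spec"))
  if (n_records(dataset) == 0) stopf("dataset is empty")
  q <- query_residues(query)
  if (use_secure) {
    group <- match.arg(group)
    d <- vapply(seq_along(dataset$records), function(i) {
      sd <- secure_banded_distance(dataset$records[i], q, spec$band,
                                   seed = derive_seed(seed, paste0("rec-", i)),
                                   group = group)
      sd$distance
    }, numeric(1))
    ids <- names(dataset$records)
  } else {
    dm <- distance_matrix(dataset, q, method = "banded", band = spec$band)
    d <- dm$distance; ids <- dm$record_id
  }
  rank_with_ties(ids, d, spec$k, decreasing = FALSE)
}

#' Joined two-stage top-k query
#'
#' Stage 1 runs the shingle/PSI approximation and keeps the top `t = c * k`
#' records (deterministic truncation at `t`, ties broken by record id);
#' stage 2 re-ranks only those survivors by (optionally secure) banded edit
#' distance and returns the final top-k (tie expansion at rank `k`). The
#' final returned set is always contained in the stage-1 survivor set.
#'
#' @inheritParams topk_approx1
#' @param use_secure compute stage-2 distances inside garbled circuits.
#' @return A `ranked_result`; attributes `stage1_survivors` (character
#'   vector of `t` ids) and `w` record the cascade internals.
#' @export
topk_joined <- function(dataset, query, spec,
                        psi_protocol = c("plaintext", "dh", "naive"),
                        use_secure = FALSE, seed = 1L,
                        group = c("modp2048", "modp512")) {
  stopifnot(inherits(spec, "query_spec"))
  if (spec$t > n_records(dataset))
    stopf("t = c*k = %d exceeds the dataset size %d", spec$t, n_records(dataset))
  q <- query_residues(query)
  w <- spec$w %||% optimal_w(nchar(q))
  spec1 <- query_spec(spec$t, c = 1L, w = w, band = spec$band, mode = "approx1")
  stage1 <- topk_approx1(dataset, q, spec1, psi_protocol = psi_protocol,
                         seed = seed, group = group)
  survivors <- head(stage1$record_id, spec$t)  # truncate: exactly t survivors
  sub <- sequence_dataset(unname(dataset$records[survivors]), survivors)
  spec2 <- query_spec(spec$k, c = spec$c, w = w, band = spec$band,
                      mode = "approx2")
  res <- topk_approx2(sub, q, spec2, use_secure = use_secure, seed = seed,
                      group = if (use_secure) "modp512" else group)
  attr(res, "stage1_survivors") <- survivors
  attr(res, "w") <- w
  res
}

#' Tie-aware top-k accuracy (recall)
#'
#' `accuracy = N_TP / (N_TP + N_FN)`: the fraction of the ground-truth
#' top-k set (from [topk_exact()], tie-expanded) that the approximation also
#' returned. Also known as true positive rate, sensitivity or recall. With
#' truth set `{1000, 1010, 505, 1101}` (a top-3 query where two records tie
#' at 3rd) and prediction `{1000, 1010, 505, 202}`, three of the four truth
#' records are recovered and the accuracy is 3/4 = 75%.
#'
#' @param truth ground-truth `ranked_result` (or character vector of ids).
#' @param predicted predicted `ranked_result` (or character vector of ids).
#' @return An object of class `accuracy_report`: `n_tp`, `n_fn`, `accuracy`.
#' @examples
#' accuracy(c("1000", "1010", "505", "1101"), c("1000", "1010", "505", "202"))
#' @export
accuracy <- function(truth, predicted) {
  tset <- if (inherits(truth, "ranked_result")) returned_set(truth)
          else as.character(truth)
  pset <- if (inherits(predicted, "ranked_result")) returned_set(predicted)
          else as.character(predicted)
  tset <- unique(tset); pset <- unique(pset)
  if (length(tset) == 0) stopf("input error: empty truth set")
  n_tp <- length(intersect(pset, tset))
  n_fn <- length(tset) - n_tp
  structure(list(n_tp = n_tp, n_fn = n_fn, accuracy = n_tp / (n_tp + n_fn)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> TP = %d, FN = %d, accuracy = %.4f (%.1f%%)\n",
              x$n_tp, x$n_fn, x$accuracy, 100 * x$accuracy))
  invisible(x)
}
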