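# Plaintext edit-distance kernels: exact Wagner-Fischer and the banded
# (Ukkonen-style) approximation. These are both the ground truth for the
# secure protocols and the functional specification the boolean circuit
# compiler implements gate-by-gate.

#' Band specification for banded alignment
#'
#' The band parameter `b` is a half-width around the main diagonal of the
#' dynamic-programming matrix: only cells `(i, j)` with `|i - j| <= b_eff`
#' are computed, where `b_eff = max(b, ||x| - |y||)`. Widening to the length
#' difference is the minimal feasible band — without it no alignment path
#' exists for sequences of unequal length, and ranking all records requires
#' a finite value for every pair.
#'
#' @param b non-negative integer band half-width.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec(5)
#' @export
band_spec <- function(b) {
  b <- as.integer(b)
  if (length(b) != 1 || is.na(b) || b < 0) stopf("band half-width b must be >= 0")
  structure(list(b = b), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> half-width b = %d\n", x$b)); invisible(x)
}

effective_band <- function(x, y, band) {
  stopifnot(inherits(band, "band_spec"))
  max(band$b, abs(nchar(x) - nchar(y)))
}

check_residues <- function(x, arg) {
  if (length(x) != 1 || is.na(x)) stopf("%s must be a single string", arg)
  if (grepl("[^ACGT]", x))
    stopf("%s contains characters outside {A,C,G,T}", arg)
  x
}

#' Exact (Levenshtein) edit distance
#'
#' Minimum number of unit-cost insertions, deletions and substitutions
#' (matches cost zero) transforming `x` into `y`, computed with the
#' Wagner-Fischer dynamic program over the `(|x|+1) x (|y|+1)` matrix,
#' stored as two rolling rows. Symmetric, and satisfies the triangle
#' inequality.
#'
#' @param x,y sequences over `{A,C,G,T}` (empty strings allowed).
#' @return Non-negative integer distance.
#' @examples
#' edit_distance("ATGC", "ATGG")  # 1
#' @export
edit_distance <- function(x, y) {
  .cpp_edit_distance(check_residues(toupper(x), "x"),
                     check_residues(toupper(y), "y"))
}

#' Banded edit distance
#'
#' Dynamic program restricted to cells within `b_eff` of the main diagonal
#' (`b_eff = max(b, ||x|-|y||)`); out-of-band neighbours are treated as
#' `+Inf`. The result is an upper bound on [edit_distance()] and equals it
#' whenever `b >= max(|x|, |y|)`; narrowing the band can only increase the
#' value. Cost is `O(n * b)` instead of `O(n * m)`.
#'
#' @param x,y sequences over `{A,C,G,T}`.
#' @param band a [band_spec()].
#' @return Non-negative integer distance.
#' @examples
#' banded_edit_distance("AAAA", "TTTT", band_spec(0))  # 4
#' @export
banded_edit_distance <- function(x, y, band) {
  x <- check_residues(toupper(x), "x"); y <- check_residues(toupper(y), "y")
  .cpp_banded_edit_distance(x, y, effective_band(x, y, band))
}

#' Distances from a query to every record of a dataset
#'
#' @param dataset a [sequence_dataset()] (non-empty).
#' @param query a single query sequence (string or one-record
#'   [sequence_dataset()]).
#' @param method `"exact"` (Wagner-Fischer) or `"banded"`.
#' @param band a [band_spec()]; required for `method = "banded"`.
#' @return A data frame with columns `record_id`, `distance`, `method`, one
#'   row per record in dataset order.
#' @export
distance_matrix <- function(dataset, query, method = c("exact", "banded"),
                            band = NULL) {
  stopifnot(inherits(dataset, "sequence_dataset"))
  if (n_records(dataset) == 0) stopf("dataset is empty")
  method <- match.arg(method)
  q <- query_residues(query)
  d <- if (method == "exact") {
    vapply(dataset$records, function(s) .cpp_edit_distance(s, q), integer(1))
  } else {
    if (is.null(band)) stopf("method = 'banded' requires a band_spec")
    vapply(dataset$records,
           function(s) .cpp_banded_edit_distance(s, q, effective_band(s, q, band)),
           integer(1))
  }
  data.frame(record_id = names(dataset$records), distance = unname(d),
             method = method, row.names = NULL, stringsAsFactors = FALSE)
}

query_residues <- function(query) {
  if (inherits(query, "sequence_dataset")) {
    if (n_records(query) != 1) stopf("query dataset must contain exactly one record")
    query <- unname(query$records[1])
  }
  check_residues(toupper(query), "query")
}
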