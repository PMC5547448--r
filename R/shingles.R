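# w-shingling of sequences, the shingle database both parties build before
# the private set intersection, and shingle-space accounting.

#' Set of w-shingles of a sequence
#'
#' A w-shingle is any length-`w` substring of the sequence; the shingle set
#' is the deduplicated collection of all such substrings (set, not bag,
#' semantics: a substring appearing several times is counted once).
#'
#' @param seq a sequence over `{A,C,G,T}` with `nchar(seq) >= w`.
#' @param w positive integer shingle width.
#' @return An object of class `shingle_set` with fields `w` and `items`
#'   (lexicographically sorted character vector of distinct shingles).
#' @examples
#' shingle_set("CAACATAGCAAC", 4)  # 8 distinct 4-shingles
#' @export
shingle_set <- function(seq, w) {
  w <- as.integer(w)
  if (length(w) != 1 || is.na(w) || w < 1) stopf("shingle width w must be >= 1")
  seq <- check_residues(toupper(seq), "seq")
  L <- nchar(seq)
  if (L < w)
    stopf("input error: sequence length %d is shorter than shingle width %d", L, w)
  items <- sort(unique(substring(seq, seq_len(L - w + 1), w:L)))
  new_shingle_set(items, w)
}

new_shingle_set <- function(items, w) {
  structure(list(w = as.integer(w), items = items), class = "shingle_set")
}

#' Construct a shingle set from explicit items
#'
#' Builds a `shingle_set` directly from a vector of shingles (deduplicated
#' and sorted), validating that every item has length `w` over `{A,C,G,T}`.
#'
#' @param items character vector of shingles.
#' @param w positive integer shingle width.
#' @return A `shingle_set`.
#' @export
as_shingle_set <- function(items, w) {
  w <- as.integer(w)
  if (w < 1) stopf("shingle width w must be >= 1")
  items <- toupper(as.character(items))
  if (any(nchar(items) != w))
    stopf("all shingles must have length w = %d", w)
  if (any(grepl("[^ACGT]", items)))
    stopf("shingles contain characters outside {A,C,G,T}")
  new_shingle_set(sort(unique(items)), w)
}

#' @export
print.shingle_set <- function(x, ...) {
  cat(sprintf("<shingle_set> w = %d, %d shingle(s)\n", x$w, length(x$items)))
  if (length(x$items))
    cat(" ", paste(head(x$items, 12), collapse = " "),
        if (length(x$items) > 12) "..." else "", "\n")
  invisible(x)
}

#' @export
length.shingle_set <- function(x) length(x$items)

#' Shingle width suited to a sequence length
#'
#' Returns `max(1, ceiling(log4(seq_length)))`: the width at which the
#' shingle space (`4^w`) first reaches the sequence length, so that shingle
#' matches stay informative. Narrower widths saturate the shingle space and
#' inflate false positives in the similarity ranking.
#'
#' @param seq_length positive integer.
#' @return Positive integer shingle width.
#' @examples
#' optimal_w(256)   # 4
#' optimal_w(3461)  # 6
#' @export
optimal_w <- function(seq_length) {
  stopifnot(seq_length >= 1)
  # round() guards against floating-point overshoot at exact powers of 4
  max(1L, as.integer(ceiling(round(log(seq_length, base = 4), 12))))
}

#' Build the per-record shingle database of a dataset
#'
#' Computes the `w`-shingle set of every record plus their union; the union
#' is what the data owner feeds into the private set intersection, and the
#' per-record sets are used afterwards for local match counting.
#'
#' @param dataset a [sequence_dataset()]; every record must have length
#'   `>= w`.
#' @param w positive integer shingle width.
#' @return An object of class `shingle_db` with fields `w`, `per_record`
#'   (named list of sorted shingle vectors) and `union` (sorted vector).
#' @export
build_shingle_db <- function(dataset, w) {
  stopifnot(inherits(dataset, "sequence_dataset"))
  w <- as.integer(w)
  if (w < 1) stopf("shingle width w must be >= 1")
  short <- nchar(dataset$records) < w
  if (any(short))
    stopf("input error: records shorter than w = %d: %s", w,
          paste(names(dataset$records)[short], collapse = ", "))
  per_record <- lapply(dataset$records, function(s) {
    L <- nchar(s)
    sort(unique(substring(s, seq_len(L - w + 1), w:L)))
  })
  union <- sort(unique(unlist(per_record, use.names = FALSE)))
  structure(list(w = w, per_record = per_record, union = union),
            class = "shingle_db")
}

#' @export
print.shingle_db <- function(x, ...) {
  cat(sprintf("<shingle_db> w = %d, %d record(s), %d unique shingle(s)\n",
              x$w, length(x$per_record), length(x$union)))
  invisible(x)
}

#' Shingle-space statistics
#'
#' Accounting of how the shingle transformation of a dataset compares to the
#' theoretical shingle space: the number of distinct shingles observed, the
#' `4^w` upper bound, and the plain-text storage footprint (one byte per
#' character, i.e. `unique_count * w` bytes).
#'
#' @param db a [build_shingle_db()] result.
#' @return A list with `unique_count`, `theoretical_max` (`4^w`) and
#'   `storage_bytes`.
#' @examples
#' d <- sequence_dataset(c(r1 = "CAACATAGCAAC"))
#' shingle_space_stats(build_shingle_db(d, 4))
#' @export
shingle_space_stats <- function(db) {
  stopifnot(inherits(db, "shingle_db"))
  uc <- length(db$union)
  list(unique_count = uc, theoretical_max = 4^db$w,
       storage_bytes = uc * db$w)
}

#' Write / read a shingle database as plain text
#'
#' Format: a header line `#w=<w>`, then one `><record_id>` section per
#' record with its shingles one per line, lexicographically sorted — so the
#' on-disk footprint is directly auditable against
#' [shingle_space_stats()].
#'
#' @param db a [build_shingle_db()] result.
#' @param path file path.
#' @return `write_shingle_db` returns `path` invisibly; `read_shingle_db`
#'   returns a `shingle_db`.
#' @export
write_shingle_db <- function(db, path) {
  stopifnot(inherits(db, "shingle_db"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#w=%d", db$w), con)
  for (id in names(db$per_record)) {
    writeLines(paste0(">", id), con)
    writeLines(db$per_record[[id]], con)
  }
  invisible(path)
}

#' @rdname write_shingle_db
#' @export
read_shingle_db <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#w="))
    stopf("shingle DB parse error: missing '#w=' header")
  w <- as.integer(sub("^#w=", "", lines[1]))
  body <- lines[-1]
  heads <- which(startsWith(body, ">"))
  per_record <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(body)
    items <- if (to >= from) body[from:to] else character(0)
    per_record[[sub("^>", "", body[heads[i]])]] <- sort(items)
  }
  union <- sort(unique(unlist(per_record, use.names = FALSE)))
  structure(list(w = w, per_record = per_record, union = union),
            class = "shingle_db")
}
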