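# Sequence and allele-frequency data model, FASTA/TSV I/O, and the synthetic
# sequence generator emulating population SNP panels.

#' Construct a sequence dataset
#'
#' A `sequence_dataset` is an ordered collection of identified DNA sequences
#' over the strict alphabet `{A, C, G, T}` — the universe both parties of a
#' Similar Patients Query compute over. Ambiguity codes (e.g. `N`) are
#' rejected rather than coerced, because the shingle-space arithmetic
#' (`4^w` possible shingles) assumes a four-letter alphabet.
#'
#' @param residues character vector of sequences (possibly named by id).
#' @param ids character vector of unique, non-empty record identifiers;
#'   defaults to `names(residues)`.
#' @return An object of class `sequence_dataset` with elements `records`
#'   (named character vector), and accessors [n_records()] and
#'   [length_range()].
#' @examples
#' d <- sequence_dataset(c(s1 = "ATGC", s2 = "ATGG"))
#' n_records(d)
#' @export
sequence_dataset <- function(residues, ids = names(residues)) {
  force(ids)
  residues <- toupper(as.character(residues))
  if (is.null(ids)) {
    if (length(residues) == 0) ids <- character(0)
    else stopf("sequence ids are required (name the residues or pass ids=)")
  }
  ids <- as.character(ids)
  if (length(ids) != length(residues))
    stopf("ids and residues lengths differ (%d vs %d)", length(ids), length(residues))
  if (any(!nzchar(ids))) stopf("sequence ids must be non-empty")
  if (anyDuplicated(ids))
    stopf("duplicate sequence ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- grepl("[^ACGT]", residues)
  if (any(bad))
    stopf("alphabet error: record '%s' contains characters outside {A,C,G,T}",
          ids[which(bad)[1]])
  structure(list(records = setNames(residues, ids)), class = "sequence_dataset")
}

#' @rdname sequence_dataset
#' @param dataset a `sequence_dataset`.
#' @export
n_records <- function(dataset) length(dataset$records)

#' @rdname sequence_dataset
#' @export
length_range <- function(dataset) {
  if (n_records(dataset) == 0) return(c(NA_integer_, NA_integer_))
  range(nchar(dataset$records))
}

#' @export
print.sequence_dataset <- function(x, ...) {
  n <- n_records(x)
  cat(sprintf("<sequence_dataset> %d record(s)", n))
  if (n > 0) {
    lr <- length_range(x)
    cat(sprintf(", lengths %d-%d", lr[1], lr[2]))
  }
  cat("\n")
  if (n > 0) {
    show <- head(x$records, 3)
    for (i in seq_along(show))
      cat(sprintf("  %s: %s%s\n", names(show)[i],
                  substr(show[i], 1, 40), if (nchar(show[i]) > 40) "..." else ""))
    if (n > 3) cat(sprintf("  ... and %d more\n", n - 3))
  }
  invisible(x)
}

#' Read a FASTA file into a sequence dataset
#'
#' Parses with `Biostrings::readDNAStringSet` (single-line or wrapped
#' sequences accepted), takes the record id as the header up to the first
#' whitespace, uppercases residues, and rejects any character outside
#' `{A, C, G, T}`.
#'
#' @param path path to an existing FASTA file. An empty file yields an empty
#'   dataset.
#' @return A [sequence_dataset()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0)
    return(sequence_dataset(character(0), character(0)))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0)
    return(sequence_dataset(character(0), character(0)))
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stopf("FASTA parse error at line %d: expected '>' header", nonblank[1])
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stopf("FASTA parse error in %s: %s",
                                          path, conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(x))
  sequence_dataset(as.character(x), ids)
}

#' Write a sequence dataset to FASTA
#'
#' Sequences are wrapped at 80 columns. Record ids containing whitespace are
#' written up to the first whitespace character, per FASTA convention, so the
#' read/write round trip is the identity on datasets with whitespace-free ids.
#'
#' @param dataset a [sequence_dataset()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "sequence_dataset"))
  ids <- sub("\\s.*$", "", names(dataset$records))
  x <- Biostrings::DNAStringSet(setNames(as.character(dataset$records), ids))
  tryCatch(Biostrings::writeXStringSet(x, filepath = path, width = 80L),
           error = function(e) stopf("cannot write FASTA to %s: %s",
                                     path, conditionMessage(e)))
  invisible(path)
}

#' Construct an allele-frequency table
#'
#' Per-site probability vectors over (A, C, G, T) that drive the synthetic
#' sequence generator, emulating accumulated population allele frequencies
#' of a SNP panel.
#'
#' @param probs numeric matrix with one row per site and columns `A, C, G, T`;
#'   each row must sum to 1 within `1e-9` and contain no negative entries.
#' @return An object of class `allele_freq_table`.
#' @export
allele_freq_table <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) < 1) stopf("frequency table needs at least one site")
  if (ncol(probs) != 4) stopf("frequency table needs 4 columns (A, C, G, T)")
  colnames(probs) <- NUCLEOTIDES
  if (any(probs < 0))
    stopf("validation error at site %d: negative probability",
          which(apply(probs < 0, 1, any))[1])
  dev <- abs(rowSums(probs) - 1)
  if (any(dev > 1e-9))
    stopf("validation error at site %d: probabilities sum to %.12f, not 1",
          which(dev > 1e-9)[1], rowSums(probs)[which(dev > 1e-9)[1]])
  rownames(probs) <- NULL
  structure(list(probs = probs), class = "allele_freq_table")
}

#' @rdname allele_freq_table
#' @param x an `allele_freq_table`.
#' @export
n_sites <- function(x) nrow(x$probs)

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("<allele_freq_table> %d site(s)\n", n_sites(x)))
  print(head(x$probs, 4))
  if (n_sites(x) > 4) cat("  ...\n")
  invisible(x)
}

#' Read an allele-frequency TSV
#'
#' Expects a tab-separated file with header `site A C G T`, one row per site,
#' a 1-based site index in column `site`, and per-site probabilities summing
#' to 1 (tolerance `1e-9`).
#'
#' @param path path to the TSV file.
#' @return An [allele_freq_table()].
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!identical(colnames(df), c("site", "A", "C", "G", "T")))
    stopf("frequency TSV must have header 'site\\tA\\tC\\tG\\tT', got: %s",
          paste(colnames(df), collapse = " "))
  if (!identical(as.integer(df$site), seq_len(nrow(df))))
    stopf("site column must be the 1-based index 1..%d", nrow(df))
  allele_freq_table(as.matrix(df[, NUCLEOTIDES]))
}

#' Write an allele-frequency TSV
#'
#' @param freqs an [allele_freq_table()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_frequency_table <- function(freqs, path) {
  stopifnot(inherits(freqs, "allele_freq_table"))
  df <- data.frame(site = seq_len(n_sites(freqs)), freqs$probs,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a SNP-like allele-frequency table
#'
#' Generates biallelic per-site frequencies of the kind obtained by
#' accumulating population allele frequencies from a variant panel: each site
#' gets a uniformly chosen major and minor nucleotide and a minor-allele
#' fraction drawn from `Beta(maf_shape1, maf_shape2)` (defaults give a mean
#' minor-allele fraction of about 0.11, typical of common-variant panels).
#'
#' @param n_sites number of sites (sequence length of generated records).
#' @param seed integer seed.
#' @param maf_shape1,maf_shape2 Beta shape parameters for the minor-allele
#'   fraction.
#' @return An [allele_freq_table()].
#' @export
simulate_frequency_table <- function(n_sites, seed, maf_shape1 = 0.5,
                                     maf_shape2 = 4) {
  stopifnot(n_sites >= 1)
  with_seed(seed, {
    maf <- stats::rbeta(n_sites, maf_shape1, maf_shape2)
    major <- sample.int(4, n_sites, replace = TRUE)
    minor <- ((major - 1 + sample.int(3, n_sites, replace = TRUE)) %% 4) + 1
    probs <- matrix(0, n_sites, 4)
    probs[cbind(seq_len(n_sites), major)] <- 1 - maf
    probs[cbind(seq_len(n_sites), minor)] <-
      probs[cbind(seq_len(n_sites), minor)] + maf
    allele_freq_table(probs)
  })
}

#' Generate synthetic sequences from per-site allele frequencies
#'
#' Every sequence is sampled independently; site `s` of each sequence is
#' drawn from the site-`s` probability vector of `freqs`. This reproduces the
#' construction of a synthetic SNP-panel corpus: a pool of
#' `n_records + n_queries` sequences is generated, the first `n_records`
#' forming the data owner's dataset and the remaining `n_queries` held out as
#' researcher queries. Identical seeds give byte-identical output.
#'
#' @param freqs an [allele_freq_table()].
#' @param n_records number of dataset sequences.
#' @param n_queries number of held-out query sequences.
#' @param seed integer seed.
#' @return A list with elements `dataset` and `queries`, both
#'   [sequence_dataset()]s; all sequences have length `n_sites(freqs)`.
#' @export
generate_dataset <- function(freqs, n_records, n_queries, seed) {
  stopifnot(inherits(freqs, "allele_freq_table"),
            n_records >= 0, n_queries >= 0)
  m <- n_sites(freqs)
  ntot <- n_records + n_queries
  seqs <- with_seed(seed, {
    if (ntot == 0) character(0)
    else {
      idx <- matrix(0L, nrow = m, ncol = ntot)
      for (s in seq_len(m))
        idx[s, ] <- sample.int(4, ntot, replace = TRUE, prob = freqs$probs[s, ])
      chars <- NUCLEOTIDES[idx]
      dim(chars) <- dim(idx)
      vapply(seq_len(ntot),
             function(j) paste(chars[, j], collapse = ""), character(1))
    }
  })
  dsd <- sequence_dataset(
    seqs[seq_len(n_records)],
    if (n_records) sprintf("seq%04d", seq_len(n_records)) else character(0))
  qsd <- sequence_dataset(
    seqs[n_records + seq_len(n_queries)],
    if (n_queries) sprintf("query%03d", seq_len(n_queries)) else character(0))
  list(dataset = dsd, queries = qsd)
}

#' Randomly perturb sequence lengths with single-nucleotide indels
#'
#' Applies to each record an independent, uniformly drawn number of random
#' single-nucleotide insertions/deletions in `[0, max_indels]` (each edit is
#' an insertion or a deletion with equal probability, at a uniform position;
#' inserted nucleotides are uniform over `{A,C,G,T}`). Used to turn the
#' fixed-length output of [generate_dataset()] into the variable-length
#' profiles of realistic corpora. Record ids are preserved. A deletion drawn
#' for an already-empty sequence is clamped (and reported via a message).
#'
#' @param dataset a [sequence_dataset()].
#' @param max_indels maximum number of indels per record (`>= 0`).
#' @param seed integer seed.
#' @return A [sequence_dataset()] with the same ids.
#' @export
perturb_lengths <- function(dataset, max_indels, seed) {
  stopifnot(inherits(dataset, "sequence_dataset"), max_indels >= 0)
  if (max_indels == 0 || n_records(dataset) == 0) return(dataset)
  clamped <- 0L
  out <- with_seed(seed, {
    vapply(dataset$records, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      nops <- sample.int(max_indels + 1L, 1L) - 1L
      for (i in seq_len(nops)) {
        if (runif(1) < 0.5) {               # insertion
          pos <- sample.int(length(ch) + 1L, 1L)
          ch <- append(ch, sample(NUCLEOTIDES, 1L), after = pos - 1L)
        } else {                            # deletion
          if (length(ch) == 0) { clamped <<- clamped + 1L; next }
          ch <- ch[-sample.int(length(ch), 1L)]
        }
      }
      paste(ch, collapse = "")
    }, character(1))
  })
  if (clamped > 0)
    message(sprintf("perturb_lengths: %d deletion(s) clamped on empty sequences",
                    clamped))
  sequence_dataset(unname(out), names(dataset$records))
}
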