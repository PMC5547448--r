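# Experiment harness: seeded accuracy sweeps of the approximation methods
# against the exact baseline, over grids of k and method parameters.

#' Run a seeded accuracy experiment
#'
#' Generates (or loads) a corpus, runs the requested methods over grids of
#' `k` and their method parameter (`w` for the shingle/PSI approximation,
#' `b` for banded, `c` for the joined cascade), measures each against the
#' exact edit-distance ground truth with [accuracy()], and returns one row
#' per `(method, k, parameter, query)` cell, plus the per-cell mean over
#' queries. Deterministic under `seed`.
#'
#' @param config a named list (or path to a flat `key = value` text file)
#'   with entries:
#'   \describe{
#'     \item{dataset_fasta, query_fasta}{optional paths to FASTA inputs; if
#'       absent, a corpus is generated.}
#'     \item{freq_file}{optional allele-frequency TSV driving generation;
#'       if absent, [simulate_frequency_table()] is used.}
#'     \item{n_records, n_queries, n_sites, max_indels}{generator parameters
#'       (defaults 200, 1, 1000, 0).}
#'     \item{k}{integer vector of top-k values (default `c(1, 5, 10)`).}
#'     \item{w, b, c}{parameter grids for approx1 / approx2 / joined
#'       (scalars or vectors; `w = NA` means [optimal_w()]).}
#'     \item{methods}{subset of `c("approx1", "approx2", "joined")`.}
#'     \item{psi}{PSI protocol for approx1/joined (default `"plaintext"`).}
#'     \item{seed}{integer seed (default 1).}
#'   }
#' @param out_tsv optional path; when given, the report is also written as
#'   TSV.
#' @return A data frame with columns `method, k, param_name, param_value,
#'   query_id, accuracy`.
#' @export
run_experiment <- function(config, out_tsv = NULL) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  stopifnot(is.list(config))
  known <- c("dataset_fasta", "query_fasta", "freq_file", "n_records",
             "n_queries", "n_sites", "max_indels", "k", "w", "b", "c",
             "methods", "psi", "seed")
  bad <- setdiff(names(config), known)
  if (length(bad)) stopf("config error: unknown key(s): %s", paste(bad, collapse = ", "))

  seed <- as.integer(config$seed %||% 1L)
  ks <- as.integer(config$k %||% c(1L, 5L, 10L))
  methods <- config$methods %||% c("approx1", "approx2", "joined")
  stopifnot(all(methods %in% c("approx1", "approx2", "joined")))
  psi <- config$psi %||% "plaintext"

  if (!is.null(config$dataset_fasta)) {
    dataset <- read_fasta(config$dataset_fasta)
    queries <- read_fasta(config$query_fasta %||%
                            stopf("config error: query_fasta required with dataset_fasta"))
  } else {
    n_records <- as.integer(config$n_records %||% 200L)
    n_queries <- as.integer(config$n_queries %||% 1L)
    n_sites <- as.integer(config$n_sites %||% 1000L)
    freqs <- if (!is.null(config$freq_file)) read_frequency_table(config$freq_file)
             else simulate_frequency_table(n_sites, derive_seed(seed, "freqs"))
    gen <- generate_dataset(freqs, n_records, n_queries,
                            derive_seed(seed, "corpus"))
    dataset <- gen$dataset; queries <- gen$queries
    max_indels <- as.integer(config$max_indels %||% 0L)
    if (max_indels > 0) {
      dataset <- perturb_lengths(dataset, max_indels, derive_seed(seed, "indel-d"))
      queries <- perturb_lengths(queries, max_indels, derive_seed(seed, "indel-q"))
    }
  }
  if (n_records(queries) == 0) stopf("config error: no query sequences")

  ws <- config$w %||% NA
  bs <- as.integer(config$b %||% 5L)
  cs <- as.integer(config$c %||% 5L)

  rows <- list()
  add <- function(method, k, pname, pval, qid, acc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, k = k, param_name = pname, param_value = pval,
      query_id = qid, accuracy = acc, stringsAsFactors = FALSE)
  }

  for (qi in seq_len(n_records(queries))) {
    qid <- names(queries$records)[qi]
    q <- unname(queries$records[qi])
    truth_by_k <- lapply(ks, function(k)
      topk_exact(dataset, q, query_spec(k)))
    names(truth_by_k) <- as.character(ks)
    for (ki in seq_along(ks)) {
      k <- ks[ki]; truth <- truth_by_k[[ki]]
      if ("approx1" %in% methods) {
        for (w in ws) {
          weff <- if (is.na(w)) optimal_w(nchar(q)) else as.integer(w)
          pred <- topk_approx1(dataset, q, query_spec(k, w = weff),
                               psi_protocol = psi, seed = seed)
          add("approx1", k, "w", weff, qid, accuracy(truth, pred)$accuracy)
        }
      }
      if ("approx2" %in% methods) {
        for (b in bs) {
          pred <- topk_approx2(dataset, q, query_spec(k, band = band_spec(b)))
          add("approx2", k, "b", b, qid, accuracy(truth, pred)$accuracy)
        }
      }
      if ("joined" %in% methods) {
        for (cc in cs) {
          if (cc * k > n_records(dataset)) next
          pred <- topk_joined(dataset, q, query_spec(k, c = cc),
                              psi_protocol = psi, seed = seed)
          add("joined", k, "c", cc, qid, accuracy(truth, pred)$accuracy)
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(out_tsv)) {
    write.table(report, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

# flat "key = value" config files; values split on commas, numerics coerced
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stopf("config parse error: '%s'", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (!anyNA(num)) num else parts
  }
  cfg
}
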