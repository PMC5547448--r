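Package: privspq
Title: Privacy-Preserving Similar Patients Queries via Approximate Edit Distance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Secure approximation of edit distance for top-k Similar Patients
    Queries over genomic sequences held by a data owner, queried by a
    researcher who must not reveal the query. Implements two approximations:
    (1) w-shingling ranked through a two-party private set intersection
    (Diffie-Hellman commutative blinding, plus the insecure salted-hash
    baseline it is contrasted with), and (2) banded (Ukkonen-style) edit
    distance evaluated inside a Yao garbled circuit with point-and-permute,
    oblivious transfer and an optional free-XOR optimization, so that only
    the final distance is revealed. Includes the exact Wagner-Fischer
    baseline, the joined two-stage cascade (shingle/PSI prefilter to top-t,
    t = c*k, then secure banded re-ranking), a tie-aware top-k recall metric,
    FASTA and allele-frequency-table I/O, and a synthetic sequence generator
    that samples per-site nucleotide frequencies to emulate population
    SNP panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    openssl,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: OpenSSL (libcrypto)
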