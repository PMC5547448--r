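# privspq

Privacy-preserving Similar Patients Queries (SPQ) over genomic sequences.

A researcher holds a patient's DNA sequence; a data owner (a hospital or a
genomic data bank) holds a collection of sequences. The researcher wants the
top-k records most similar to the query under **edit distance** — without
revealing the query, and without the owner revealing anything beyond the
final top-k. Exact edit distance is both too slow for long sequences
(O(nm) per pair) and awkward to compute securely, so `privspq` implements
two approximations, each with a matching cryptographic protocol, plus their
combination:

1. **w-shingling + private set intersection (PSI).** Every sequence is
   reduced to its set of length-`w` substrings (shingles). The researcher's
   query shingle set is intersected with the owner's union shingle database
   through a PSI, and the owner ranks its records by how many of their
   shingles fall in the intersection. Two PSI instantiations are provided:
   a Diffie–Hellman commutative-blinding protocol (semi-honest secure), and
   the salted-hash exchange baseline — functionally identical but
   brute-forceable over the `4^w` shingle space, and flagged insecure.
2. **Banded edit distance inside a Yao garbled circuit.** The
   Wagner–Fischer dynamic program restricted to a band of half-width `b`
   around the diagonal (`O(nb)` instead of `O(nm)`; an upper bound that
   equals the exact distance once `b ≥ max(|x|,|y|)`) is compiled into a
   boolean circuit — equality gadgets, saturating adders, minimum gadgets —
   and the *whole* DP is evaluated inside one garbled circuit with
   point-and-permute, a DH-based 1-out-of-2 oblivious transfer, and an
   optional free-XOR optimization. Only the final distance is revealed;
   per-cell comparisons never leak.
3. **Joined cascade.** Shingles + PSI first select the top `t = c·k`
   candidates; the secure banded distance then re-ranks those `t` survivors
   to the final top-k. The cheap stage shrinks the search space for the
   expensive one.

Accuracy against the exact baseline is measured as tie-aware top-k recall,
`accuracy = N_TP / (N_TP + N_FN)`, where the truth set is the exact top-k
*expanded across ties* at rank k.

The package also ships the exact Wagner–Fischer baseline, FASTA and
allele-frequency-table I/O, a synthetic corpus generator (per-site sampling
from SNP-panel-style allele frequencies), an experiment harness, and a CLI
(`inst/cli/spq.R`).

## Worked example

```r
library(privspq)

freqs  <- simulate_frequency_table(1000, seed = 42)          # SNP-like sites
corpus <- generate_dataset(freqs, n_records = 200, n_queries = 1, seed = 43)
query  <- corpus$queries$records[1]

truth <- topk_exact(corpus$dataset, query, query_spec(10))
truth
#> <ranked_result> top-10 (ascending scores), tie-expanded to 12
#>    rank record_id score
#> 1     1   seq0076   135
#> 2     2   seq0074   142
#> ...
#> 12   12   seq0126   152
```

The exact top-10 contains 12 records: three records tie at distance 152, so
the truth set expands across the tie. Now the private two-stage query —
shingle/PSI prefilter to `t = c·k = 50` candidates, then banded re-ranking:

```r
approx <- topk_joined(corpus$dataset, query, query_spec(10, c = 5))
accuracy(truth, approx)
#> <accuracy_report> TP = 9, FN = 3, accuracy = 0.7500 (75.0%)
```

Nine of the twelve true neighbours survive the cascade: recall 75%.
A single secure distance, computed without either party seeing the other's
sequence:

```r
secure_banded_distance("ATGC", "ATGG", band_spec(1), seed = 1)
#> <secure_distance> distance = 1 (bit width 4)
```

And the shingle view of a sequence (repeated substrings count once):

```r
shingle_set("CAACATAGCAAC", 4)
#> <shingle_set> w = 4, 8 shingle(s)
#>   AACA ACAT AGCA ATAG CAAC CATA GCAA TAGC
```

## Command line

```sh
Rscript inst/cli/spq.R gen-data --sites 1000 --n-records 200 --n-queries 5 \
    --seed 1 --out-dataset data.fasta --out-queries queries.fasta
Rscript inst/cli/spq.R build-shingles --fasta data.fasta --w 5 --out shingles.txt
Rscript inst/cli/spq.R query --fasta data.fasta --query q.fasta \
    --mode joined --k 10 --c 5 --band 5 --psi dh --seed 1 --out topk.tsv
Rscript inst/cli/spq.R evaluate --truth truth.tsv --predicted topk.tsv
Rscript inst/cli/spq.R experiment --config sweep.cfg --out report.tsv
```

See `vignettes/secure-similar-patients-queries.Rmd` for the model,
protocol and design discussion.
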