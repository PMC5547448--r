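---
title: "Secure approximation of edit distance for Similar Patients Queries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secure approximation of edit distance for Similar Patients Queries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privspq)
```

## The problem

A Similar Patients Query (SPQ) retrieves, from a data owner's collection of
genomic sequences, the top-k records most similar to a researcher's query
sequence. Similarity is Levenshtein edit distance: the minimum number of
unit-cost insertions, deletions and substitutions transforming one sequence
into the other (matches cost zero). Genomic sequences identify individuals,
so neither side can simply hand its data to the other: the researcher's
query and the owner's records must both stay private, with only the final
top-k revealed. Both parties are modelled as *semi-honest*: they follow the
protocol but may try to infer extra information from the messages they see.

Exact edit distance costs O(nm) per pair, which is prohibitive for long
sequences and even more so under cryptographic protection. `privspq`
therefore implements two approximations with complementary profiles — one
fast and coarse, one near-exact and expensive — plus their cascade.

## Approximation 1: shingles ranked through PSI

A *w-shingle* is any length-w substring of a sequence; the shingle set is
the deduplicated collection of all such substrings (`shingle_set()`,
set semantics — a substring occurring twice counts once). Similar sequences
share most of their shingles, so the number of query shingles a record
contains is a cheap similarity proxy.

The private pipeline (`topk_approx1()`): the owner builds the per-record
shingle sets and their union (`build_shingle_db()`); the researcher's query
shingle set is intersected **once** with that union through a private set
intersection (PSI); the owner — who learns the intersection, and must,
since it ranks its own records — counts per-record matches locally and
returns the top-k. Running one PSI against the union rather than one per
record matches the global shingle database the owner stores anyway and
keeps the protocol round count independent of the collection size.

Two PSI instantiations share one interface:

* `psi_dh()`: Diffie–Hellman commutative blinding. Each shingle is hashed
  to an exponent and mapped to `g^H(x)`; each party blinds with its secret
  scalar; double-blinded values coincide exactly for shared shingles. The
  transcript contains only group elements. We use safe-prime groups with
  generator `g = 4`: the square of 2 is a quadratic residue for *every*
  safe prime, hence of order exactly `q = (p-1)/2`, which the mod-`q`
  exponent arithmetic requires (a generator of order `2q` would silently
  break the blinding commutativity for half the elements). The
  production group is the 2048-bit RFC 3526 MODP group; a fixed 512-bit
  safe-prime group (`"modp512"`) is provided for fast protocol runs in
  tests and is documented as reduced-strength.
* `psi_naive_hash()`: both sides exchange `SHA256(salt || shingle)`.
  Functionally identical, and faster — but a `w`-shingle takes only `4^w`
  values, so anyone can enumerate the space, hash every candidate with the
  public salt, and read the other party's set off the transcript. The test
  suite demonstrates exactly this attack; the result object is flagged
  `secure = FALSE`. It exists as the baseline the secure protocol is
  measured against, not for use.

The permutation-based-hashing PSI family (with OT extension) that achieves
still better asymptotics is deliberately out of scope; the DH protocol has
the same input/output contract and is self-contained.

**Choosing w.** `optimal_w(l)` returns `max(1, ceil(log4(l)))` — the width
at which the `4^w` shingle space first reaches the sequence length. We use
the ceiling rather than floor or round: at widths below `log4(l)` the
shingle space saturates (nearly every shingle occurs in nearly every
record), match counts lose discrimination and false positives inflate.
Records shorter than `w` are an error, not an empty set — a silent empty
set would zero that record's similarity and quietly corrupt the ranking.

## Approximation 2: banded edit distance in a garbled circuit

The banded (Ukkonen-style) dynamic program computes only the DP cells
`(i, j)` with `|i − j| ≤ b_eff`, treating out-of-band neighbours as `+Inf`
(`banded_edit_distance()`). It costs O(nb), upper-bounds the exact
distance, is monotone non-increasing in `b`, and equals the exact distance
once `b ≥ max(|x|, |y|)`. For unequal lengths no alignment path exists
within a narrow band, so the effective half-width is
`b_eff = max(b, ||x| − |y||)` — the minimal widening that keeps every pair
rankable; a ranking over records cannot use an infinite sentinel.

To run this privately (`secure_banded_distance()`), the *entire* DP is
compiled into one boolean circuit (`compile_banded_ed_circuit()`) and
evaluated under Yao's garbled-circuit protocol. Evaluating per-cell
character comparisons in separate small circuits would leak: with a
four-letter alphabet, a curious party could exhaustively probe positions.
One circuit, one output — the distance — is the whole point.

Circuit construction, per in-band cell: a 2-bit equality gadget
(nucleotides encoded `A=00, C=01, G=10, T=11`), three saturating adders and
two minimum gadgets. Registers are `bit_width`-wide,
defaulting to `ceil(log2(max_len + 1)) + 1` — one headroom bit above the
largest possible distance. The out-of-band `+Inf` is the all-ones constant;
the adders *saturate* at all-ones, so "infinity plus one" cannot wrap
around and undercut a genuine distance (whether to saturate or wrap at the
band boundary is a genuinely open choice; wrapping is simply wrong at this
width, so we saturate). Public boundary values (`D[i][0] = i`,
`D[0][j] = j`) and the infinity pattern are folded at compile time, so they
cost no gates and carry no labels. Sequence lengths and the band are public
protocol parameters — the circuit topology necessarily reveals them — and
only the residues are private.

The garbling scheme is the standard point-and-permute construction with an
explicit integrity check: every wire has two 16-byte labels with
complementary permute bits (the label's last bit); a gate row is
`H(labelA || labelB || gate_id) XOR (output_label || 16 zero bytes)` with
`H = SHA-256`, rows ordered by permute bits; the zero tag marks the one row
that decrypts validly. Labels come from a counter-mode SHA-256 CSPRNG
seeded explicitly, so protocol runs are reproducible. Free-XOR
(`label1 = label0 XOR delta` globally, XOR gates without tables) is an
optimization flag, off by default; the suite asserts it never changes an
output. The data owner plays generator, the researcher evaluator; the
evaluator's input-wire labels are delivered through a DH-based 1-out-of-2
oblivious transfer (Bellare–Micali style: the receiver's two candidate
public keys multiply to a sender-chosen group element of unknown discrete
log, so it can know the secret key of exactly one). The hot loops —
garbling and evaluation — are in C++ (Rcpp), calling OpenSSL's SHA-256;
the circuit compiler and the protocols are R.

## The joined cascade

`topk_joined()` runs approximation 1 to select the top `t = c·k`
candidates, then re-ranks only those survivors with the (optionally
secure) banded distance. The cascade factor `c` trades accuracy for time:
larger `t` lets the accurate stage see more of the true neighbourhood. `c`
has no closed-form rule — it depends on `k`, the sequence length and the
collection size — so it stays a user parameter, defaulting to 5 (as do
`b = 5` and `w = optimal_w(query length)`, the package's benchmark-style
settings). Revealing the `t` intermediate records to the owner leaks
nothing new: the owner computes them itself, and they never reach the
researcher.

**Ties.** Ranked outputs expand at rank k: every record tied with the
rank-k score is returned, with a deterministic secondary ordering by record
id; the tie-aware recall metric
(`accuracy = N_TP / (N_TP + N_FN)`) takes the *expanded* exact top-k as its
denominator. Stage 1 of the cascade is the one deliberate exception: it
truncates at exactly `t` survivors (id tie-break) rather than expanding.
The cascade's defining property — the final top-k is contained in the
stage-1 survivor set, which holds under truncation too — and the survivor
arithmetic (`t = c·k` exactly: 2000 records, `k = 10`, `c = 5` passes
exactly 50) would otherwise wobble with data-dependent tie widths; on long
integer-valued match-count scales, boundary ties are common.

## Synthetic data

Real SPQ corpora are built from variant panels, which cannot be
redistributed. `simulate_frequency_table()` emulates their statistical
shape: biallelic sites with a uniformly chosen major/minor nucleotide and a
minor-allele fraction drawn from Beta(0.5, 4) (mean ≈ 0.11, typical of
accumulated common-variant population frequencies).
`generate_dataset()` then samples every sequence i.i.d. per site from the
table — so records share the panel's structure but are unrelated
individuals — and splits the pool into the owner's collection and held-out
queries. Length variation, when wanted, is applied afterwards by
`perturb_lengths()` (uniform count of random single-nucleotide indels per
record): the sampler stays exactly per-site i.i.d., and the two concerns
stay separately testable. Whether real corpora's length variation arises
from indels or from per-individual site counts is not something this
generator claims to settle; the indel step is a stand-in.

What this emulates — and what it does not: per-site allele frequencies,
fixed-panel structure, SNP-like substitution dominance. It does **not**
model linkage disequilibrium, population stratification, relatedness,
structural variants or sequencing error. Passing accuracy properties on
this corpus shows the pipeline ranks correctly when similarity structure
is present; it does not certify accuracy figures on any real cohort.

All sampling flows through explicit integer seeds (R's RNG inside a
save/restore guard, so library calls never disturb the caller's RNG
state); cryptographic material is derived separately through a seeded
SHA-256 counter stream.

## Numerical and engineering choices

* Alphabet strictly `{A, C, G, T}`; ambiguity codes are rejected, not
  coerced — the `4^w` shingle-space arithmetic and the 2-bit circuit
  encoding both assume four letters.
* Frequency TSVs have the fixed header `site A C G T` with a 1-based site
  index and rows summing to 1 within 1e-9, for bit-exact interchange.
* The DP kernels keep two rolling rows (O(min length) memory); the banded
  kernel guards band-edge neighbours explicitly so stale cells are never
  read.
* Both protocol parties run in one process over an in-memory `channel()`
  with an append-only transcript; correctness is transport-independent,
  and the transcript is the object of the security-structure tests (no
  plaintext shingle ever crosses the DH-PSI wire; at most one label per
  evaluator wire, and none in the clear; exactly one garbled row decrypts
  per gate). A TCP transport would be a drop-in replacement and is not
  required.
* Both distance registers saturate rather than wrap; decode checks a
  16-byte zero tag and fails loudly on corrupted tables.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run on deliberately scaled
corpora chosen as representative rather than exhaustive: oracle-equivalence
sweeps on sequences up to length 20–30 (against an exhaustive-recursion
edit-distance oracle up to length 5 over a two-letter alphabet, a
full-matrix banded oracle, and `utils::adist` as an independent
implementation); 1000 random PSI set pairs; survivor arithmetic on a
2000-record corpus; and accuracy properties on a 200-record, 1000-site
corpus with 25 held-out queries — where full-band banded recall is exactly
1, the joined cascade's mean recall rises monotonically over
`c ∈ {1, 2, 5, 10}`, and the shingle/PSI ranking beats a random top-k
draw several-fold.

## Known limitations

* Semi-honest security only: no malicious-security machinery
  (cut-and-choose, OT extension, consistency proofs).
* The garbled circuit reveals sequence lengths and the band; applications
  needing length privacy must pad inputs.
* Shingle/PSI ranking degrades on long sequences as the shingle space
  saturates — which is precisely the regime the banded stage exists for.
* The 512-bit group exists for test speed, not security; production use
  should stay on the 2048-bit group.
* Cost-only distances: no traceback, no affine gaps, no similarity
  scoring.
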