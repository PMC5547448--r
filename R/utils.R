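# Internal helpers: seeded randomness plumbing.
#
# Two kinds of randomness coexist. Statistical sampling (synthetic sequences,
# test-style perturbations) goes through R's RNG inside with_seed(), so the
# caller's global RNG state is never consumed or disturbed. Cryptographic
# material (wire labels, protocol secrets, salts) is derived from an explicit
# integer seed through a SHA-256 counter-mode stream (.cpp_prng_bytes), so
# protocol runs are bit-reproducible.

with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# 32-byte key from an integer seed and a domain-separation context string
derive_key <- function(seed, context) {
  .cpp_sha256(charToRaw(paste0("privspq/", context, "/", format(seed, scientific = FALSE))))
}

# sub-seed (< 2^31) for nested seeded operations
derive_seed <- function(seed, context) {
  b <- as.integer(derive_key(seed, context)[1:4])
  s <- (((b[1] * 256 + b[2]) * 256 + b[3]) * 256 + b[4]) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

NUCLEOTIDES <- c("A", "C", "G", "T")
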