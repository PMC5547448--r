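# Multiplicative groups for the DH-style protocols (PSI blinding, oblivious
# transfer). Both are safe-prime groups: p = 2q + 1 with q prime. The
# generator is g = 4 = 2^2, a quadratic residue for every safe prime and
# hence of order exactly q — which matters because all exponent arithmetic
# is done mod q, and a generator of order 2q would break the commutative
# blinding for half the elements. Set elements are hashed to exponents, so
# "hash-to-group" is g^(H(x) mod q) and commutative blinding needs a single
# modular exponentiation per element.

# RFC 3526 group 14 (2048-bit MODP), the production-strength group.
.MODP2048_HEX <- paste0(
  "FFFFFFFFFFFFFFFFC90FDAA22168C234C4C6628B80DC1CD129024E088A67CC74",
  "020BBEA63B139B22514A08798E3404DDEF9519B3CD3A431B302B0A6DF25F1437",
  "4FE1356D6D51C245E485B576625E7EC6F44C42E9A637ED6B0BFF5CB6F406B7ED",
  "EE386BFB5A899FA5AE9F24117C4B1FE649286651ECE45B3DC2007CB8A163BF05",
  "98DA48361C55D39A69163FA8FD24CF5F83655D23DCA3AD961C62F356208552BB",
  "9ED529077096966D670C354E4ABC9804F1746C08CA18217C32905E462E36CE3B",
  "E39E772C180E86039B2783A2EC07A28FB5C55DF06F4C52C9DE2BCBF695581718",
  "3995497CEA956AE515D2261898FA051015728E5A8AACAA68FFFFFFFFFFFFFFFF")

# Fixed 512-bit safe prime (generated once with `openssl prime -generate
# -safe -bits 512`). Reduced-strength group used to keep test-suite protocol
# runs fast; not for production use.
.MODP512_HEX <- paste0(
  "E9CFB327667F762EA07BFD87BE4BFABEF14D64BB6C093864F56CEB6BDE7566F2",
  "9C93519306A3210C8825795AFC50FD5D19BF5E80EB0EA0CADFB44AB9531278BB")

#' Named Diffie-Hellman group
#'
#' @param name `"modp2048"` (RFC 3526 group 14; default for protocols) or
#'   `"modp512"` (fixed 512-bit safe prime; reduced strength, intended for
#'   fast test runs).
#' @return List with bignum fields `p` (safe prime), `q = (p-1)/2` (subgroup
#'   order), `g` (generator 4, of order `q`) and `nbytes` (byte width of
#'   serialized elements).
#' @export
dh_group <- function(name = c("modp2048", "modp512")) {
  name <- match.arg(name)
  hex <- switch(name, modp2048 = .MODP2048_HEX, modp512 = .MODP512_HEX)
  p <- openssl::bignum(hex, hex = TRUE)
  q <- (p - openssl::bignum(1L)) %/% openssl::bignum(2L)
  list(name = name, p = p, q = q, g = openssl::bignum(4L),
       nbytes = nchar(hex) %/% 2L)
}

# left-pad a bignum to the group's fixed element width
bn_to_raw <- function(x, nbytes) {
  b <- as.raw(x)
  if (length(b) > nbytes) stopf("bignum wider than group element width")
  c(raw(nbytes - length(b)), b)
}

raw_to_bn <- function(bytes) openssl::bignum(bytes)

# hash a string to an exponent in [1, q-1]
hash_to_exponent <- function(item, grp, domain = "psi-element") {
  h <- .cpp_sha256(c(charToRaw(domain), as.raw(0L), charToRaw(item)))
  e <- raw_to_bn(h) %% grp$q
  if (e == openssl::bignum(0L)) e <- openssl::bignum(1L)
  e
}

# deterministic secret scalar in [1, q-1] from a 32-byte key stream
scalar_from_key <- function(key32, grp) {
  b <- .cpp_prng_bytes(key32, grp$nbytes + 8L)
  s <- raw_to_bn(b) %% grp$q
  if (s == openssl::bignum(0L)) s <- openssl::bignum(1L)
  s
}

mod_exp <- function(base, exp, grp) openssl::bignum_mod_exp(base, exp, grp$p)

# modular inverse via Fermat (p prime)
mod_inv <- function(x, grp) {
  openssl::bignum_mod_exp(x, grp$p - openssl::bignum(2L), grp$p)
}
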