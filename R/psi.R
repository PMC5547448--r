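# Two-party private set intersection over shingle sets. Two instantiations:
# a Diffie-Hellman commutative-blinding protocol (secure in the semi-honest
# model), and the naive salted-hash exchange it is contrasted with — which is
# functionally identical but breakable by brute force over the 4^w shingle
# space, and therefore flagged insecure.
#
# Output direction: the data owner learns the intersection (it must rank its
# records by match count); the researcher learns nothing at this stage beyond
# the owner's set size.

#' Private set intersection via Diffie-Hellman commutative blinding
#'
#' Each shingle is hashed to an exponent and mapped to the group element
#' `g^H(x)`; each party blinds elements with its secret scalar, so that
#' double-blinded values `g^(H(x)*r*o)` coincide exactly when the underlying
#' shingles do. Protocol flow (researcher set `A`, owner set `B`):
#' \enumerate{
#'   \item researcher sends `g^(H(a_i) * r)` for each of its shingles;
#'   \item owner raises each to its secret `o` and keeps the set;
#'   \item owner sends `g^(H(b_j) * o)`;
#'   \item researcher raises each to `r` and returns them in order;
#'   \item owner intersects the two double-blinded sets and maps matches back
#'     to its own shingles.
#' }
#' The owner learns exactly the plaintext intersection; the transcript
#' contains only blinded group elements.
#'
#' @param researcher_set,owner_set [shingle_set()]s with equal `w`.
#' @param channel a [channel()]; created if `NULL`. Holds the audit
#'   transcript afterwards.
#' @param seed integer seed driving both parties' secret scalars.
#' @param group group name passed to [dh_group()].
#' @return An object of class `psi_result`: fields `intersection`
#'   (a `shingle_set`), `learned_by = "data_owner"`, `protocol`, `secure`.
#' @export
psi_dh <- function(researcher_set, owner_set, channel = NULL, seed = 1L,
                   group = c("modp2048", "modp512")) {
  check_psi_inputs(researcher_set, owner_set)
  group <- match.arg(group)
  ch <- channel %||% channel()
  grp <- dh_group(group)
  r_sec <- scalar_from_key(derive_key(seed, "psi-dh-researcher"), grp)
  o_sec <- scalar_from_key(derive_key(seed, "psi-dh-owner"), grp)

  # researcher: single-blinded query shingles
  blind1 <- lapply(researcher_set$items, function(it) {
    e <- (hash_to_exponent(it, grp) * r_sec) %% grp$q
    bn_to_raw(mod_exp(grp$g, e, grp), grp$nbytes)
  })
  ch_send(ch, "researcher", pack_blobs(blind1, grp$nbytes), "researcher-blinded")

  # owner: double-blind the researcher's elements (kept local)
  rcv <- unpack_blobs(ch_recv(ch, "data_owner"))
  double_r <- vapply(rcv, function(b) {
    paste(as.character(bn_to_raw(mod_exp(raw_to_bn(b), o_sec, grp), grp$nbytes)),
          collapse = "")
  }, character(1))

  # owner: single-blinded own shingles
  blind2 <- lapply(owner_set$items, function(it) {
    e <- (hash_to_exponent(it, grp) * o_sec) %% grp$q
    bn_to_raw(mod_exp(grp$g, e, grp), grp$nbytes)
  })
  ch_send(ch, "data_owner", pack_blobs(blind2, grp$nbytes), "owner-blinded")

  # researcher: double-blind the owner's elements, return in order
  rcv2 <- unpack_blobs(ch_recv(ch, "researcher"))
  double_o <- lapply(rcv2, function(b) {
    bn_to_raw(mod_exp(raw_to_bn(b), r_sec, grp), grp$nbytes)
  })
  ch_send(ch, "researcher", pack_blobs(double_o, grp$nbytes), "owner-double-blinded")

  # owner: match double-blinded values
  back <- unpack_blobs(ch_recv(ch, "data_owner"))
  hex_back <- vapply(back, function(b) paste(as.character(b), collapse = ""),
                     character(1))
  matched <- owner_set$items[hex_back %in% double_r]
  new_psi_result(sort(matched), researcher_set$w, "dh", secure = TRUE, ch)
}

#' Private set intersection via salted-hash exchange (insecure baseline)
#'
#' The owner sends a random salt; the researcher replies with
#' `SHA256(salt || shingle)` for each of its shingles; the owner hashes its
#' own shingles locally and intersects. Functionally identical to
#' [psi_dh()], but insecure: because a `w`-shingle takes only `4^w` values,
#' an adversary can enumerate the whole shingle space, hash every candidate
#' with the public salt and recover the researcher's set from the
#' transcript. The result is flagged `secure = FALSE`.
#'
#' @inheritParams psi_dh
#' @return A `psi_result` with `secure = FALSE` and an `insecurity_note`.
#' @export
psi_naive_hash <- function(researcher_set, owner_set, channel = NULL,
                           seed = 1L) {
  check_psi_inputs(researcher_set, owner_set)
  ch <- channel %||% channel()
  salt <- .cpp_prng_bytes(derive_key(seed, "psi-naive-salt"), 16L)
  ch_send(ch, "data_owner", salt, "salt")

  salt_r <- ch_recv(ch, "researcher")
  if (length(salt_r) != 16) stopf("protocol abort: malformed salt message")
  hashes <- lapply(researcher_set$items,
                   function(it) .cpp_sha256(c(salt_r, charToRaw(it))))
  ch_send(ch, "researcher", pack_blobs(hashes, 32L), "researcher-hashes")

  rcv <- unpack_blobs(ch_recv(ch, "data_owner"))
  hex_rcv <- vapply(rcv, function(b) paste(as.character(b), collapse = ""),
                    character(1))
  own_hex <- vapply(owner_set$items, function(it) {
    paste(as.character(.cpp_sha256(c(salt, charToRaw(it)))), collapse = "")
  }, character(1))
  matched <- owner_set$items[own_hex %in% hex_rcv]
  res <- new_psi_result(sort(matched), researcher_set$w, "naive_hash",
                        secure = FALSE, ch)
  res$insecurity_note <-
    "salted hashes of w-shingles are brute-forceable over the 4^w shingle space"
  res
}

check_psi_inputs <- function(a, b) {
  stopifnot(inherits(a, "shingle_set"), inherits(b, "shingle_set"))
  if (a$w != b$w)
    stopf("protocol abort: shingle width mismatch (researcher w=%d, owner w=%d)",
          a$w, b$w)
  invisible(TRUE)
}

new_psi_result <- function(items, w, protocol, secure, ch) {
  structure(list(intersection = new_shingle_set(items, w),
                 learned_by = "data_owner", protocol = protocol,
                 secure = secure, channel = ch),
            class = "psi_result")
}

#' @export
print.psi_result <- function(x, ...) {
  cat(sprintf("<psi_result> protocol = %s (%s), |intersection| = %d, learned by %s\n",
              x$protocol, if (x$secure) "secure" else "INSECURE",
              length(x$intersection$items), x$learned_by))
  invisible(x)
}
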