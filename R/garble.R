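# Yao garbled-circuit engine: garbling, oblivious transfer, evaluation, and
# the two-party secure banded edit distance built on top of them.
#
# Scheme: each wire has two 16-byte labels with complementary point-and-
# permute bits (the last bit of the label). Row ciphertext =
# H(labelA || labelB || gate_id) XOR (output_label || 16 zero bytes), rows
# ordered by the permute bits; H is SHA-256. The 16-byte zero tag detects the
# valid row, alongside point-and-permute. Free-XOR is an optional
# optimization (off by default): with it, label1 = label0 XOR delta globally
# and XOR gates need no table.

#' Garble a boolean circuit
#'
#' Draws all wire labels from a seeded counter-mode SHA-256 stream, encrypts
#' each gate's truth table with keys derived from both input labels and the
#' gate id, and orders rows by permute bits (point-and-permute).
#'
#' @param circuit a `boolean_circuit` (e.g. from
#'   [compile_banded_ed_circuit()]).
#' @param seed integer seed for the label CSPRNG.
#' @param free_xor logical; garble XOR gates for free (default `FALSE`).
#' @return An object of class `garbled_circuit`. The fields `tables`,
#'   `offsets`, `nrows` are the public garbled gates; `label0` / `label1`
#'   are the generator's secret label tables (used to encode inputs and to
#'   decode outputs) and must not be sent wholesale to the evaluator.
#' @export
garble <- function(circuit, seed, free_xor = FALSE) {
  stopifnot(inherits(circuit, "boolean_circuit"))
  if (nrow(circuit$gates) > 0) {
    outs <- circuit$gates[, "out"]
    ins <- c(circuit$gates[, "in1"],
             circuit$gates[circuit$gates[, "kind"] != GK_NOT, "in2"])
    if (anyDuplicated(outs) || any(outs %in% circuit$input_wires$generator) ||
        any(outs %in% circuit$input_wires$evaluator))
      stopf("structural error: circuit is not in single-assignment form")
  }
  g <- .cpp_gc_garble(circuit$gates, circuit$n_wires,
                      derive_key(seed, "garble-labels"), free_xor)
  structure(list(circuit = circuit, tables = g$tables, offsets = g$offsets,
                 nrows = g$nrows, label0 = g$label0, label1 = g$label1,
                 free_xor = free_xor),
            class = "garbled_circuit")
}

#' @export
print.garbled_circuit <- function(x, ...) {
  cat(sprintf("<garbled_circuit> %d gate(s), %d table row(s)%s\n",
              nrow(x$circuit$gates), length(x$tables) %/% 32L,
              if (x$free_xor) ", free-XOR" else ""))
  invisible(x)
}

# 16-byte label of wire w for bit value v, from the generator's tables
gc_label <- function(garbled, wire, value) {
  src <- if (value) garbled$label1 else garbled$label0
  src[(wire - 1L) * 16L + seq_len(16L)]
}

#' Evaluate a garbled circuit
#'
#' Gate-by-gate decryption using the permute bits of the active labels;
#' exactly one row per gate decrypts to a label with a valid (all-zero) tag.
#' A failed tag raises an integrity error.
#'
#' @param garbled a [garble()] result (the evaluator only needs its public
#'   parts plus one active label per input wire).
#' @param active_labels named list mapping input wire id to its active
#'   16-byte label (the generator's own labels sent directly, the
#'   evaluator's obtained via [oblivious_transfer()]).
#' @param audit logical; additionally try every table row per gate and
#'   record how many decrypt validly (security-structure diagnostics).
#' @return List with `value` (decoded non-negative integer), `output_labels`
#'   (active labels of output wires), `audit_rows` (per-gate valid-row
#'   counts, `-1` for free-XOR gates) and `bit_width`.
#' @export
evaluate <- function(garbled, active_labels, audit = FALSE) {
  stopifnot(inherits(garbled, "garbled_circuit"))
  circ <- garbled$circuit
  act <- raw(circ$n_wires * 16L)
  has <- logical(circ$n_wires)
  for (w in names(active_labels)) {
    wi <- as.integer(w)
    act[(wi - 1L) * 16L + seq_len(16L)] <- active_labels[[w]]
    has[wi] <- TRUE
  }
  ev <- .cpp_gc_evaluate(circ$gates, circ$n_wires, garbled$tables,
                         garbled$offsets, garbled$nrows, act, has,
                         garbled$free_xor, audit)
  out_wires <- circ$output_bits[circ$output_bits > 0L]
  out_labels <- lapply(out_wires, function(w) ev$active[(w - 1L) * 16L + seq_len(16L)])
  names(out_labels) <- as.character(out_wires)
  value <- decode_output(garbled, out_labels)
  list(value = value, output_labels = out_labels,
       audit_rows = if (audit) ev$audit else NULL,
       bit_width = length(circ$output_bits))
}

# generator-side decoding: map each output wire's active label back to a bit
decode_output <- function(garbled, output_labels) {
  circ <- garbled$circuit
  bits <- vapply(seq_along(circ$output_bits), function(i) {
    b <- circ$output_bits[i]
    if (b == 0L) return(FALSE)
    if (b == -1L) return(TRUE)
    lab <- output_labels[[as.character(b)]]
    if (identical(lab, gc_label(garbled, b, FALSE))) FALSE
    else if (identical(lab, gc_label(garbled, b, TRUE))) TRUE
    else stopf("integrity error: output label of wire %d matches neither value", b)
  }, logical(1))
  as.integer(sum(2^(seq_along(bits) - 1) * bits))
}

#' 1-out-of-2 oblivious transfer (Diffie-Hellman based)
#'
#' Bellare-Micali-style construction over a safe-prime group: the sender
#' publishes a random group element `c` of unknown discrete log; the
#' receiver's two candidate public keys satisfy `PK0 * PK1 = c`, so it can
#' know the secret key of exactly one. The receiver obtains
#' `sender_msgs[[choice_bit + 1]]`; the sender's transcript is independent of
#' the choice bit, and the other message stays hidden behind a fresh DH key.
#'
#' @param sender_msgs list of two equal-length raw vectors.
#' @param choice_bit 0 or 1.
#' @param channel a [channel()]; sender is `data_owner`, receiver
#'   `researcher`.
#' @param seed integer seed for both parties' ephemeral secrets.
#' @param group group name for [dh_group()] (tests use the fast reduced-
#'   strength group).
#' @return The chosen message (raw vector).
#' @export
oblivious_transfer <- function(sender_msgs, choice_bit, channel = NULL,
                               seed = 1L, group = c("modp512", "modp2048")) {
  stopifnot(is.list(sender_msgs), length(sender_msgs) == 2,
            is.raw(sender_msgs[[1]]), is.raw(sender_msgs[[2]]))
  if (length(sender_msgs[[1]]) != length(sender_msgs[[2]]))
    stopf("protocol abort: OT messages must have equal length")
  choice_bit <- as.integer(choice_bit)
  stopifnot(choice_bit %in% c(0L, 1L))
  group <- match.arg(group)
  grp <- dh_group(group)
  ch <- channel %||% channel()
  mlen <- length(sender_msgs[[1]])
  if (mlen > 32) stopf("OT messages longer than 32 bytes are not supported")

  # sender: random c with unknown dlog for the receiver
  s <- scalar_from_key(derive_key(seed, "ot-sender-c"), grp)
  cc <- mod_exp(grp$g, s, grp)
  ch_send(ch, "data_owner", bn_to_raw(cc, grp$nbytes), "ot-c")

  # receiver: PK_b = g^x, PK_{1-b} = c / PK_b; sends PK0
  cc_r <- raw_to_bn(ch_recv(ch, "researcher"))
  x <- scalar_from_key(derive_key(seed, "ot-receiver-x"), grp)
  pk_b <- mod_exp(grp$g, x, grp)
  pk_other <- (cc_r * mod_inv(pk_b, grp)) %% grp$p
  pk0 <- if (choice_bit == 0L) pk_b else pk_other
  ch_send(ch, "researcher", bn_to_raw(pk0, grp$nbytes), "ot-pk0")

  # sender: encrypt both messages under fresh DH keys
  pk0_s <- raw_to_bn(ch_recv(ch, "data_owner"))
  pk1_s <- (cc * mod_inv(pk0_s, grp)) %% grp$p
  r0 <- scalar_from_key(derive_key(seed, "ot-sender-r0"), grp)
  r1 <- scalar_from_key(derive_key(seed, "ot-sender-r1"), grp)
  pad <- function(pk, r, tag) {
    k <- .cpp_sha256(c(bn_to_raw(mod_exp(pk, r, grp), grp$nbytes), as.raw(tag)))
    k[seq_len(mlen)]
  }
  e0 <- xor_raw(sender_msgs[[1]], pad(pk0_s, r0, 0L))
  e1 <- xor_raw(sender_msgs[[2]], pad(pk1_s, r1, 1L))
  ch_send(ch, "data_owner",
          c(bn_to_raw(mod_exp(grp$g, r0, grp), grp$nbytes), e0,
            bn_to_raw(mod_exp(grp$g, r1, grp), grp$nbytes), e1),
          "ot-ciphertexts")

  # receiver: derive the key for its branch only
  msg <- ch_recv(ch, "researcher")
  if (length(msg) != 2 * (grp$nbytes + mlen))
    stopf("protocol abort: malformed OT ciphertext message")
  off <- if (choice_bit == 0L) 0L else grp$nbytes + mlen
  gr <- raw_to_bn(msg[off + seq_len(grp$nbytes)])
  eb <- msg[off + grp$nbytes + seq_len(mlen)]
  kb <- .cpp_sha256(c(bn_to_raw(mod_exp(gr, x, grp), grp$nbytes),
                      as.raw(choice_bit)))
  xor_raw(eb, kb[seq_len(mlen)])
}

xor_raw <- function(a, b) as.raw(bitwAnd(255L, bitwXor(as.integer(a), as.integer(b))))

#' Secure two-party banded edit distance
#'
#' Runs the whole banded edit-distance dynamic program inside one garbled
#' circuit: the data owner (generator) compiles and garbles the circuit for
#' the public lengths and band, sends the garbled tables and its own input
#' labels; the researcher (evaluator) obtains the labels of its sequence
#' bits through [oblivious_transfer()], evaluates gate by gate and returns
#' the output-wire labels; the owner decodes and shares the distance.
#' Sequence lengths and the band are public protocol parameters; only the
#' residues are private, and nothing but the final distance is revealed.
#'
#' The output equals [banded_edit_distance()] on the same inputs for all
#' inputs. Zero-length sequences are resolved without a circuit, since the
#' distance then equals the (public) other length.
#'
#' @param owner_seq,researcher_seq sequences over `{A,C,G,T}`.
#' @param band a [band_spec()].
#' @param channel a [channel()]; created if `NULL`.
#' @param seed integer seed (labels, OT secrets).
#' @param bit_width optional register width, see
#'   [compile_banded_ed_circuit()].
#' @param free_xor garble XOR gates for free (optimization flag).
#' @param audit collect per-gate valid-row counts and label diagnostics.
#' @param group DH group for the oblivious transfers.
#' @return An object of class `secure_distance`: `distance`, `bit_width`,
#'   `channel`, and (if `audit`) `audit_rows` plus `evaluator_labels`
#'   bookkeeping.
#' @export
secure_banded_distance <- function(owner_seq, researcher_seq, band,
                                   channel = NULL, seed = 1L,
                                   bit_width = NULL, free_xor = FALSE,
                                   audit = FALSE,
                                   group = c("modp512", "modp2048")) {
  owner_seq <- check_residues(toupper(owner_seq), "owner_seq")
  researcher_seq <- check_residues(toupper(researcher_seq), "researcher_seq")
  group <- match.arg(group)
  ch <- channel %||% channel()
  if (nchar(owner_seq) == 0 || nchar(researcher_seq) == 0) {
    d <- max(nchar(owner_seq), nchar(researcher_seq))
    return(structure(list(distance = d, bit_width = 0L, channel = ch,
                          audit_rows = NULL, degenerate = TRUE),
                     class = "secure_distance"))
  }

  circuit <- compile_banded_ed_circuit(nchar(owner_seq), nchar(researcher_seq),
                                       band, bit_width)
  garbled <- garble(circuit, seed, free_xor = free_xor)

  # owner -> researcher: garbled tables (public part) and owner input labels
  ch_send(ch, "data_owner", garbled$tables, "garbled-tables")
  x_bits <- nucleotide_bits(owner_seq)
  gen_labels <- lapply(seq_along(circuit$input_wires$generator), function(i) {
    gc_label(garbled, circuit$input_wires$generator[i], x_bits[i] == 1L)
  })
  ch_send(ch, "data_owner", pack_blobs(gen_labels, 16L), "generator-labels")

  # researcher: receive the garbled material, then one OT per own input wire
  tables_rx <- ch_recv(ch, "researcher")
  gen_labels_rx <- unpack_blobs(ch_recv(ch, "researcher"))
  eval_view <- garbled
  eval_view$tables <- tables_rx          # evaluation runs on received bytes
  y_bits <- nucleotide_bits(researcher_seq)
  eva_wires <- circuit$input_wires$evaluator
  active <- gen_labels_rx
  names(active) <- as.character(circuit$input_wires$generator)
  for (i in seq_along(eva_wires)) {
    w <- eva_wires[i]
    lab <- oblivious_transfer(
      list(gc_label(garbled, w, FALSE), gc_label(garbled, w, TRUE)),
      y_bits[i], channel = ch, seed = derive_seed(seed, paste0("ot-wire-", w)),
      group = group)
    active[[as.character(w)]] <- lab
  }

  ev <- evaluate(eval_view, active, audit = audit)
  ch_send(ch, "researcher",
          pack_blobs(unname(ev$output_labels), 16L), "output-labels")

  # owner: decode the received output labels and share the distance
  out_rx <- unpack_blobs(ch_recv(ch, "data_owner"))
  out_wires <- circuit$output_bits[circuit$output_bits > 0L]
  names(out_rx) <- as.character(out_wires)
  distance <- decode_output(garbled, out_rx)
  ch_send(ch, "data_owner", writeBin(as.integer(distance), raw(),
                                     size = 4, endian = "big"),
          "decoded-distance")

  structure(list(distance = distance, bit_width = circuit$meta$bit_width,
                 channel = ch,
                 audit_rows = ev$audit_rows,
                 evaluator_wires = eva_wires,
                 garbled = if (audit) garbled else NULL,
                 degenerate = FALSE),
            class = "secure_distance")
}

#' @export
print.secure_distance <- function(x, ...) {
  cat(sprintf("<secure_distance> distance = %d (bit width %d)\n",
              x$distance, x$bit_width))
  invisible(x)
}
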