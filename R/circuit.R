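# Boolean-circuit IR and the compiler that turns the banded edit-distance
# dynamic program into one circuit, so that the whole DP iteration runs
# inside a single garbled circuit and only the final distance is revealed.
#
# Representation during compilation: a "bit" is an integer — a wire id (> 0),
# the constant FALSE (0L) or the constant TRUE (-1L). Gate emitters fold
# constants, so public boundary values (D[i][0] = i, D[0][j] = j) and the
# out-of-band +infinity pattern never consume gates or wires. Multi-bit
# values are integer vectors of bits, least-significant first.
#
# Gate kinds: 1 = AND, 2 = XOR, 3 = OR, 4 = NOT (matching src/garble.cpp).

GK_AND <- 1L; GK_XOR <- 2L; GK_OR <- 3L; GK_NOT <- 4L

cb_new <- function(n_inputs) {
  env <- new.env(parent = emptyenv())
  env$nw <- as.integer(n_inputs)
  env$ng <- 0L
  cap <- 1024L
  env$kind <- integer(cap); env$in1 <- integer(cap)
  env$in2 <- integer(cap); env$out <- integer(cap)
  env
}

cb_gate <- function(cb, kind, a, b = 0L) {
  ng <- cb$ng + 1L
  if (ng > length(cb$kind)) {
    grow <- function(v) c(v, integer(length(v)))
    cb$kind <- grow(cb$kind); cb$in1 <- grow(cb$in1)
    cb$in2 <- grow(cb$in2); cb$out <- grow(cb$out)
  }
  w <- cb$nw + 1L
  cb$nw <- w; cb$ng <- ng
  cb$kind[ng] <- kind; cb$in1[ng] <- a; cb$in2[ng] <- b; cb$out[ng] <- w
  w
}

c_not <- function(cb, a) {
  if (a == 0L) return(-1L)
  if (a == -1L) return(0L)
  cb_gate(cb, GK_NOT, a)
}

c_xor <- function(cb, a, b) {
  if (a == 0L) return(b)
  if (b == 0L) return(a)
  if (a == -1L) return(c_not(cb, b))
  if (b == -1L) return(c_not(cb, a))
  if (a == b) return(0L)
  cb_gate(cb, GK_XOR, a, b)
}

c_and <- function(cb, a, b) {
  if (a == 0L || b == 0L) return(0L)
  if (a == -1L) return(b)
  if (b == -1L) return(a)
  if (a == b) return(a)
  cb_gate(cb, GK_AND, a, b)
}

c_or <- function(cb, a, b) {
  if (a == -1L || b == -1L) return(-1L)
  if (a == 0L) return(b)
  if (b == 0L) return(a)
  if (a == b) return(a)
  cb_gate(cb, GK_OR, a, b)
}

# integer constant as a bit vector (LSB first)
const_bits <- function(value, bw) {
  bits <- integer(bw)
  for (i in seq_len(bw)) {
    bits[i] <- if (value %% 2 == 1) -1L else 0L
    value <- value %/% 2
  }
  if (value != 0) stopf("constant %s does not fit in %d bits", value, bw)
  bits
}

# saturating add of a single bit c to bit-vector v: on carry-out the result
# clamps to all ones, realizing the +infinity convention in finite width
gadget_add_sat_bit <- function(cb, v, c) {
  bw <- length(v)
  s <- integer(bw)
  carry <- c
  for (i in seq_len(bw)) {
    s[i] <- c_xor(cb, v[i], carry)
    carry <- c_and(cb, v[i], carry)
  }
  vapply(s, function(bit) c_or(cb, bit, carry), integer(1))
}

# unsigned minimum of two bit-vectors: comparator chain (LSB to MSB) then mux
gadget_min <- function(cb, u, v) {
  bw <- length(u)
  lt <- 0L
  for (i in seq_len(bw)) {
    bit_lt <- c_and(cb, c_not(cb, u[i]), v[i])
    bit_eq <- c_not(cb, c_xor(cb, u[i], v[i]))
    lt <- c_or(cb, bit_lt, c_and(cb, bit_eq, lt))
  }
  # out = lt ? u : v, bitwise: v XOR (lt AND (u XOR v))
  vapply(seq_len(bw), function(i) {
    c_xor(cb, v[i], c_and(cb, lt, c_xor(cb, u[i], v[i])))
  }, integer(1))
}

# full ripple-carry adder of two bit-vectors (used by tests as an
# arithmetic reference gadget; carry-out dropped)
gadget_add <- function(cb, u, v) {
  bw <- length(u)
  s <- integer(bw)
  carry <- 0L
  for (i in seq_len(bw)) {
    axb <- c_xor(cb, u[i], v[i])
    s[i] <- c_xor(cb, axb, carry)
    carry <- c_or(cb, c_and(cb, u[i], v[i]), c_and(cb, axb, carry))
  }
  s
}

# substitution cost of one cell: 1 iff the two 2-bit nucleotide encodings
# differ
gadget_cost <- function(cb, x_bits, y_bits) {
  c_or(cb, c_xor(cb, x_bits[1], y_bits[1]), c_xor(cb, x_bits[2], y_bits[2]))
}

new_boolean_circuit <- function(cb, input_wires, output_bits, meta = list()) {
  gates <- cbind(kind = cb$kind[seq_len(cb$ng)], in1 = cb$in1[seq_len(cb$ng)],
                 in2 = cb$in2[seq_len(cb$ng)], out = cb$out[seq_len(cb$ng)])
  structure(list(n_wires = cb$nw, gates = gates, input_wires = input_wires,
                 output_bits = output_bits, meta = meta),
            class = "boolean_circuit")
}

#' @export
print.boolean_circuit <- function(x, ...) {
  cat(sprintf("<boolean_circuit> %d gate(s), %d wire(s), inputs: generator %d / evaluator %d, %d output bit(s)\n",
              nrow(x$gates), x$n_wires, length(x$input_wires$generator),
              length(x$input_wires$evaluator), length(x$output_bits)))
  invisible(x)
}

#' Compile banded edit distance to a boolean circuit
#'
#' Builds a circuit computing exactly the [banded_edit_distance()] semantics
#' for sequences of the given (public) lengths: per in-band DP cell a 2-bit
#' nucleotide equality gadget, saturating adders for the three candidate
#' moves, and two minimum gadgets; out-of-band neighbours are hardwired to
#' the all-ones constant (the finite-width stand-in for `+Inf`), and public
#' boundary values are folded as constants. Only the final DP cell is an
#' output, so an evaluation reveals nothing but the distance.
#'
#' Nucleotides are encoded in 2 bits per character (`A=00, C=01, G=10,
#' T=11`); the generator (data owner) holds the `x` input wires and the
#' evaluator (researcher) the `y` wires. Saturating arithmetic guarantees the
#' all-ones pattern cannot wrap, so `min(+Inf, v) = v` always holds.
#'
#' @param len_x,len_y sequence lengths (public protocol parameters, `>= 1`).
#' @param band a [band_spec()]; the effective half-width is
#'   `max(b, |len_x - len_y|)`.
#' @param bit_width width of the distance registers; default
#'   `ceiling(log2(max(len_x, len_y) + 1)) + 1`, one headroom bit above the
#'   largest representable distance.
#' @return A `boolean_circuit` whose `meta` records lengths, band and width.
#' @export
compile_banded_ed_circuit <- function(len_x, len_y, band, bit_width = NULL) {
  stopifnot(len_x >= 1, len_y >= 1, inherits(band, "band_spec"))
  need <- ceiling(log2(max(len_x, len_y) + 1))
  bw <- as.integer(bit_width %||% (need + 1))
  if (bw < need)
    stopf("bit_width %d cannot represent distances up to %d", bw, max(len_x, len_y))
  beff <- max(band$b, abs(len_x - len_y))

  gen_wires <- seq_len(2L * len_x)
  eva_wires <- 2L * len_x + seq_len(2L * len_y)
  cb <- cb_new(2L * (len_x + len_y))
  xbits <- lapply(seq_len(len_x), function(i) gen_wires[c(2L * i - 1L, 2L * i)])
  ybits <- lapply(seq_len(len_y), function(j) eva_wires[c(2L * j - 1L, 2L * j)])

  inf_bits <- rep(-1L, bw)
  prev <- vector("list", len_y + 1L)  # row i-1, index j+1
  cur <- vector("list", len_y + 1L)
  for (j in 0:min(len_y, beff)) prev[[j + 1L]] <- const_bits(j, bw)

  for (i in seq_len(len_x)) {
    lo <- max(0L, i - beff); hi <- min(len_y, i + beff)
    cur <- vector("list", len_y + 1L)
    if (lo == 0L) cur[[1L]] <- const_bits(i, bw)
    for (j in max(1L, lo):hi) {
      diag <- prev[[j]]                                   # always in band
      up <- if (j <= i - 1L + beff && !is.null(prev[[j + 1L]])) prev[[j + 1L]] else inf_bits
      left <- if (j - 1L >= lo && !is.null(cur[[j]])) cur[[j]] else inf_bits
      cost <- gadget_cost(cb, xbits[[i]], ybits[[j]])
      cand_sub <- gadget_add_sat_bit(cb, diag, cost)
      cand_del <- gadget_add_sat_bit(cb, up, -1L)
      cand_ins <- gadget_add_sat_bit(cb, left, -1L)
      cur[[j + 1L]] <- gadget_min(cb, gadget_min(cb, cand_sub, cand_del), cand_ins)
    }
    prev <- cur
  }
  out <- prev[[len_y + 1L]]
  if (is.null(out)) stopf("band infeasible: final cell outside band") # unreachable
  new_boolean_circuit(
    cb,
    input_wires = list(generator = gen_wires, evaluator = eva_wires),
    output_bits = out,
    meta = list(len_x = len_x, len_y = len_y, b = band$b, b_eff = beff,
                bit_width = bw))
}

# reference bw-bit adder circuit: generator holds u, evaluator holds v
cc_adder_circuit <- function(bit_width) {
  bw <- as.integer(bit_width)
  cb <- cb_new(2L * bw)
  u <- seq_len(bw); v <- bw + seq_len(bw)
  s <- gadget_add(cb, u, v)
  new_boolean_circuit(cb, list(generator = u, evaluator = v), s,
                      meta = list(bit_width = bw))
}

# 2-bit LSB-first encoding of a nucleotide string (A=00, C=01, G=10, T=11)
nucleotide_bits <- function(seq) {
  if (nchar(seq) == 0) return(integer(0))
  vals <- match(strsplit(seq, "", fixed = TRUE)[[1]], NUCLEOTIDES) - 1L
  if (anyNA(vals)) stopf("sequence contains characters outside {A,C,G,T}")
  as.integer(rbind(vals %% 2L, vals %/% 2L))
}

# plaintext evaluation of a boolean circuit: the independent reference used
# to check garbled evaluation on arbitrary circuits
eval_circuit_plain <- function(circuit, generator_bits, evaluator_bits) {
  stopifnot(inherits(circuit, "boolean_circuit"))
  vals <- logical(circuit$n_wires)
  vals[circuit$input_wires$generator] <- as.logical(generator_bits)
  vals[circuit$input_wires$evaluator] <- as.logical(evaluator_bits)
  g <- circuit$gates
  for (r in seq_len(nrow(g))) {
    a <- vals[g[r, "in1"]]
    vals[g[r, "out"]] <- switch(g[r, "kind"],
      a && vals[g[r, "in2"]],        # AND
      xor(a, vals[g[r, "in2"]]),     # XOR
      a || vals[g[r, "in2"]],        # OR
      !a)                            # NOT
  }
  bit_vals <- vapply(circuit$output_bits, function(b) {
    if (b == 0L) FALSE else if (b == -1L) TRUE else vals[b]
  }, logical(1))
  sum(2^(seq_along(bit_vals) - 1) * bit_vals)
}

#' Serialize / read a boolean circuit as text
#'
#' One gate per line: `gate_id kind in1 in2 out`, preceded by header lines
#' recording wire count, input wires and output bits.
#'
#' @param circuit a `boolean_circuit`.
#' @param path file path.
#' @return `write_circuit` returns `path` invisibly; `read_circuit` a
#'   `boolean_circuit`.
#' @export
write_circuit <- function(circuit, path) {
  stopifnot(inherits(circuit, "boolean_circuit"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("#wires %d", circuit$n_wires),
    sprintf("#generator %s", paste(circuit$input_wires$generator, collapse = " ")),
    sprintf("#evaluator %s", paste(circuit$input_wires$evaluator, collapse = " ")),
    sprintf("#outputs %s", paste(circuit$output_bits, collapse = " "))), con)
  g <- circuit$gates
  writeLines(sprintf("%d %d %d %d %d", seq_len(nrow(g)), g[, "kind"],
                     g[, "in1"], g[, "in2"], g[, "out"]), con)
  invisible(path)
}

#' @rdname write_circuit
#' @export
read_circuit <- function(path) {
  lines <- readLines(path)
  hdr <- function(tag) {
    ln <- grep(paste0("^#", tag, " ?"), lines, value = TRUE)[1]
    v <- trimws(sub(paste0("^#", tag), "", ln))
    if (nzchar(v)) as.integer(strsplit(v, " ")[[1]]) else integer(0)
  }
  body <- lines[!startsWith(lines, "#")]
  g <- if (length(body)) {
    m <- do.call(rbind, lapply(strsplit(body, " "), as.integer))
    cbind(kind = m[, 2], in1 = m[, 3], in2 = m[, 4], out = m[, 5])
  } else cbind(kind = integer(0), in1 = integer(0), in2 = integer(0),
               out = integer(0))
  structure(list(n_wires = hdr("wires"), gates = g,
                 input_wires = list(generator = hdr("generator"),
                                    evaluator = hdr("evaluator")),
                 output_bits = hdr("outputs"), meta = list()),
            class = "boolean_circuit")
}
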