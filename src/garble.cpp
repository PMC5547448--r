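#define OPENSSL_SUPPRESS_DEPRECATED
#include <Rcpp.h>
#include <openssl/sha.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Gate kind codes shared with the R circuit builder.
enum { G_AND = 1, G_XOR = 2, G_OR = 3, G_NOT = 4 };

// ---- counter-mode SHA-256 stream (seeded CSPRNG for wire labels) ----------

struct Prng {
  unsigned char key[32];
  uint64_t ctr;
  unsigned char buf[32];
  int pos; // next unread byte in buf; 32 = empty
};

static void prng_init(Prng &p, const unsigned char *key32) {
  std::memcpy(p.key, key32, 32);
  p.ctr = 0;
  p.pos = 32;
}

static void prng_refill(Prng &p) {
  unsigned char in[40];
  std::memcpy(in, p.key, 32);
  for (int i = 0; i < 8; ++i) in[32 + i] = (unsigned char)(p.ctr >> (56 - 8 * i));
  SHA256(in, 40, p.buf);
  p.ctr++;
  p.pos = 0;
}

static void prng_bytes(Prng &p, unsigned char *out, int n) {
  int got = 0;
  while (got < n) {
    if (p.pos >= 32) prng_refill(p);
    int take = std::min(n - got, 32 - p.pos);
    std::memcpy(out + got, p.buf + p.pos, take);
    p.pos += take;
    got += take;
  }
}

// Deterministic byte stream from a 32-byte key; used for all seeded
// randomness (labels, protocol secrets) so runs are reproducible.
// [[Rcpp::export(name = ".cpp_prng_bytes")]]
RawVector cpp_prng_bytes(RawVector key32, int n) {
  if (key32.size() != 32) stop("prng key must be 32 bytes");
  Prng p;
  prng_init(p, RAW(key32));
  RawVector out(n);
  prng_bytes(p, RAW(out), n);
  return out;
}

// [[Rcpp::export(name = ".cpp_sha256")]]
RawVector cpp_sha256(RawVector x) {
  RawVector out(32);
  SHA256(RAW(x), x.size(), RAW(out));
  return out;
}

// ---- garbling --------------------------------------------------------------

static inline int permute_bit(const unsigned char *label) {
  return label[15] & 1;
}

static inline int gate_truth(int kind, int a, int b) {
  switch (kind) {
    case G_AND: return a & b;
    case G_XOR: return a ^ b;
    case G_OR:  return a | b;
    case G_NOT: return 1 - a;
  }
  return 0;
}

// H(labelA || labelB || gate_id) -> 32 bytes. For NOT gates labelB is zero.
static void row_key(const unsigned char *la, const unsigned char *lb,
                    int gid, unsigned char *out) {
  unsigned char in[36];
  std::memcpy(in, la, 16);
  if (lb) std::memcpy(in + 16, lb, 16);
  else std::memset(in + 16, 0, 16);
  in[32] = (unsigned char)(gid >> 24);
  in[33] = (unsigned char)(gid >> 16);
  in[34] = (unsigned char)(gid >> 8);
  in[35] = (unsigned char)(gid);
  SHA256(in, 36, out);
}

// Garble a topologically ordered circuit. gates: columns kind, in1, in2, out
// (wire ids 1-based; in2 = 0 for NOT). Labels are 16-byte keys whose last
// bit is the point-and-permute bit; the two labels of a wire always carry
// complementary permute bits. Row ciphertext = H(la||lb||gid) XOR
// (out_label || 16 zero bytes); a 16-byte zero tag marks valid decryption.
// With free_xor, XOR gates are label arithmetic only (no table) and
// label1 = label0 XOR delta globally.
// [[Rcpp::export(name = ".cpp_gc_garble")]]
List cpp_gc_garble(IntegerMatrix gates, int n_wires, RawVector key32,
                   bool free_xor) {
  if (key32.size() != 32) stop("garbling key must be 32 bytes");
  int ng = gates.nrow();
  Prng prng;
  prng_init(prng, RAW(key32));

  std::vector<unsigned char> lab0((size_t)n_wires * 16);
  std::vector<unsigned char> lab1((size_t)n_wires * 16);
  std::vector<char> assigned(n_wires, 0);
  unsigned char delta[16];
  if (free_xor) {
    prng_bytes(prng, delta, 16);
    delta[15] |= 1; // complementary permute bits come for free
  }

  std::vector<char> is_gate_out(n_wires, 0);
  for (int g = 0; g < ng; ++g) {
    int out = gates(g, 3) - 1;
    if (out < 0 || out >= n_wires) stop("gate output wire out of range");
    is_gate_out[out] = 1;
  }

  auto fresh_labels = [&](int w) {
    unsigned char *l0 = &lab0[(size_t)w * 16], *l1 = &lab1[(size_t)w * 16];
    prng_bytes(prng, l0, 16);
    if (free_xor) {
      for (int i = 0; i < 16; ++i) l1[i] = l0[i] ^ delta[i];
    } else {
      prng_bytes(prng, l1, 16);
      l1[15] = (unsigned char)((l1[15] & 0xFE) | (1 - permute_bit(l0)));
    }
    assigned[w] = 1;
  };

  // input wires (anything that is not a gate output) get labels first,
  // in wire-id order, so the stream is reproducible
  for (int w = 0; w < n_wires; ++w)
    if (!is_gate_out[w]) fresh_labels(w);

  // row bookkeeping
  IntegerVector offsets(ng), nrows(ng);
  int total_rows = 0;
  for (int g = 0; g < ng; ++g) {
    int kind = gates(g, 0);
    int nr = (kind == G_XOR && free_xor) ? 0 : (kind == G_NOT ? 2 : 4);
    offsets[g] = total_rows;
    nrows[g] = nr;
    total_rows += nr;
  }
  RawVector tables((size_t)total_rows * 32);
  unsigned char *tab = RAW(tables);

  for (int g = 0; g < ng; ++g) {
    int kind = gates(g, 0);
    int a = gates(g, 1) - 1, b = gates(g, 2) - 1, out = gates(g, 3) - 1;
    if (a < 0 || !assigned[a]) stop("circuit not topologically ordered");
    if (kind != G_NOT && (b < 0 || !assigned[b]))
      stop("circuit not topologically ordered");

    if (kind == G_XOR && free_xor) {
      unsigned char *o0 = &lab0[(size_t)out * 16], *o1 = &lab1[(size_t)out * 16];
      for (int i = 0; i < 16; ++i) {
        o0[i] = lab0[(size_t)a * 16 + i] ^ lab0[(size_t)b * 16 + i];
        o1[i] = o0[i] ^ delta[i];
      }
      assigned[out] = 1;
      continue;
    }
    fresh_labels(out);

    unsigned char *base = tab + (size_t)offsets[g] * 32;
    if (kind == G_NOT) {
      for (int va = 0; va <= 1; ++va) {
        const unsigned char *la = (va ? &lab1[(size_t)a * 16] : &lab0[(size_t)a * 16]);
        int idx = permute_bit(la);
        int vout = gate_truth(kind, va, 0);
        const unsigned char *lo = (vout ? &lab1[(size_t)out * 16] : &lab0[(size_t)out * 16]);
        unsigned char h[32];
        row_key(la, NULL, g, h);
        unsigned char *ct = base + (size_t)idx * 32;
        for (int i = 0; i < 16; ++i) ct[i] = h[i] ^ lo[i];
        for (int i = 16; i < 32; ++i) ct[i] = h[i]; // XOR with zero tag
      }
    } else {
      for (int va = 0; va <= 1; ++va) {
        for (int vb = 0; vb <= 1; ++vb) {
          const unsigned char *la = (va ? &lab1[(size_t)a * 16] : &lab0[(size_t)a * 16]);
          const unsigned char *lb = (vb ? &lab1[(size_t)b * 16] : &lab0[(size_t)b * 16]);
          int idx = (permute_bit(la) << 1) | permute_bit(lb);
          int vout = gate_truth(kind, va, vb);
          const unsigned char *lo = (vout ? &lab1[(size_t)out * 16] : &lab0[(size_t)out * 16]);
          unsigned char h[32];
          row_key(la, lb, g, h);
          unsigned char *ct = base + (size_t)idx * 32;
          for (int i = 0; i < 16; ++i) ct[i] = h[i] ^ lo[i];
          for (int i = 16; i < 32; ++i) ct[i] = h[i];
        }
      }
    }
  }

  RawVector r0((size_t)n_wires * 16), r1((size_t)n_wires * 16);
  std::memcpy(RAW(r0), lab0.data(), lab0.size());
  std::memcpy(RAW(r1), lab1.data(), lab1.size());
  return List::create(_["label0"] = r0, _["label1"] = r1,
                      _["tables"] = tables, _["offsets"] = offsets,
                      _["nrows"] = nrows);
}

// Evaluate a garbled circuit given one active label per input wire.
// active: n_wires*16 raw, input positions filled; has: which wires hold a
// label. Returns active labels for every wire plus, when audit = TRUE, the
// number of table rows that decrypt with a valid tag per gate (-1 for
// free-XOR gates, which have no table).
// [[Rcpp::export(name = ".cpp_gc_evaluate")]]
List cpp_gc_evaluate(IntegerMatrix gates, int n_wires, RawVector tables,
                     IntegerVector offsets, IntegerVector nrows,
                     RawVector active, LogicalVector has, bool free_xor,
                     bool audit) {
  int ng = gates.nrow();
  if ((int)active.size() != n_wires * 16) stop("active label buffer size mismatch");
  std::vector<unsigned char> act(RAW(active), RAW(active) + active.size());
  std::vector<char> have(n_wires, 0);
  for (int w = 0; w < n_wires; ++w) have[w] = has[w] ? 1 : 0;
  const unsigned char *tab = RAW(tables);
  IntegerVector audit_counts(audit ? ng : 0);

  for (int g = 0; g < ng; ++g) {
    int kind = gates(g, 0);
    int a = gates(g, 1) - 1, b = gates(g, 2) - 1, out = gates(g, 3) - 1;
    if (!have[a] || (kind != G_NOT && !have[b]))
      stop("evaluator missing a label for gate %d", g + 1);
    unsigned char *la = &act[(size_t)a * 16];
    unsigned char *lb = (kind == G_NOT) ? NULL : &act[(size_t)b * 16];

    if (kind == G_XOR && free_xor) {
      for (int i = 0; i < 16; ++i)
        act[(size_t)out * 16 + i] = la[i] ^ lb[i];
      have[out] = 1;
      if (audit) audit_counts[g] = -1;
      continue;
    }
    unsigned char h[32];
    row_key(la, lb, g, h);
    int idx = (kind == G_NOT) ? permute_bit(la)
                              : ((permute_bit(la) << 1) | permute_bit(lb));
    const unsigned char *ct = tab + ((size_t)offsets[g] + idx) * 32;
    bool ok = true;
    for (int i = 16; i < 32; ++i) if ((ct[i] ^ h[i]) != 0) { ok = false; break; }
    if (!ok) stop("integrity error: no row decrypts validly at gate %d", g + 1);
    for (int i = 0; i < 16; ++i) act[(size_t)out * 16 + i] = ct[i] ^ h[i];
    have[out] = 1;

    if (audit) {
      int nvalid = 0;
      for (int r = 0; r < nrows[g]; ++r) {
        const unsigned char *cr = tab + ((size_t)offsets[g] + r) * 32;
        bool valid = true;
        for (int i = 16; i < 32; ++i) if ((cr[i] ^ h[i]) != 0) { valid = false; break; }
        if (valid) nvalid++;
      }
      audit_counts[g] = nvalid;
    }
  }

  RawVector out_act((size_t)n_wires * 16);
  std::memcpy(RAW(out_act), act.data(), act.size());
  LogicalVector out_have(n_wires);
  for (int w = 0; w < n_wires; ++w) out_have[w] = have[w] != 0;
  return List::create(_["active"] = out_act, _["have"] = out_have,
                      _["audit"] = audit_counts);
}
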