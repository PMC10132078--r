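#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes: A=00, C=01, G=10, T=11; 4 codes per byte, little-endian
// within the byte (code i occupies bits (i%4)*2 .. (i%4)*2+1).

static inline int base_code(char b) {
  switch (b) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static inline int get_code(const uint8_t *p, int i) {
  return (p[i >> 2] >> ((i & 3) << 1)) & 3;
}

static inline void set_code(uint8_t *p, int i, int code) {
  int shift = (i & 3) << 1;
  p[i >> 2] = (uint8_t)((p[i >> 2] & ~(3 << shift)) | (code << shift));
}

// Build the packed concatenated store: reads separated by spacer_len
// pseudo-random codes (supplied by the caller so seeding stays in R).
// [[Rcpp::export]]
List cpp_build_store(CharacterVector seqs, IntegerVector spacer_codes,
                     int spacer_len) {
  int n = seqs.size();
  std::vector<int> lens(n);
  long long total = 0;
  for (int i = 0; i < n; ++i) {
    lens[i] = LENGTH(STRING_ELT(seqs, i));
    total += lens[i];
  }
  if (n > 1) total += (long long)spacer_len * (n - 1);
  if (total > INT_MAX)
    stop("read pool too large for a single 2-bit store");
  int total_codes = (int)total;
  if (n > 1 && spacer_codes.size() < spacer_len * (n - 1))
    stop("not enough spacer codes supplied");

  RawVector packed((total_codes + 3) / 4);
  uint8_t *p = (uint8_t *)RAW(packed);
  IntegerVector starts(n), ends(n);
  int off = 0, sp = 0;
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      for (int j = 0; j < spacer_len; ++j)
        set_code(p, off++, spacer_codes[sp++] & 3);
    }
    starts[i] = off;
    const char *s = CHAR(STRING_ELT(seqs, i));
    for (int j = 0; j < lens[i]; ++j) {
      int c = base_code(s[j]);
      if (c < 0) stop("non-ACGT base in read %d (reads must be pre-filtered)", i + 1);
      set_code(p, off++, c);
    }
    ends[i] = off;
  }
  return List::create(_["packed"] = packed, _["start_offset"] = starts,
                      _["end_offset"] = ends, _["total_codes"] = total_codes);
}

// [[Rcpp::export]]
CharacterVector cpp_decode_span(RawVector packed, IntegerVector start,
                                IntegerVector end, int total_codes) {
  static const char bases[] = "ACGT";
  const uint8_t *p = (const uint8_t *)RAW(packed);
  int n = start.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (start[i] < 0 || end[i] > total_codes || start[i] > end[i])
      stop("span out of range");
    std::string s(end[i] - start[i], ' ');
    for (int j = start[i]; j < end[i]; ++j) s[j - start[i]] = bases[get_code(p, j)];
    out[i] = s;
  }
  return out;
}

struct Ext {
  int left, right;
};

// Maximal extension of an equal k-block at global offsets (oa, ob), bounded to
// stay within [lo, hi) on each side. Interval-halving: try the full remaining
// extension, halve on mismatch until a matching block is found, then elongate
// one code at a time.
static Ext extend_block(const uint8_t *p, int oa, int ob, int k, int lo_a,
                        int hi_a, int lo_b, int hi_b) {
  Ext e;
  // left
  int max_left = std::min(oa - lo_a, ob - lo_b);
  int left = 0, E = max_left;
  while (E > 0) {
    bool ok = true;
    for (int t = 1; t <= E; ++t) {
      if (get_code(p, oa - t) != get_code(p, ob - t)) { ok = false; break; }
    }
    if (ok) { left = E; break; }
    E /= 2;
  }
  while (left < max_left &&
         get_code(p, oa - left - 1) == get_code(p, ob - left - 1))
    ++left;
  // right
  int max_right = std::min(hi_a - (oa + k), hi_b - (ob + k));
  int right = 0;
  E = max_right;
  while (E > 0) {
    bool ok = true;
    for (int t = 0; t < E; ++t) {
      if (get_code(p, oa + k + t) != get_code(p, ob + k + t)) { ok = false; break; }
    }
    if (ok) { right = E; break; }
    E /= 2;
  }
  while (right < max_right &&
         get_code(p, oa + k + right) == get_code(p, ob + k + right))
    ++right;
  e.left = left;
  e.right = right;
  return e;
}

// [[Rcpp::export]]
IntegerVector cpp_extend_seed(RawVector packed, IntegerVector start_offset,
                              IntegerVector end_offset, int read_a, int pos_a,
                              int read_b, int pos_b, int k) {
  const uint8_t *p = (const uint8_t *)RAW(packed);
  int ia = read_a - 1, ib = read_b - 1;
  if (ia < 0 || ia >= start_offset.size() || ib < 0 || ib >= start_offset.size())
    stop("read ordinal out of range");
  int oa = start_offset[ia] + pos_a, ob = start_offset[ib] + pos_b;
  if (oa + k > end_offset[ia] || ob + k > end_offset[ib] || pos_a < 0 || pos_b < 0)
    stop("seed window out of range");
  for (int t = 0; t < k; ++t)
    if (get_code(p, oa + t) != get_code(p, ob + t))
      stop("seed k-mers are not equal");
  if (read_a == read_b && pos_a == pos_b) stop("seed is a self-hit");
  Ext e = extend_block(p, oa, ob, k, start_offset[ia], end_offset[ia],
                       start_offset[ib], end_offset[ib]);
  return IntegerVector::create(_["start_a"] = pos_a - e.left,
                               _["start_b"] = pos_b - e.left,
                               _["length"] = k + e.left + e.right);
}

// Sparse-indexed scan: index k-mers at within-read positions that are
// multiples of stride, scan every query window, extend seeds, keep the first
// MEM per query read passing the [min_len, max_len] window and the end-buffer
// rule on both reads.
// [[Rcpp::export]]
DataFrame cpp_find_repeat_reads(RawVector packed, IntegerVector start_offset,
                                IntegerVector end_offset, int k, int stride,
                                int min_len, int max_len, int buffer) {
  const uint8_t *p = (const uint8_t *)RAW(packed);
  int n = start_offset.size();
  if (k < 1 || k > 31) stop("k must be in 1..31");
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  // reference hash table over sparse-sampled k-mers
  std::unordered_map<uint64_t, std::vector<int64_t>> index;
  index.reserve(1 << 20);
  for (int r = 0; r < n; ++r) {
    int len = end_offset[r] - start_offset[r];
    if (len < k) continue;
    uint64_t km = 0;
    // rolling k-mer over the read; record positions p with p % stride == 0
    for (int pos = 0; pos < len; ++pos) {
      km = ((km << 2) | get_code(p, start_offset[r] + pos)) & mask;
      int st = pos - k + 1;
      if (st >= 0 && st % stride == 0) {
        int64_t packed_pos = ((int64_t)r << 32) | (uint32_t)st;
        index[km].push_back(packed_pos);
      }
    }
  }

  std::vector<int> out_a, out_sa, out_b, out_sb, out_len;
  for (int a = 0; a < n; ++a) {
    int len_a = end_offset[a] - start_offset[a];
    if (len_a < k) continue;
    uint64_t km = 0;
    bool done = false;
    for (int pos = 0; pos < len_a && !done; ++pos) {
      km = ((km << 2) | get_code(p, start_offset[a] + pos)) & mask;
      int q = pos - k + 1;
      if (q < 0) continue;
      auto it = index.find(km);
      if (it == index.end()) continue;
      for (int64_t hit : it->second) {
        int b = (int)(hit >> 32);
        int pb = (int)(hit & 0xffffffff);
        if (b == a && pb == q) continue; // self-hit
        Ext e = extend_block(p, start_offset[a] + q, start_offset[b] + pb, k,
                             start_offset[a], end_offset[a], start_offset[b],
                             end_offset[b]);
        int mlen = k + e.left + e.right;
        if (mlen < min_len || mlen > max_len) continue;
        int sa = q - e.left, sb = pb - e.left;
        int len_b = end_offset[b] - start_offset[b];
        if (sa < buffer || sa + mlen > len_a - buffer) continue;
        if (sb < buffer || sb + mlen > len_b - buffer) continue;
        out_a.push_back(a + 1);
        out_sa.push_back(sa);
        out_b.push_back(b + 1);
        out_sb.push_back(sb);
        out_len.push_back(mlen);
        done = true; // one repeat per query read
        break;
      }
    }
  }
  return DataFrame::create(_["read_a"] = out_a, _["start_a"] = out_sa,
                           _["read_b"] = out_b, _["start_b"] = out_sb,
                           _["length"] = out_len);
}

// Indexed sparse k-mer start positions, for inspection and the sampling-
// guarantee check (read-major, position-ascending order).
// [[Rcpp::export]]
DataFrame cpp_index_positions(IntegerVector start_offset,
                              IntegerVector end_offset, int k, int stride) {
  std::vector<int> reads, poss, offs;
  for (int r = 0; r < start_offset.size(); ++r) {
    int len = end_offset[r] - start_offset[r];
    for (int pos = 0; pos + k <= len; pos += stride) {
      reads.push_back(r + 1);
      poss.push_back(pos);
      offs.push_back(start_offset[r] + pos);
    }
  }
  return DataFrame::create(_["read_ordinal"] = reads, _["position"] = poss,
                           _["offset"] = offs);
}
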