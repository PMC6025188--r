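#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Ungapped placement scanner for one tag against one canonical context
// string (upstream_flank + body + downstream_flank). Coordinates follow the
// package convention: offset5 = tag 5' start minus canonical 5' start in
// piRNA orientation (negative = tag extends 5' of the body), offset3 = tag
// 3' end minus canonical 3' end (positive = tag extends 3').
//
// A placement is valid iff the body overlap is >= min_overlap, the number
// of body mismatches is <= max_mm, and any body mismatch is internal (not
// the first or last tag position). 'N' never matches. Extension
// nucleotides beyond the stored flank are non-templated by definition.

struct Plc {
  int off5, off3, body_matches, mmpos, t5, t3;
};

static void scan_one(const std::string &tag, const std::string &ctx,
                     int ulen, int blen, int min_ov, int max_mm,
                     std::vector<Plc> &out) {
  const int L = (int)tag.size();
  const int C = (int)ctx.size();
  const int lo = min_ov - L, hi = blen - min_ov;
  for (int o5 = lo; o5 <= hi; ++o5) {
    const int o3 = o5 + L - blen;
    // tag indices aligned within the canonical body
    const int i0 = std::max(0, -o5);
    const int i1 = std::min(L - 1, blen - 1 - o5);
    const int ov = i1 - i0 + 1;
    if (ov < min_ov) continue;
    int mm = 0, mmpos = NA_INTEGER;
    bool ok = true;
    for (int i = i0; i <= i1; ++i) {
      const char a = tag[i], b = ctx[ulen + o5 + i];
      if (a != b || a == 'N' || b == 'N') {
        ++mm;
        if (mm > max_mm || i == 0 || i == L - 1) { ok = false; break; }
        mmpos = i + 1;  // 1-based tag position
      }
    }
    if (!ok) continue;
    // templated run on the 5' extension, contiguous outward from the body
    const int e5 = o5 < 0 ? -o5 : 0;
    int t5 = 0;
    for (int i = e5 - 1; i >= 0; --i) {
      const int p = ulen + o5 + i;
      if (p < 0) break;  // beyond stored flank
      const char a = tag[i], b = ctx[p];
      if (a == b && a != 'N' && b != 'N') ++t5; else break;
    }
    // templated run on the 3' extension
    const int e3 = o3 > 0 ? o3 : 0;
    int t3 = 0;
    for (int i = L - e3; i < L; ++i) {
      const int p = ulen + o5 + i;
      if (p >= C) break;
      const char a = tag[i], b = ctx[p];
      if (a == b && a != 'N' && b != 'N') ++t3; else break;
    }
    Plc pl;
    pl.off5 = o5; pl.off3 = o3; pl.body_matches = ov - mm;
    pl.mmpos = mm > 0 ? mmpos : NA_INTEGER; pl.t5 = t5; pl.t3 = t3;
    out.push_back(pl);
  }
}

static DataFrame plc_frame(const std::vector<Plc> &v,
                           const std::vector<int> *canon = nullptr) {
  const int n = (int)v.size();
  IntegerVector o5(n), o3(n), bm(n), mp(n), t5(n), t3(n), ci(n);
  for (int j = 0; j < n; ++j) {
    o5[j] = v[j].off5; o3[j] = v[j].off3; bm[j] = v[j].body_matches;
    mp[j] = v[j].mmpos; t5[j] = v[j].t5; t3[j] = v[j].t3;
    if (canon) ci[j] = (*canon)[j];
  }
  if (canon)
    return DataFrame::create(_["canonical_idx"] = ci, _["offset5"] = o5,
                             _["offset3"] = o3, _["body_matches"] = bm,
                             _["body_mismatch_pos"] = mp,
                             _["templated5"] = t5, _["templated3"] = t3);
  return DataFrame::create(_["offset5"] = o5, _["offset3"] = o3,
                           _["body_matches"] = bm,
                           _["body_mismatch_pos"] = mp,
                           _["templated5"] = t5, _["templated3"] = t3);
}

// [[Rcpp::export]]
DataFrame scan_placements_cpp(std::string tag, std::string context,
                              int ulen, int blen, int min_overlap,
                              int max_mismatch) {
  std::vector<Plc> out;
  scan_one(tag, context, ulen, blen, min_overlap, max_mismatch, out);
  return plc_frame(out);
}

// All valid placements of one tag against a registry of canonical contexts.
// canonical_idx in the result is the 1-based index into `contexts`.
// [[Rcpp::export]]
DataFrame scan_registry_cpp(std::string tag, CharacterVector contexts,
                            IntegerVector ulens, IntegerVector blens,
                            int min_overlap, int max_mismatch) {
  std::vector<Plc> out;
  std::vector<int> canon;
  const int nc = contexts.size();
  for (int c = 0; c < nc; ++c) {
    std::vector<Plc> one;
    std::string ctx = as<std::string>(contexts[c]);
    scan_one(tag, ctx, ulens[c], blens[c], min_overlap, max_mismatch, one);
    for (size_t j = 0; j < one.size(); ++j) {
      out.push_back(one[j]);
      canon.push_back(c + 1);
    }
  }
  return plc_frame(out, &canon);
}
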