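#include <Rcpp.h>
using namespace Rcpp;

// Leftmost window of each sequence whose Hamming distance to `pattern` is
// <= max_mm[i] (max_mm recycled if length 1). Substitution-only: no indels.
// Returns a 2-column integer matrix: [ , 1] 1-based offset (NA if no window
// qualifies), [ , 2] mismatch count of that window (NA likewise).
// [[Rcpp::export]]
IntegerMatrix cpp_hamming_search(CharacterVector seqs, std::string pattern,
                                 IntegerVector max_mm) {
  const int n = seqs.size();
  const int plen = pattern.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(seqs[i])) {
      out(i, 0) = NA_INTEGER; out(i, 1) = NA_INTEGER; continue;
    }
    const char *s = CHAR(STRING_ELT(seqs, i));
    const int slen = LENGTH(STRING_ELT(seqs, i));
    const int cap = max_mm.size() == 1 ? max_mm[0] : max_mm[i];
    int best_off = NA_INTEGER, best_mm = NA_INTEGER;
    if (cap >= 0) {
      for (int off = 0; off + plen <= slen; ++off) {
        int mm = 0;
        for (int j = 0; j < plen; ++j) {
          if (s[off + j] != pattern[j] && ++mm > cap) break;
        }
        if (mm <= cap) { best_off = off + 1; best_mm = mm; break; }
      }
    }
    out(i, 0) = best_off;
    out(i, 1) = best_mm;
  }
  return out;
}

// Elementwise Hamming distance between two vectors of equal-length strings.
// [[Rcpp::export]]
IntegerVector cpp_hamming_pairs(CharacterVector x, CharacterVector y) {
  const int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i]) || CharacterVector::is_na(y[i])) {
      out[i] = NA_INTEGER; continue;
    }
    const char *a = CHAR(STRING_ELT(x, i));
    const char *b = CHAR(STRING_ELT(y, i));
    const int la = LENGTH(STRING_ELT(x, i));
    if (la != LENGTH(STRING_ELT(y, i))) stop("strings must have equal length");
    int mm = 0;
    for (int j = 0; j < la; ++j) if (a[j] != b[j]) ++mm;
    out[i] = mm;
  }
  return out;
}

// Mismatches of seqs[i] against ref starting at 1-based starts[i], capped at
// cap + 1 (early exit). NA when the window falls outside ref.
// [[Rcpp::export]]
IntegerVector cpp_mismatch_at(CharacterVector seqs, std::string ref,
                              IntegerVector starts, int cap) {
  const int n = seqs.size();
  const int rlen = ref.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(seqs[i]) || starts[i] == NA_INTEGER) {
      out[i] = NA_INTEGER; continue;
    }
    const char *s = CHAR(STRING_ELT(seqs, i));
    const int slen = LENGTH(STRING_ELT(seqs, i));
    const int st = starts[i] - 1;
    if (st < 0 || st + slen > rlen) { out[i] = NA_INTEGER; continue; }
    int mm = 0;
    for (int j = 0; j < slen; ++j) {
      if (s[j] != ref[st + j] && ++mm > cap) break;
    }
    out[i] = mm;
  }
  return out;
}

// Greedy abundance-ranked clustering. `barcodes` must already be sorted by
// descending count with lexicographic tie-break; each barcode joins the
// first existing cluster whose *center* is within Hamming distance d, else
// founds a new cluster. Returns the 1-based index (into `barcodes`) of the
// assigned cluster center for every barcode.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector barcodes, int d) {
  const int n = barcodes.size();
  IntegerVector out(n);
  std::vector<int> centers;
  centers.reserve(64);
  for (int i = 0; i < n; ++i) {
    const char *b = CHAR(STRING_ELT(barcodes, i));
    const int blen = LENGTH(STRING_ELT(barcodes, i));
    int assigned = 0;
    for (size_t c = 0; c < centers.size(); ++c) {
      const char *ctr = CHAR(STRING_ELT(barcodes, centers[c] - 1));
      if (LENGTH(STRING_ELT(barcodes, centers[c] - 1)) != blen)
        stop("barcodes must all have the same length");
      int mm = 0;
      for (int j = 0; j < blen; ++j) {
        if (b[j] != ctr[j] && ++mm > d) break;
      }
      if (mm <= d) { assigned = centers[c]; break; }
    }
    if (assigned == 0) {
      centers.push_back(i + 1);
      assigned = i + 1;
    }
    out[i] = assigned;
  }
  return out;
}
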