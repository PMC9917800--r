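#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman local alignment of a read against one
// reference segment.  A gap of length L costs gap_open + L * gap_extend
// (both passed as positive penalties), i.e. opening move costs
// gap_open + gap_extend for the first gapped base.
//
// Tie-breaking is fully deterministic:
//   * the best cell is the first maximum in row-major scan order
//     (smallest read end, then smallest segment end);
//   * traceback prefers diagonal over a gap in the segment (read
//     consumed) over a gap in the read (segment consumed).
//
// Returns 0-based half-open coordinates plus `seg_map`: for each
// segment position in [seg_start, seg_end), the 0-based read position
// it aligns to, or NA when the segment base aligns to a gap.  This map
// is what projects IMGT anchor codons from the reference onto the read.

// Score-only pass over many segments with O(m) memory; used to find the
// best candidate before a single full traceback.
// [[Rcpp::export(name = ".sw_scores_cpp")]]
IntegerVector sw_scores_cpp(std::string read, CharacterVector segs,
                            int match, int mismatch,
                            int gap_open, int gap_extend) {
  const int n = (int) read.size();
  const int NEG = -1000000000;
  const int open_cost = gap_open + gap_extend;
  IntegerVector out(segs.size());
  std::vector<int> Hprev, Hcur, Eprev;
  for (int s = 0; s < segs.size(); ++s) {
    std::string seg = as<std::string>(segs[s]);
    const int m = (int) seg.size();
    Hprev.assign(m + 1, 0);
    Hcur.assign(m + 1, 0);
    Eprev.assign(m + 1, NEG);
    std::vector<int> Fcol(m + 1, NEG);
    int best = 0;
    const char *segp = seg.c_str();
    for (int i = 1; i <= n; ++i) {
      const char ri = read[(size_t)i - 1];
      int e = NEG, h_left = 0;
      int *hp = Hprev.data(), *hc = Hcur.data(), *fc = Fcol.data();
      for (int j = 1; j <= m; ++j) {
        int ecand = h_left - open_cost;
        e = e - gap_extend;
        if (ecand > e) e = ecand;
        int f = fc[j] - gap_extend;
        int fcand = hp[j] - open_cost;
        if (fcand > f) f = fcand;
        fc[j] = f;
        int h = hp[j - 1] + ((ri == segp[j - 1]) ? match : mismatch);
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0) h = 0;
        hc[j] = h;
        h_left = h;
        if (h > best) best = h;
      }
      std::swap(Hprev, Hcur);
    }
    out[s] = best;
  }
  return out;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string read, std::string seg,
                  int match, int mismatch,
                  int gap_open, int gap_extend) {
  const int n = (int) read.size();   // rows: read
  const int m = (int) seg.size();    // cols: segment
  const int NEG = -1000000000;
  const int open_cost = gap_open + gap_extend;

  // (n+1) x (m+1) matrices, row-major
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> E((size_t)(n + 1) * (m + 1), NEG);  // gap in read (seg consumed)
  std::vector<int> F((size_t)(n + 1) * (m + 1), NEG);  // gap in seg (read consumed)

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char ri = read[(size_t)i - 1];
    size_t row = (size_t)i * (m + 1), prow = (size_t)(i - 1) * (m + 1);
    for (int j = 1; j <= m; ++j) {
      const int s = (ri == seg[(size_t)j - 1]) ? match : mismatch;
      int e = std::max(H[row + j - 1] - open_cost, E[row + j - 1] - gap_extend);
      int f = std::max(H[prow + j] - open_cost, F[prow + j] - gap_extend);
      int h = H[prow + j - 1] + s;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E[row + j] = e;
      F[row + j] = f;
      H[row + j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0) {
    return List::create(_["score"] = 0, _["read_start"] = NA_INTEGER,
                        _["read_end"] = NA_INTEGER, _["seg_start"] = NA_INTEGER,
                        _["seg_end"] = NA_INTEGER, _["n_match"] = 0,
                        _["aln_len"] = 0, _["seg_map"] = IntegerVector(0));
  }

  // traceback from (bi, bj); state 0 = H, 1 = E, 2 = F
  int i = bi, j = bj, state = 0, n_match = 0, aln_len = 0;
  std::vector<int> seg_pos, read_pos;  // aligned columns, reverse order
  while (true) {
    size_t row = (size_t)i * (m + 1), prow = (size_t)(i - 1) * (m + 1);
    if (state == 0) {
      if (H[row + j] == 0) break;
      const int s = (read[(size_t)i - 1] == seg[(size_t)j - 1]) ? match : mismatch;
      if (i > 0 && j > 0 && H[row + j] == H[prow + j - 1] + s) {
        if (s == match) ++n_match;
        seg_pos.push_back(j - 1); read_pos.push_back(i - 1);
        ++aln_len; --i; --j;
      } else if (H[row + j] == F[row + j]) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 2) {  // gap in segment: consume read base
      seg_pos.push_back(NA_INTEGER); read_pos.push_back(i - 1);
      ++aln_len;
      bool from_h = (F[row + j] == H[prow + j] - open_cost);
      --i;
      if (from_h) state = 0;
    } else {  // state == 1, gap in read: consume segment base
      seg_pos.push_back(j - 1); read_pos.push_back(NA_INTEGER);
      ++aln_len;
      bool from_h = (E[row + j] == H[row + j - 1] - open_cost);
      --j;
      if (from_h) state = 0;
    }
  }

  const int read_start = i, read_end = bi;  // half-open on the read
  // smallest / largest segment positions actually touched
  int seg_start = m, seg_end = 0;
  for (size_t k = 0; k < seg_pos.size(); ++k) {
    if (seg_pos[k] == NA_INTEGER) continue;
    if (seg_pos[k] < seg_start) seg_start = seg_pos[k];
    if (seg_pos[k] + 1 > seg_end) seg_end = seg_pos[k] + 1;
  }

  IntegerVector seg_map(seg_end - seg_start, NA_INTEGER);
  for (size_t k = 0; k < seg_pos.size(); ++k) {
    if (seg_pos[k] == NA_INTEGER) continue;
    int rp = read_pos[k];
    seg_map[seg_pos[k] - seg_start] = (rp == NA_INTEGER) ? NA_INTEGER : rp;
  }

  return List::create(_["score"] = best,
                      _["read_start"] = read_start, _["read_end"] = read_end,
                      _["seg_start"] = seg_start, _["seg_end"] = seg_end,
                      _["n_match"] = n_match, _["aln_len"] = aln_len,
                      _["seg_map"] = seg_map);
}
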