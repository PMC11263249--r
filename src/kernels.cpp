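#include <Rcpp.h>
using namespace Rcpp;

// Global pairwise alignment with affine gap penalties (Gotoh). A gap of
// length k costs gap_open + k * gap_ext. Intended for gene-scale sequences;
// guarded against quadratic blow-up on whole genomes.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_ext) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("empty sequence in alignment");
  const double INF = 1e18;
  if ((double)(m + 1) * (double)(n + 1) > 2.6e7)
    stop("sequences too long for global alignment (limit ~5 kb x 5 kb)");

  std::vector<double> M((m + 1) * (n + 1), -INF);
  std::vector<double> X((m + 1) * (n + 1), -INF); // gap in b (consume a)
  std::vector<double> Y((m + 1) * (n + 1), -INF); // gap in a (consume b)
  std::vector<unsigned char> tb((m + 1) * (n + 1), 0); // 2 bits per matrix
  const int w = n + 1;

  M[0] = 0.0;
  for (int i = 1; i <= m; ++i) X[i * w] = gap_open + i * gap_ext;
  for (int j = 1; j <= n; ++j) Y[j] = gap_open + j * gap_ext;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int ij = i * w + j;
      // X: gap in b
      double xo = std::max(M[(i - 1) * w + j], Y[(i - 1) * w + j]) + gap_open + gap_ext;
      double xe = X[(i - 1) * w + j] + gap_ext;
      unsigned char xdir;
      if (xe >= xo) { X[ij] = xe; xdir = 1; } else { X[ij] = xo; xdir = 0; }
      // Y: gap in a
      double yo = std::max(M[i * w + j - 1], X[i * w + j - 1]) + gap_open + gap_ext;
      double ye = Y[i * w + j - 1] + gap_ext;
      unsigned char ydir;
      if (ye >= yo) { Y[ij] = ye; ydir = 1; } else { Y[ij] = yo; ydir = 0; }
      // M: (mis)match
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double md = M[(i - 1) * w + j - 1], xd = X[(i - 1) * w + j - 1],
             yd = Y[(i - 1) * w + j - 1];
      double best = md; unsigned char mdir = 0;
      if (xd > best) { best = xd; mdir = 1; }
      if (yd > best) { best = yd; mdir = 2; }
      M[ij] = best + s;
      tb[ij] = (unsigned char)(mdir | (xdir << 2) | (ydir << 3));
    }
  }

  const int end = m * w + n;
  int state; // 0 = M, 1 = X, 2 = Y
  double score = M[end]; state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::string ra, rb;
  ra.reserve(m + n); rb.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (i == 0) { ra.push_back('-'); rb.push_back(b[--j]); continue; }
    if (j == 0) { ra.push_back(a[--i]); rb.push_back('-'); continue; }
    const unsigned char t = tb[i * w + j];
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = t & 3; --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      unsigned char ext = (t >> 2) & 1;
      --i;
      if (!ext) {
        // reopened from M or Y: decide by score at the new cell
        state = (M[i * w + j] >= Y[i * w + j]) ? 0 : 2;
      }
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      unsigned char ext = (t >> 3) & 1;
      --j;
      if (!ext) state = (M[i * w + j] >= X[i * w + j]) ? 0 : 1;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score);
}

// Tandem-repeat candidate scan: for each period p, positions i with
// s[i] == s[i+p] form runs; a tandem array of unit length p and total
// length L yields a run of ~L-p matches. Runs tolerate short mismatch
// stretches; candidates are verified against a tiled consensus in R.
// Returns 1-based inclusive loci: columns start, end, period, n_match, run_len.
// [[Rcpp::export]]
List tandem_scan_cpp(std::string s, int max_period, int min_copies,
                     double min_frac) {
  const int n = s.size();
  std::vector<int> st, en, pd;
  std::vector<double> mpct;
  std::vector<std::string> cons_v;
  const char *bases = "ACGTN";
  for (int p = 1; p <= max_period && p < n; ++p) {
    const int tol = std::max(1, p / 10); // max consecutive mismatches inside a run
    int i = 0;
    const int lim = n - p;
    while (i < lim) {
      if (s[i] != s[i + p]) { ++i; continue; }
      // start of a candidate run
      int start = i, matches = 0, miss_run = 0, last_match = i;
      int j = i;
      while (j < lim) {
        if (s[j] == s[j + p]) { ++matches; miss_run = 0; last_match = j; }
        else { ++miss_run; if (miss_run > tol) break; }
        ++j;
      }
      int run_len = last_match - start + 1;
      if (run_len >= p * (min_copies - 1) &&
          (double)matches / (double)run_len >= min_frac) {
        const int lstart = start, lend = last_match + p; // 0-based inclusive
        const int llen = lend - lstart + 1;
        // majority-vote consensus of the tiled units
        std::vector<int> cnt(5 * p, 0);
        for (int q = lstart; q <= lend; ++q) {
          int col = (q - lstart) % p, bi = 4;
          switch (s[q]) {
            case 'A': bi = 0; break; case 'C': bi = 1; break;
            case 'G': bi = 2; break; case 'T': bi = 3; break;
          }
          ++cnt[col * 5 + bi];
        }
        std::string cons(p, 'N');
        for (int col = 0; col < p; ++col) {
          int best = 0;
          for (int bi = 1; bi < 5; ++bi)
            if (cnt[col * 5 + bi] > cnt[col * 5 + best]) best = bi;
          cons[col] = bases[best];
        }
        int cmatch = 0;
        for (int q = lstart; q <= lend; ++q)
          if (s[q] == cons[(q - lstart) % p]) ++cmatch;
        double pct = 100.0 * cmatch / llen;
        if (pct >= 100.0 * min_frac) {
          st.push_back(lstart + 1);
          en.push_back(lend + 1);
          pd.push_back(p);
          mpct.push_back(pct);
          cons_v.push_back(cons);
        }
      }
      i = last_match + 1;
    }
  }
  return List::create(
    _["start"] = wrap(st), _["end"] = wrap(en), _["period"] = wrap(pd),
    _["matches"] = wrap(mpct), _["consensus"] = wrap(cons_v));
}

// Ungapped identity between two equal-length strings, ignoring positions
// where either has N.
// [[Rcpp::export]]
NumericVector ungapped_identity_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("length mismatch");
  long match = 0, valid = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] == 'N' || b[i] == 'N') continue;
    ++valid;
    if (a[i] == b[i]) ++match;
  }
  return NumericVector::create(valid ? 100.0 * match / valid : NA_REAL);
}
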