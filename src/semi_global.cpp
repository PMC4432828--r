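#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Semi-global (glocal) affine-gap alignment: the read (pattern) is aligned
// end to end; gaps at either end of the consensus (subject) are free, so the
// read matches a consecutive subsequence of the consensus. A gap of length k
// costs gap_open + k * gap_ext.
//
// Three-state DP (M: read i aligned to consensus j; X: gap in consensus,
// i.e. read base inserted; Y: gap in read, i.e. consensus base deleted).
// Free end gaps on the subject = zero initialisation of row 0 and maximum
// taken over the last row.

// [[Rcpp::export(name = ".semi_global_align_cpp")]]
List semi_global_align_cpp(std::string read, std::string consensus,
                           double match, double mismatch,
                           double gap_open, double gap_ext) {
  const int n = read.size();     // rows: read positions
  const int m = consensus.size();  // cols: consensus positions
  const double NEG = -std::numeric_limits<double>::infinity();
  // DP matrices (n+1) x (m+1), flattened
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  for (int j = 0; j <= m; ++j) M[at(0, j)] = 0.0;  // free subject start gap
  for (int i = 1; i <= n; ++i) {
    // read prefix unmatched before subject: insertion of read bases
    X[at(i, 0)] = gap_open + gap_ext * i;
  }

  for (int i = 1; i <= n; ++i) {
    const char rb = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char cb = consensus[j - 1];
      const double s = (rb == cb) ? match : mismatch;
      double diag = std::max(M[at(i - 1, j - 1)],
                             std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      M[at(i, j)] = diag + s;
      // X: consume read base i against a gap (vertical move)
      double open_x = std::max(M[at(i - 1, j)], Y[at(i - 1, j)]) + gap_open + gap_ext;
      double ext_x = X[at(i - 1, j)] + gap_ext;
      X[at(i, j)] = std::max(open_x, ext_x);
      // Y: consume consensus base j against a gap (horizontal move)
      double open_y = std::max(M[at(i, j - 1)], X[at(i, j - 1)]) + gap_open + gap_ext;
      double ext_y = Y[at(i, j - 1)] + gap_ext;
      Y[at(i, j)] = std::max(open_y, ext_y);
    }
  }

  // best score over the last row (free subject end gap)
  double best = NEG;
  int best_j = 0;
  char best_state = 'M';
  for (int j = 0; j <= m; ++j) {
    double vals[3] = {M[at(n, j)], X[at(n, j)], Y[at(n, j)]};
    char states[3] = {'M', 'X', 'Y'};
    for (int k = 0; k < 3; ++k) {
      if (vals[k] > best) {  // strict: ties resolved to the leftmost j
        best = vals[k];
        best_j = j;
        best_state = states[k];
      }
    }
  }

  // traceback from (n, best_j, best_state) to row 0
  int i = n, j = best_j;
  char state = best_state;
  int matches = 0, mismatches = 0, gap_cols = 0, aligned_cols = 0;
  int span_end = best_j;  // 0-based exclusive end on consensus
  const double eps = 1e-9;
  while (i > 0) {
    if (state == 'M') {
      double diag = std::max(M[at(i - 1, j - 1)],
                             std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      (void)diag;
      aligned_cols++;
      if (read[i - 1] == consensus[j - 1]) matches++; else mismatches++;
      // previous state is the diagonal argmax
      double a = M[at(i - 1, j - 1)], b = X[at(i - 1, j - 1)], c = Y[at(i - 1, j - 1)];
      i--; j--;
      if (a >= b - eps && a >= c - eps) state = 'M';
      else if (b >= c - eps) state = 'X';
      else state = 'Y';
    } else if (state == 'X') {
      aligned_cols++;
      gap_cols++;
      if (j == 0) {
        i--;  // leading read insertion
        continue;
      }
      double ext_x = X[at(i - 1, j)] + gap_ext;
      double open_m = M[at(i - 1, j)] + gap_open + gap_ext;
      double open_y = Y[at(i - 1, j)] + gap_open + gap_ext;
      i--;
      if (ext_x >= open_m - eps && ext_x >= open_y - eps) state = 'X';
      else if (open_m >= open_y - eps) state = 'M';
      else state = 'Y';
    } else {  // Y
      aligned_cols++;
      gap_cols++;
      double ext_y = Y[at(i, j - 1)] + gap_ext;
      double open_m = M[at(i, j - 1)] + gap_open + gap_ext;
      double open_x = X[at(i, j - 1)] + gap_open + gap_ext;
      j--;
      if (ext_y >= open_m - eps && ext_y >= open_x - eps) state = 'Y';
      else if (open_m >= open_x - eps) state = 'M';
      else state = 'X';
    }
  }
  int span_start = j;

  double identity = aligned_cols > 0 ? 100.0 * matches / aligned_cols : 0.0;
  return List::create(
    _["score"] = best,
    _["subject_start"] = span_start,
    _["subject_end"] = span_end,
    _["matches"] = matches,
    _["mismatches"] = mismatches,
    _["gap_columns"] = gap_cols,
    _["aligned_columns"] = aligned_cols,
    _["identity_percent"] = identity
  );
}
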