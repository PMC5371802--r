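#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch global alignment with match +1, mismatch -1, gap -1.
// Traceback ties resolve diagonal > up (gap in b) > left (gap in a), so the
// alignment -- and hence the identity, whose denominator counts gap columns --
// is fully deterministic.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("global_identity() requires non-empty sequences");
  NumericMatrix M(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) M(i, 0) = -i;
  for (int j = 1; j <= m; ++j) M(0, j) = -j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? 1.0 : -1.0;
      double diag = M(i - 1, j - 1) + s;
      double up = M(i - 1, j) - 1.0;
      double left = M(i, j - 1) - 1.0;
      M(i, j) = std::max(diag, std::max(up, left));
    }
  }
  std::string aa, bb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double s = (a[i - 1] == b[j - 1]) ? 1.0 : -1.0;
      if (M(i, j) == M(i - 1, j - 1) + s) {
        aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j;
        continue;
      }
    }
    if (i > 0 && M(i, j) == M(i - 1, j) - 1.0) {
      aa.push_back(a[i - 1]); bb.push_back('-'); --i;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  int matches = 0;
  for (size_t k = 0; k < aa.size(); ++k) {
    if (aa[k] == bb[k] && aa[k] != '-') ++matches;
  }
  return List::create(_["score"] = M(n, m),
                      _["matches"] = matches,
                      _["columns"] = (int)aa.size(),
                      _["identity"] = (double)matches / (double)aa.size(),
                      _["aligned_a"] = aa,
                      _["aligned_b"] = bb);
}
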