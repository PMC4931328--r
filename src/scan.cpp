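#include <Rcpp.h>
using namespace Rcpp;

// Scan `subject` for occurrences of `query` with at most `max_mm` mismatches
// (substitutions only, no indels). Returns 0-based start positions and the
// mismatch count of each hit. Early exit once the mismatch budget is blown,
// so the scan is fast for small budgets.
// [[Rcpp::export(name = ".scan_hits")]]
List scan_hits(const std::string& subject, const std::string& query,
               int max_mm) {
  const int n = (int)subject.size();
  const int m = (int)query.size();
  std::vector<int> pos, mm;
  if (m == 0 || m > n) {
    return List::create(_["pos"] = IntegerVector(0),
                        _["mm"] = IntegerVector(0));
  }
  const char* s = subject.data();
  const char* q = query.data();
  for (int i = 0; i <= n - m; ++i) {
    int d = 0;
    const char* w = s + i;
    for (int j = 0; j < m; ++j) {
      if (w[j] != q[j]) {
        if (++d > max_mm) break;
      }
    }
    if (d <= max_mm) {
      pos.push_back(i);
      mm.push_back(d);
    }
  }
  return List::create(_["pos"] = wrap(pos), _["mm"] = wrap(mm));
}

// Batched variant: one call per (subject, set of reads). Returns, per read,
// the number of best-stratum hits (stratum 0 = exact, stratum 1 = one
// mismatch, ...), the position of the first best hit and its stratum.
// Used by align_unique(); keeping the loop in C++ avoids per-read call
// overhead for libraries of 1e4+ reads.
// [[Rcpp::export(name = ".scan_best_stratum")]]
List scan_best_stratum(const std::string& subject,
                       const CharacterVector& queries, int max_mm) {
  const int nq = queries.size();
  IntegerVector n_best(nq), best_pos(nq), best_mm(nq);
  const int n = (int)subject.size();
  const char* s = subject.data();
  for (int r = 0; r < nq; ++r) {
    const char* q = CHAR(STRING_ELT(queries, r));
    const int m = (int)LENGTH(STRING_ELT(queries, r));
    int bmm = max_mm + 1, cnt = 0, bpos = -1;
    if (m > 0 && m <= n) {
      for (int i = 0; i <= n - m; ++i) {
        int d = 0;
        const char* w = s + i;
        // bound by current best stratum: a hit worse than it is irrelevant
        const int lim = bmm < max_mm ? bmm : max_mm;
        for (int j = 0; j < m; ++j) {
          if (w[j] != q[j]) {
            if (++d > lim) break;
          }
        }
        if (d <= lim) {
          if (d < bmm) {
            bmm = d; cnt = 1; bpos = i;
          } else if (d == bmm) {
            ++cnt;
          }
        }
      }
    }
    n_best[r] = cnt;
    best_pos[r] = bpos;
    best_mm[r] = (cnt > 0) ? bmm : NA_INTEGER;
  }
  return List::create(_["n_best"] = n_best, _["best_pos"] = best_pos,
                      _["best_mm"] = best_mm);
}
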