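#include <Rcpp.h>
#include <vector>
#include <set>
using namespace Rcpp;

// Average-linkage agglomeration on a precomputed distance matrix with a
// one-item-per-subject constraint: two clusters may merge only if their
// subject sets are disjoint.  Merges that would violate the constraint
// are skipped in favour of the next-smallest admissible distance.
// Ties are broken by the lexicographically smallest (i, j) pair, which
// keeps the procedure fully deterministic.
// [[Rcpp::export(name = ".constrained_linkage_cpp")]]
IntegerVector constrained_linkage_cpp(NumericMatrix D, IntegerVector subject,
                                      int n_clusters) {
  int n = D.nrow();
  if (D.ncol() != n) stop("distance matrix must be square");
  if (subject.size() != n) stop("subject vector length mismatch");
  if (n_clusters < 1 || n_clusters > n) stop("invalid n_clusters");

  std::vector<double> d(D.begin(), D.end());   // working copy, column-major
  std::vector<int> size(n, 1), parent(n);
  std::vector<bool> active(n, true);
  std::vector<std::set<int> > subj(n);
  for (int i = 0; i < n; ++i) { parent[i] = i; subj[i].insert(subject[i]); }

  int n_active = n;
  while (n_active > n_clusters) {
    double best = R_PosInf;
    int bi = -1, bj = -1;
    for (int j = 1; j < n; ++j) {
      if (!active[j]) continue;
      for (int i = 0; i < j; ++i) {
        if (!active[i]) continue;
        double dd = d[i + (long)n * j];
        if (dd < best) {
          // constraint: subject sets must be disjoint
          bool ok = true;
          const std::set<int> &a = subj[i].size() < subj[j].size() ? subj[i] : subj[j];
          const std::set<int> &b = subj[i].size() < subj[j].size() ? subj[j] : subj[i];
          for (std::set<int>::const_iterator it = a.begin(); it != a.end(); ++it)
            if (b.count(*it)) { ok = false; break; }
          if (ok) { best = dd; bi = i; bj = j; }
        }
      }
    }
    if (bi < 0) break;  // no admissible merge remains
    // Lance-Williams update for average linkage: merge bj into bi
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == bi || k == bj) continue;
      double dik = d[std::min(bi, k) + (long)n * std::max(bi, k)];
      double djk = d[std::min(bj, k) + (long)n * std::max(bj, k)];
      double dnew = (size[bi] * dik + size[bj] * djk) / (double)(size[bi] + size[bj]);
      d[std::min(bi, k) + (long)n * std::max(bi, k)] = dnew;
    }
    size[bi] += size[bj];
    subj[bi].insert(subj[bj].begin(), subj[bj].end());
    active[bj] = false;
    parent[bj] = bi;
    --n_active;
  }
  // resolve membership to active roots, then relabel 1..K in order of
  // smallest original member index
  IntegerVector memb(n);
  std::vector<int> root(n);
  for (int i = 0; i < n; ++i) {
    int r = i;
    while (parent[r] != r) r = parent[r];
    root[i] = r;
  }
  std::vector<int> relab(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (relab[root[i]] == 0) relab[root[i]] = ++next;
    memb[i] = relab[root[i]];
  }
  memb.attr("n_clusters") = next;
  return memb;
}
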