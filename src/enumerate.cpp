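#include <Rcpp.h>
#include <unordered_set>
#include <string>
#include <vector>
using namespace Rcpp;

// Pairwise-AND template enumeration over nibble-encoded rows.
//
// nib:   N x P integer matrix, nibble values 0..15 (column-major from R)
// n_col: original column count M (padded bits beyond M are guaranteed 0)
// r_min, c_min: minimum bicluster dimensions
// skip_sparse_seeds: skip seed pairs where either row has fewer than c_min
//   ones (their templates can never reach width c_min); output-equivalent.
// collect_k: also record, per scanned template, the per-nibble-position
//   exclusion counts (the K-sequence of the complexity derivation).
//
// One "comparison" is one nibble containment test (template AND row == template);
// a row scan stops at the first failing position.
// [[Rcpp::export(name = ".cpp_enumerate")]]
List cpp_enumerate(IntegerMatrix nib, int n_col, int r_min, int c_min,
                   bool skip_sparse_seeds, bool collect_k) {
  const int N = nib.nrow(), P = nib.ncol();
  static const int POP[16] = {0,1,1,2,1,2,2,3,1,2,2,3,2,3,3,4};

  // row-major copy for cache-friendly scans
  std::vector<unsigned char> rows((size_t)N * P);
  std::vector<int> ones(N, 0);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < P; ++k) {
      int v = nib(i, k);
      rows[(size_t)i * P + k] = (unsigned char)v;
      ones[i] += POP[v];
    }
  }

  std::unordered_set<std::string> seen;
  std::vector<std::vector<int> > bic_rows, bic_cols;
  std::vector<std::pair<int,int> > bic_seed;
  std::vector<double> per_template_checks;
  std::vector<std::pair<int,int> > template_seeds;
  List k_seqs;
  if (collect_k) k_seqs = List(0);
  std::vector<IntegerVector> k_store;

  long long total_checks = 0;
  long long n_pairs = 0, n_dup = 0, n_narrow = 0;
  std::string key((size_t)P, '\0');
  std::vector<unsigned char> tmpl(P);
  std::vector<int> members;
  std::vector<int> kexc(P);

  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      ++n_pairs;
      if (skip_sparse_seeds && (ones[i] < c_min || ones[j] < c_min)) {
        // template width <= min(ones) < c_min: would be skipped after ANDing
        continue;
      }
      const unsigned char *ri = &rows[(size_t)i * P];
      const unsigned char *rj = &rows[(size_t)j * P];
      int width = 0;
      for (int k = 0; k < P; ++k) {
        tmpl[k] = (unsigned char)(ri[k] & rj[k]);
        width += POP[tmpl[k]];
        key[k] = (char)tmpl[k];
      }
      if (!seen.insert(key).second) { ++n_dup; continue; }
      if (width < c_min) { ++n_narrow; continue; }

      // scan all non-seed rows against the template
      members.clear();
      std::fill(kexc.begin(), kexc.end(), 0);
      long long checks = 0;
      for (int l = 0; l < N; ++l) {
        if (l == i || l == j) continue;
        const unsigned char *rl = &rows[(size_t)l * P];
        bool ok = true;
        for (int k = 0; k < P; ++k) {
          ++checks;
          if ((unsigned char)(rl[k] & tmpl[k]) != tmpl[k]) {
            ok = false;
            ++kexc[k];
            break;
          }
        }
        if (ok) members.push_back(l);
      }
      total_checks += checks;
      per_template_checks.push_back((double)checks);
      template_seeds.push_back(std::make_pair(i, j));
      if (collect_k) k_store.push_back(IntegerVector(kexc.begin(), kexc.end()));

      // I = members plus the two seeds, in row order
      if ((int)members.size() + 2 >= r_min) {
        std::vector<int> I;
        I.reserve(members.size() + 2);
        size_t m = 0;
        for (int l = 0; l < N; ++l) {
          if (l == i || l == j) { I.push_back(l + 1); continue; }
          if (m < members.size() && members[m] == l) { I.push_back(l + 1); ++m; }
        }
        std::vector<int> J;
        J.reserve(width);
        for (int k = 0; k < P; ++k) {
          if (!tmpl[k]) continue;
          for (int b = 0; b < 4; ++b) {
            if (tmpl[k] & (8 >> b)) J.push_back(4 * k + b + 1);
          }
        }
        bic_rows.push_back(I);
        bic_cols.push_back(J);
        bic_seed.push_back(std::make_pair(i + 1, j + 1));
      }
    }
  }

  int nb = (int)bic_rows.size();
  List rows_out(nb), cols_out(nb);
  IntegerMatrix bseeds(nb, 2);
  for (int b = 0; b < nb; ++b) {
    rows_out[b] = IntegerVector(bic_rows[b].begin(), bic_rows[b].end());
    cols_out[b] = IntegerVector(bic_cols[b].begin(), bic_cols[b].end());
    bseeds(b, 0) = bic_seed[b].first;
    bseeds(b, 1) = bic_seed[b].second;
  }
  int nt = (int)per_template_checks.size();
  IntegerMatrix seeds(nt, 2);
  for (int t = 0; t < nt; ++t) {
    seeds(t, 0) = template_seeds[t].first + 1;
    seeds(t, 1) = template_seeds[t].second + 1;
  }
  List stats = List::create(
    _["per_template_checks"] = NumericVector(per_template_checks.begin(),
                                             per_template_checks.end()),
    _["template_seeds"] = seeds,
    _["total_checks"] = (double)total_checks,
    _["n_seed_pairs"] = (double)n_pairs,
    _["n_templates_scanned"] = (double)nt,
    _["n_duplicate_templates"] = (double)n_dup,
    _["n_below_cmin"] = (double)n_narrow);
  if (collect_k) {
    List ks(nt);
    for (int t = 0; t < nt; ++t) ks[t] = k_store[t];
    stats["k_sequences"] = ks;
  }
  return List::create(_["rows"] = rows_out, _["cols"] = cols_out,
                      _["seed_pairs"] = bseeds, _["stats"] = stats);
}
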