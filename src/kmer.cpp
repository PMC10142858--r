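#include <Rcpp.h>
using namespace Rcpp;

// Keep an x k-mer iff its Hamming distance to EVERY y k-mer is >= min_diff.
// Early exit per comparison once min_diff mismatches are seen.
// [[Rcpp::export(name = ".kmer_filter_cpp")]]
LogicalVector kmer_filter_cpp(CharacterVector xk, CharacterVector yk,
                              int min_diff) {
  int nx = xk.size(), ny = yk.size();
  LogicalVector keep(nx);
  std::vector<std::string> ys(ny);
  for (int j = 0; j < ny; ++j) ys[j] = as<std::string>(yk[j]);
  for (int i = 0; i < nx; ++i) {
    std::string x = as<std::string>(xk[i]);
    int k = x.size();
    bool ok = true;
    for (int j = 0; j < ny && ok; ++j) {
      const std::string &y = ys[j];
      if ((int)y.size() != k) continue;
      int d = 0;
      for (int p = 0; p < k; ++p) {
        if (x[p] != y[p] && ++d >= min_diff) break;
      }
      if (d < min_diff) ok = false;
    }
    keep[i] = ok;
  }
  return keep;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t p = 0; p < r.size(); ++p) {
      switch (r[p]) {
        case 'A': r[p] = 'T'; break;
        case 'C': r[p] = 'G'; break;
        case 'G': r[p] = 'C'; break;
        case 'T': r[p] = 'A'; break;
        case 'a': r[p] = 't'; break;
        case 'c': r[p] = 'g'; break;
        case 'g': r[p] = 'c'; break;
        case 't': r[p] = 'a'; break;
        default: break;
      }
    }
    out[i] = r;
  }
  return out;
}
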