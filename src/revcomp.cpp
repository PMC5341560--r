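#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = s[s.size() - 1 - j];
      switch (c) {
        case 'A': r[j] = 'T'; break;
        case 'C': r[j] = 'G'; break;
        case 'G': r[j] = 'C'; break;
        case 'T': r[j] = 'A'; break;
        case 'a': r[j] = 't'; break;
        case 'c': r[j] = 'g'; break;
        case 'g': r[j] = 'c'; break;
        case 't': r[j] = 'a'; break;
        default: r[j] = 'N';
      }
    }
    out[i] = r;
  }
  return out;
}
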