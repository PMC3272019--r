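#include <Rcpp.h>
#include <string>
#include <vector>
#include <sstream>

// Sliding-window substitution-only alignment of tags against a set of
// reference sequences, both strands, reporting every placement with at most
// max_mm mismatches. Mismatches are encoded "pos:REF>ALT" (1-based tag
// coordinates, bases in tag orientation), ";"-separated.

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

// [[Rcpp::export(name = ".scan_align")]]
Rcpp::List scan_align(Rcpp::CharacterVector tags, Rcpp::CharacterVector refs,
                      int max_mm) {
  std::vector<int> out_tag, out_ref, out_start, out_end, out_nmm;
  std::vector<int> out_anti;
  std::vector<std::string> out_mm;

  int nref = refs.size();
  std::vector<std::string> refstr(nref);
  for (int r = 0; r < nref; ++r) refstr[r] = Rcpp::as<std::string>(refs[r]);

  for (int t = 0; t < tags.size(); ++t) {
    std::string tag = Rcpp::as<std::string>(tags[t]);
    int L = tag.size();
    std::string rc(L, 'N');
    for (int i = 0; i < L; ++i) rc[L - 1 - i] = comp(tag[i]);

    for (int r = 0; r < nref; ++r) {
      const std::string &ref = refstr[r];
      int n = ref.size();
      if (L > n) continue;
      for (int anti = 0; anti < 2; ++anti) {
        const std::string &q = anti ? rc : tag;
        for (int s = 0; s + L <= n; ++s) {
          int mm = 0;
          for (int i = 0; i < L && mm <= max_mm; ++i) {
            if (q[i] != ref[s + i]) ++mm;
          }
          if (mm > max_mm) continue;
          std::ostringstream enc;
          bool first = true;
          if (mm > 0) {
            for (int i = 0; i < L; ++i) {
              if (q[i] != ref[s + i]) {
                int tagpos;
                char refbase, altbase;
                if (anti) {
                  tagpos = L - i;             // 1-based position in the tag
                  refbase = comp(ref[s + i]); // ref in tag orientation
                  altbase = tag[tagpos - 1];
                } else {
                  tagpos = i + 1;
                  refbase = ref[s + i];
                  altbase = tag[i];
                }
                if (!first) enc << ";";
                enc << tagpos << ":" << refbase << ">" << altbase;
                first = false;
              }
            }
          }
          out_tag.push_back(t + 1);
          out_ref.push_back(r + 1);
          out_start.push_back(s + 1);
          out_end.push_back(s + L);
          out_anti.push_back(anti);
          out_nmm.push_back(mm);
          out_mm.push_back(enc.str());
        }
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("tag_idx") = out_tag, Rcpp::Named("ref_idx") = out_ref,
      Rcpp::Named("start") = out_start, Rcpp::Named("end") = out_end,
      Rcpp::Named("antisense") = out_anti, Rcpp::Named("n_mismatch") = out_nmm,
      Rcpp::Named("mismatches") = out_mm);
}
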