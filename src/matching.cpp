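#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive ungapped scan of many tags against many precursor sequences.
// For every placement of a tag on a precursor with Hamming mismatches
// <= max_mismatch, one row (tag index, precursor index, 0-based start,
// mismatch count) is emitted. Equivalent to a brute-force sliding window;
// the early-abort on the mismatch budget is the only shortcut.
// [[Rcpp::export(name = ".hamming_scan_all")]]
DataFrame hamming_scan_all(CharacterVector tags, CharacterVector precursors,
                           int max_mismatch) {
  std::vector<int> out_tag, out_prec, out_start, out_mm;
  std::vector<std::string> precs(precursors.size());
  for (int j = 0; j < precursors.size(); ++j)
    precs[j] = as<std::string>(precursors[j]);

  for (int i = 0; i < tags.size(); ++i) {
    const std::string tag = as<std::string>(tags[i]);
    const int tlen = (int)tag.size();
    for (int j = 0; j < (int)precs.size(); ++j) {
      const std::string& prec = precs[j];
      const int plen = (int)prec.size();
      if (tlen > plen) continue;
      for (int s = 0; s <= plen - tlen; ++s) {
        int mm = 0;
        for (int k = 0; k < tlen; ++k) {
          if (tag[k] != prec[s + k] && ++mm > max_mismatch) break;
        }
        if (mm <= max_mismatch) {
          out_tag.push_back(i + 1);
          out_prec.push_back(j + 1);
          out_start.push_back(s);
          out_mm.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["tag_idx"] = out_tag, _["prec_idx"] = out_prec,
                           _["start"] = out_start, _["mismatches"] = out_mm,
                           _["stringsAsFactors"] = false);
}

// Leftmost 3' adapter hit per read: position p (0-based) such that the
// read suffix starting at p aligns to a prefix of the adapter with
// overlap >= min_overlap and mismatch rate <= max_mismatch_rate.
// Returns the 0-based cut position, or -1 when no hit is found.
// [[Rcpp::export(name = ".adapter_cut_positions")]]
IntegerVector adapter_cut_positions(CharacterVector reads, std::string adapter,
                                    int min_overlap, double max_mismatch_rate) {
  const int alen = (int)adapter.size();
  IntegerVector cut(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    const std::string read = as<std::string>(reads[i]);
    const int rlen = (int)read.size();
    int pos = -1;
    for (int p = 0; p + min_overlap <= rlen; ++p) {
      const int ov = std::min(rlen - p, alen);
      const int budget = (int)std::floor(max_mismatch_rate * ov + 1e-9);
      int mm = 0;
      bool ok = true;
      for (int k = 0; k < ov; ++k) {
        if (read[p + k] != adapter[k] && ++mm > budget) { ok = false; break; }
      }
      if (ok) { pos = p; break; }
    }
    cut[i] = pos;
  }
  return cut;
}
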