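#include <Rcpp.h>
using namespace Rcpp;

// Pool runs of bins where both histograms have < 5 counts, then compute
// chi^2 = sum (p_e - p_m)^2 / (p_e/n_e + p_m/n_m) and the number of
// admitted (pooled, non-empty) bins. Trailing underfilled bins join the
// previous group.
// [[Rcpp::export(name = ".chisqBinnedCpp")]]
NumericVector chisqBinnedCpp(NumericVector ce, NumericVector cm,
                             double ne, double nm) {
  int n = ce.size();
  std::vector<double> gE, gM;
  double accE = 0.0, accM = 0.0;
  bool open = false;
  for (int i = 0; i < n; ++i) {
    accE += ce[i]; accM += cm[i];
    open = true;
    if (accE >= 5.0 || accM >= 5.0) {
      gE.push_back(accE); gM.push_back(accM);
      accE = accM = 0.0; open = false;
    }
  }
  if (open) {
    if (!gE.empty()) { gE.back() += accE; gM.back() += accM; }
    else { gE.push_back(accE); gM.push_back(accM); }
  }
  // pooled-proportion error: s_i^2 = pbar (1/ne + 1/nm), the stable
  // evaluation of the Poisson errors of both normalized histograms
  double chi2 = 0.0;
  int admitted = 0;
  for (size_t i = 0; i < gE.size(); ++i) {
    if (gE[i] + gM[i] <= 0.0) continue;
    ++admitted;
    double pe = gE[i] / ne, pm = gM[i] / nm;
    double pb = (gE[i] + gM[i]) / (ne + nm);
    double s2 = pb * (1.0 / ne + 1.0 / nm);
    double d = pe - pm;
    chi2 += d * d / s2;
  }
  return NumericVector::create(chi2, (double)admitted);
}
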