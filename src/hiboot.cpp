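#include <Rcpp.h>
using namespace Rcpp;

// One uniform draw -> index in [0, n). Uses R's RNG stream so results are
// reproducible from set.seed() and can be mirrored draw-for-draw in R with
// floor(runif(1) * n) + 1.
static inline int draw_index(int n) {
  int i = (int)(unif_rand() * n);
  return (i == n) ? n - 1 : i;
}

// Three-level hierarchical bootstrap engine.
//
// Per resample: draw n_bird_slots birds with replacement; for each drawn
// bird, draw (its own syllable count) syllables with replacement from its
// syllables; for each drawn syllable draw m_base baseline iterations (Hz),
// optionally m_ref reference-day iterations, and m_win window iterations,
// all with replacement and with counts fixed independently of the
// syllable's observed iteration counts. The syllable baseline is recomputed
// from the resampled baseline draws; window draws are converted to
// semitones against that recomputed baseline only then, and (in washout
// mode) the recomputed reference mean in semitones is subtracted. Returns
// the unweighted mean of all converted window values per resample.
//
// RNG consumption order per syllable draw: syllable index, baseline draws,
// reference draws (washout only), window draws.
// [[Rcpp::export(name = ".hb_engine")]]
NumericVector hb_engine(List base, List win, List ref, IntegerVector bird_syls_ptr,
                        IntegerVector syl_of_bird, int n_resamples,
                        int m_base, int m_win, int m_ref, bool washout) {
  const int n_syl = base.size();
  const int n_birds = bird_syls_ptr.size() - 1;
  std::vector<NumericVector> base_v(n_syl), win_v(n_syl), ref_v(n_syl);
  for (int s = 0; s < n_syl; ++s) {
    base_v[s] = as<NumericVector>(base[s]);
    win_v[s] = as<NumericVector>(win[s]);
    if (washout) ref_v[s] = as<NumericVector>(ref[s]);
    if (base_v[s].size() == 0 || win_v[s].size() == 0 ||
        (washout && ref_v[s].size() == 0))
      stop("syllable with an empty baseline/window/reference pool");
  }
  const double log2e12 = 12.0 / std::log(2.0);
  NumericVector out(n_resamples);
  for (int r = 0; r < n_resamples; ++r) {
    double tot = 0.0;
    long cnt = 0;
    for (int b = 0; b < n_birds; ++b) {
      int k = draw_index(n_birds);
      int from = bird_syls_ptr[k], to = bird_syls_ptr[k + 1];
      int nsy = to - from;
      for (int t = 0; t < nsy; ++t) {
        int s = syl_of_bird[from + draw_index(nsy)];
        const NumericVector &bp = base_v[s];
        double bsum = 0.0;
        int nb = bp.size();
        for (int i = 0; i < m_base; ++i) bsum += bp[draw_index(nb)];
        double bmean = bsum / m_base;
        double ref_st = 0.0;
        if (washout) {
          const NumericVector &rp = ref_v[s];
          double rsum = 0.0;
          int nr = rp.size();
          for (int i = 0; i < m_ref; ++i) rsum += rp[draw_index(nr)];
          ref_st = log2e12 * std::log((rsum / m_ref) / bmean);
        }
        const NumericVector &wp = win_v[s];
        int nw = wp.size();
        for (int i = 0; i < m_win; ++i) {
          double st = log2e12 * std::log(wp[draw_index(nw)] / bmean);
          tot += st - ref_st;
          ++cnt;
        }
      }
    }
    out[r] = tot / cnt;
  }
  return out;
}
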