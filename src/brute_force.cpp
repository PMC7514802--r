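#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Class cost over the half-open bin range [lo, hi), in O(1) via prefix
// sums. Empty classes (zero probability mass) cost 0.
namespace {

struct Prefix {
    std::vector<double> P;   // cumulative p
    std::vector<double> E;   // cumulative p*log(p)
    std::vector<double> M;   // cumulative p*level
    double muT;
    bool kapur;

    explicit Prefix(const NumericVector &probs, bool kapur_) :
        P(257, 0.0), E(257, 0.0), M(257, 0.0), kapur(kapur_) {
        for (int j = 0; j < 256; ++j) {
            double p = probs[j];
            P[j + 1] = P[j] + p;
            E[j + 1] = E[j] + (p > 0.0 ? p * std::log(p) : 0.0);
            M[j + 1] = M[j] + p * j;
        }
        muT = M[256];
    }

    double cost(int lo, int hi) const {
        double w = P[hi] - P[lo];
        if (w <= 0.0) return 0.0;
        if (kapur) {
            double s = E[hi] - E[lo];
            return std::log(w) - s / w;
        }
        double mu = (M[hi] - M[lo]) / w;
        double d = mu - muT;
        return w * d * d;
    }
};

} // namespace

// [[Rcpp::export]]
List brute_force_cpp(NumericVector probs, int K, bool kapur) {
    if (probs.size() != 256)
        stop("probs must have length 256");
    if (K < 1 || K > 3)
        stop("K must be 1, 2 or 3");
    Prefix pre(probs, kapur);

    double best = R_NegInf;
    int b1 = -1, b2 = -1, b3 = -1;

    if (K == 1) {
        for (int t1 = 1; t1 <= 255; ++t1) {
            double f = pre.cost(0, t1) + pre.cost(t1, 256);
            if (f > best) { best = f; b1 = t1; }
        }
        return List::create(_["thresholds"] = IntegerVector::create(b1),
                            _["fitness"] = best);
    }
    if (K == 2) {
        for (int t1 = 1; t1 <= 254; ++t1) {
            double c0 = pre.cost(0, t1);
            for (int t2 = t1 + 1; t2 <= 255; ++t2) {
                double f = c0 + pre.cost(t1, t2) + pre.cost(t2, 256);
                if (f > best) { best = f; b1 = t1; b2 = t2; }
            }
        }
        return List::create(_["thresholds"] = IntegerVector::create(b1, b2),
                            _["fitness"] = best);
    }
    for (int t1 = 1; t1 <= 253; ++t1) {
        double c0 = pre.cost(0, t1);
        for (int t2 = t1 + 1; t2 <= 254; ++t2) {
            double c1 = c0 + pre.cost(t1, t2);
            for (int t3 = t2 + 1; t3 <= 255; ++t3) {
                double f = c1 + pre.cost(t2, t3) + pre.cost(t3, 256);
                if (f > best) { best = f; b1 = t1; b2 = t2; b3 = t3; }
            }
        }
    }
    return List::create(_["thresholds"] = IntegerVector::create(b1, b2, b3),
                        _["fitness"] = best);
}
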