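#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// One lattice update of the Fokker-Planck propagator:
//   p'(i,j) = p(i,j) * (1 - S(i,j)/5) + (1/5) * sum of incoming fluxes,
// where S is the sum of the four outward acceptance probabilities.
// kl(i,j): acceptance (i,j) -> (i-1,j); kr: -> (i+1,j);
// kd(i,j): acceptance (i,j) -> (i,j-1); ku: -> (i,j+1).
// Edge entries pointing at ghost cells are zero, which implements the
// no-flux boundary.
static void mh_step_inner(const double* p, double* out, int n,
                          const double* kl, const double* kr,
                          const double* kd, const double* ku,
                          const double* stay) {
    for (int j = 0; j < n; ++j) {
        const int col = j * n;
        for (int i = 0; i < n; ++i) {
            const int idx = col + i;
            double in = 0.0;
            if (i + 1 < n) in += p[idx + 1] * kl[idx + 1];
            if (i > 0)     in += p[idx - 1] * kr[idx - 1];
            if (j + 1 < n) in += p[idx + n] * kd[idx + n];
            if (j > 0)     in += p[idx - n] * ku[idx - n];
            out[idx] = p[idx] * stay[idx] + 0.2 * in;
        }
    }
}

static void make_stay(const double* kl, const double* kr, const double* kd,
                      const double* ku, int n, std::vector<double>& stay) {
    stay.resize((size_t)n * n);
    for (int idx = 0; idx < n * n; ++idx)
        stay[idx] = 1.0 - 0.2 * (kl[idx] + kr[idx] + kd[idx] + ku[idx]);
}

// [[Rcpp::export]]
NumericMatrix mh_propagate_cpp(NumericMatrix p, NumericMatrix kl,
                               NumericMatrix kr, NumericMatrix kd,
                               NumericMatrix ku, int steps) {
    const int n = p.nrow();
    if (p.ncol() != n) stop("field must be square");
    std::vector<double> stay;
    make_stay(kl.begin(), kr.begin(), kd.begin(), ku.begin(), n, stay);
    std::vector<double> a(p.begin(), p.end()), b((size_t)n * n);
    double* cur = a.data();
    double* nxt = b.data();
    for (int s = 0; s < steps; ++s) {
        mh_step_inner(cur, nxt, n, kl.begin(), kr.begin(), kd.begin(),
                      ku.begin(), stay.data());
        std::swap(cur, nxt);
    }
    NumericMatrix res(n, n);
    std::copy(cur, cur + (size_t)n * n, res.begin());
    return res;
}

// Summed negative log transition density over a list of observation pairs
// sharing one kernel. For pair q a unit mass is placed in cell
// (from_i[q], from_j[q]) (0-based), propagated steps[q] lattice updates,
// and each target point r with to_pair[r] == q contributes
// -log(max(mass(to_i[r], to_j[r]) / delta^2, floor)).
// Target points must be grouped so that to_pair is non-decreasing.
// [[Rcpp::export]]
double nll_pairs_cpp(NumericMatrix kl, NumericMatrix kr, NumericMatrix kd,
                     NumericMatrix ku, IntegerVector from_i,
                     IntegerVector from_j, IntegerVector steps,
                     IntegerVector to_i, IntegerVector to_j,
                     IntegerVector to_pair, double delta2,
                     double dens_floor) {
    const int n = kl.nrow();
    const int npair = from_i.size();
    std::vector<double> stay;
    make_stay(kl.begin(), kr.begin(), kd.begin(), ku.begin(), n, stay);
    std::vector<double> a((size_t)n * n), b((size_t)n * n);
    double total = 0.0;
    int r = 0;
    const int nto = to_i.size();
    for (int q = 0; q < npair; ++q) {
        std::fill(a.begin(), a.end(), 0.0);
        a[(size_t)from_j[q] * n + from_i[q]] = 1.0;
        double* cur = a.data();
        double* nxt = b.data();
        for (int s = 0; s < steps[q]; ++s) {
            mh_step_inner(cur, nxt, n, kl.begin(), kr.begin(), kd.begin(),
                          ku.begin(), stay.data());
            std::swap(cur, nxt);
        }
        while (r < nto && to_pair[r] == q) {
            double mass = cur[(size_t)to_j[r] * n + to_i[r]];
            double dens = mass / delta2;
            if (dens < dens_floor) dens = dens_floor;
            total -= std::log(dens);
            ++r;
        }
    }
    return total;
}
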