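#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Self-contained counter-free RNG for the Euler-Maruyama oracle.
// xoshiro256++ seeded through splitmix64; normals by Box-Muller.
// The oracle burns through billions of Gaussian draws, so it keeps its own
// generator, seeded explicitly from the user-supplied seed.
namespace {

struct Xoshiro {
    uint64_t s[4];
    explicit Xoshiro(uint64_t seed) {
        uint64_t x = seed;
        for (int i = 0; i < 4; ++i) {
            x += 0x9E3779B97F4A7C15ULL;
            uint64_t z = x;
            z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
            z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
            s[i] = z ^ (z >> 31);
        }
    }
    static uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }
    uint64_t next() {
        uint64_t result = rotl(s[0] + s[3], 23) + s[0];
        uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t;
        s[3] = rotl(s[3], 45);
        return result;
    }
    double runif() {  // in (0, 1)
        return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    }
};

struct Normals {
    Xoshiro rng;
    double spare;
    bool has_spare;
    explicit Normals(uint64_t seed) : rng(seed), spare(0), has_spare(false) {}
    double draw() {
        if (has_spare) { has_spare = false; return spare; }
        double u = rng.runif(), v = rng.runif();
        double r = std::sqrt(-2.0 * std::log(u));
        double a = 6.283185307179586476925286766559 * v;
        spare = r * std::sin(a);
        has_spare = true;
        return r * std::cos(a);
    }
};

inline void grad_aim(double y1, double y2, const double* p, double& g1,
                     double& g2) {
    // p = (l1, l2, l12, th1, th2, n1, n2)
    g1 = -2.0 * p[0] * y1 + p[3] + p[5] * (std::log(y1) - std::log(1.0 - y1))
         + p[2] * y2;
    g2 = -2.0 * p[1] * y2 + p[4] + p[6] * (std::log(y2) - std::log(1.0 - y2))
         + p[2] * y1;
}

inline void grad_ou(double y1, double y2, const double* p, double& g1,
                    double& g2) {
    // p = (mu1, mu2, a11, a22, a12)
    g1 = p[2] * (y1 - p[0]) + p[4] * (y2 - p[1]);
    g2 = p[4] * (y1 - p[0]) + p[3] * (y2 - p[1]);
}

inline double clamp(double x, double lo, double hi) {
    return x < lo ? lo : (x > hi ? hi : x);
}

}  // namespace

// Euler-Maruyama endpoints of the gradient diffusion
//   dy_i = -D dF/dy_i dt + sqrt(2D) dW_i
// clamped into [eps, 1-eps] after every step. Trajectories are recorded at
// every requested duration (sorted ascending); between recordings steps of
// size dt are taken, with a truncated final step landing exactly on the
// requested time. model: 1 = AIM, 2 = bounded OU.
// [[Rcpp::export]]
List em_simulate_cpp(double y01, double y02, int n_traj, double dt,
                     int model, NumericVector pars, double D, double eps,
                     NumericVector durations, double seed) {
    const int nsnap = durations.size();
    std::vector<NumericMatrix> snaps;
    snaps.reserve(nsnap);
    for (int s = 0; s < nsnap; ++s) snaps.emplace_back(n_traj, 2);
    Normals rng((uint64_t)seed);
    const double* p = pars.begin();
    const double sdt_full = std::sqrt(2.0 * D * dt);
    for (int k = 0; k < n_traj; ++k) {
        double y1 = y01, y2 = y02, t = 0.0;
        for (int s = 0; s < nsnap; ++s) {
            double remaining = durations[s] - t;
            long nfull = (long)std::floor(remaining / dt + 1e-9);
            double rem = remaining - nfull * dt;
            if (rem < dt * 1e-9) rem = 0.0;
            for (long u = 0; u < nfull; ++u) {
                double g1, g2;
                if (model == 1) grad_aim(y1, y2, p, g1, g2);
                else grad_ou(y1, y2, p, g1, g2);
                y1 += -D * g1 * dt + sdt_full * rng.draw();
                y2 += -D * g2 * dt + sdt_full * rng.draw();
                y1 = clamp(y1, eps, 1.0 - eps);
                y2 = clamp(y2, eps, 1.0 - eps);
            }
            if (rem > 0.0) {
                double g1, g2;
                if (model == 1) grad_aim(y1, y2, p, g1, g2);
                else grad_ou(y1, y2, p, g1, g2);
                const double sdt = std::sqrt(2.0 * D * rem);
                y1 += -D * g1 * rem + sdt * rng.draw();
                y2 += -D * g2 * rem + sdt * rng.draw();
                y1 = clamp(y1, eps, 1.0 - eps);
                y2 = clamp(y2, eps, 1.0 - eps);
            }
            snaps[s](k, 0) = y1;
            snaps[s](k, 1) = y2;
            t = durations[s];
        }
    }
    List out(nsnap);
    for (int s = 0; s < nsnap; ++s) out[s] = snaps[s];
    return out;
}
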