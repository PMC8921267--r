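#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Self-contained counter RNG (splitmix64) so that trajectories are bitwise
// reproducible from an integer seed, independent of R's RNG state.
static inline uint64_t sm64_next(uint64_t &state) {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

// uniform on [0, 1)
static inline double sm64_unif(uint64_t &state) {
    return (double)(sm64_next(state) >> 11) * (1.0 / 9007199254740992.0);
}

// sin and cos in one call where glibc provides it (the integrator spends
// most of its time here)
#if defined(__linux__) && defined(__GLIBC__)
extern "C" void sincos(double, double *, double *);
static inline void sincos2(double x, double *s, double *c) {
    sincos(x, s, c);
}
#else
static inline void sincos2(double x, double *s, double *c) {
    *s = std::sin(x);
    *c = std::cos(x);
}
#endif

// Stochastic Heun (predictor-corrector) for delay-coupled phase oscillators
//   dtheta_i/dt = omega_i + sum_j k_ij sin(theta_j(t - d_ij*dt) - theta_i(t))
//                 + sigma * eta_i(t),   eta ~ U[-1, 1]
// Noise increment sigma*sqrt(dt)*u added once per step, identical in
// predictor and corrector. Delay history kept in sin/cos ring buffers of
// depth max(d_ij)+1, pre-filled with the initial phases (history for t <= 0).
// The sine of a phase difference is expanded so the inner pair loop is
// multiply-add only.
//
// Phases are recorded (unwrapped) at steps m*stride for m in [m0, m1].
// [[Rcpp::export]]
NumericMatrix heun_kuramoto_cpp(NumericMatrix k, IntegerMatrix dsteps,
                                NumericVector omega, double sigma, double dt,
                                int stride, int m0, int m1, int seed,
                                Nullable<NumericVector> init_phases =
                                    R_NilValue) {
    const int N = omega.size();
    if (k.nrow() != N || k.ncol() != N || dsteps.nrow() != N ||
        dsteps.ncol() != N)
        stop("coupling/delay matrices must be N x N with N = length(omega)");
    if (m1 < m0) stop("no samples retained: m1 < m0");
    const int n_steps = m1 * stride;

    // sparse directed pair list (targets i, sources j) over nonzero k
    std::vector<int> pi_, pj_, pd_;
    std::vector<double> pk_;
    int maxd = 0;
    for (int i = 0; i < N; ++i) {
        for (int j = 0; j < N; ++j) {
            if (i != j && k(i, j) != 0.0) {
                pi_.push_back(i);
                pj_.push_back(j);
                pk_.push_back(k(i, j));
                int d = dsteps(i, j);
                if (d < 0) stop("negative delay step");
                pd_.push_back(d);
                if (d > maxd) maxd = d;
            }
        }
    }
    const int npair = (int)pi_.size();
    const int D = maxd + 1;

    uint64_t rng = (uint64_t)(uint32_t)seed * 0x2545F4914F6CDD1DULL + 1ULL;

    std::vector<double> theta(N);
    if (init_phases.isNotNull()) {
        NumericVector ip(init_phases);
        if (ip.size() != N) stop("init_phases must have length N");
        for (int i = 0; i < N; ++i) theta[i] = ip[i];
    } else {
        for (int i = 0; i < N; ++i)
            theta[i] = 2.0 * M_PI * sm64_unif(rng);
    }

    // ring buffers of sin/cos, column-major [slot + D*i]
    std::vector<double> sbuf((size_t)D * N), cbuf((size_t)D * N);
    for (int i = 0; i < N; ++i) {
        double s, c;
        sincos2(theta[i], &s, &c);
        for (int sl = 0; sl < D; ++sl) {
            sbuf[sl + (size_t)D * i] = s;
            cbuf[sl + (size_t)D * i] = c;
        }
    }

    const int M = m1 - m0 + 1;
    NumericMatrix out(M, N);
    const double sq = sigma * std::sqrt(dt);

    std::vector<double> drift1(N), drift2(N), xi(N), pred(N), sp(N), cp(N);

    for (int n = 0; n <= n_steps; ++n) {
        if (n % stride == 0) {
            int m = n / stride;
            if (m >= m0 && m <= m1)
                for (int i = 0; i < N; ++i) out(m - m0, i) = theta[i];
        }
        if (n == n_steps) break;

        const int h = n % D;  // slot holding step n

        // predictor drift at t_n
        for (int i = 0; i < N; ++i) drift1[i] = omega[i];
        for (int p = 0; p < npair; ++p) {
            const int i = pi_[p], j = pj_[p], d = pd_[p];
            int sl = h - d;
            if (sl < 0) sl += D;
            const double sj = sbuf[sl + (size_t)D * j];
            const double cj = cbuf[sl + (size_t)D * j];
            const double si = sbuf[h + (size_t)D * i];
            const double ci = cbuf[h + (size_t)D * i];
            drift1[i] += pk_[p] * (sj * ci - cj * si);
        }

        if (sigma > 0.0) {
            for (int i = 0; i < N; ++i)
                xi[i] = sq * (2.0 * sm64_unif(rng) - 1.0);
        } else {
            for (int i = 0; i < N; ++i) xi[i] = 0.0;
        }

        for (int i = 0; i < N; ++i) {
            pred[i] = theta[i] + dt * drift1[i] + xi[i];
            sincos2(pred[i], &sp[i], &cp[i]);
        }

        // corrector drift at t_{n+1}: delayed phase is the stored history for
        // d >= 1 and the predicted value for d = 0
        for (int i = 0; i < N; ++i) drift2[i] = omega[i];
        for (int p = 0; p < npair; ++p) {
            const int i = pi_[p], j = pj_[p], d = pd_[p];
            double sj, cj;
            if (d == 0) {
                sj = sp[j];
                cj = cp[j];
            } else {
                int sl = (n + 1 - d) % D;
                if (sl < 0) sl += D;
                sj = sbuf[sl + (size_t)D * j];
                cj = cbuf[sl + (size_t)D * j];
            }
            drift2[i] += pk_[p] * (sj * cp[i] - cj * sp[i]);
        }

        const int hn = (n + 1) % D;
        for (int i = 0; i < N; ++i) {
            theta[i] += 0.5 * dt * (drift1[i] + drift2[i]) + xi[i];
            if (!std::isfinite(theta[i]))
                stop("non-finite phase for region %d at step %d", i + 1,
                     n + 1);
            sincos2(theta[i], &sbuf[hn + (size_t)D * i],
                    &cbuf[hn + (size_t)D * i]);
        }
    }
    return out;
}
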