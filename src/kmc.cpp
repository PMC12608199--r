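#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <vector>
#include <random>

using namespace Rcpp;

// Rejection-free (Gillespie) kinetic Monte Carlo for HP chains on the simple
// cubic lattice.  The move set is restricted to corner flips and 90-degree
// end flips (180-degree end reversals are never generated); each move
// displaces exactly one bead by a lattice diagonal.  Rates are Metropolis,
// W = min(1, exp(-dE/T)) with kB = 1; the waiting time for an event is
// exponential with rate W_T = sum(W_i).
//
// Engine notes.  Occupancy lives on a 32^3 torus (the diameter of a chain of
// at most 31 beads never reaches 32, so modular wrap-around cannot alias two
// beads); each site carries a packed record (occupant bead, adjacent-H
// count, adjacent-P count), so the energy change of a flip is two loads:
// both bonded neighbours of a flipping bead are adjacent to the old and the
// new site alike, hence their contributions cancel and dE reduces to count
// differences.  The proposal table is rebuilt after every event.

namespace {

constexpr int GBITS = 5, GSIDE = 1 << GBITS, GMASK = GSIDE - 1;
constexpr size_t GSIZE = (size_t)GSIDE * GSIDE * GSIDE;
inline int gidx(int x, int y, int z) {
    return ((x & GMASK) << (2 * GBITS)) | ((y & GMASK) << GBITS) | (z & GMASK);
}

const int DX[6] = {1, -1, 0, 0, 0, 0};
const int DY[6] = {0, 0, 1, -1, 0, 0};
const int DZ[6] = {0, 0, 0, 0, 1, -1};

constexpr int WOFF = 256;     // dE offset into the rate table
constexpr int MAXN = 31;      // grid aliasing bound
constexpr int MAXK = 2 * MAXN + 8;

struct Site {                  // one lattice site, packed into 4 bytes
    int8_t bead;               // occupant index or -1
    int8_t nH, nP;             // adjacent beads of each type
    int8_t pad;
};

// xoshiro256++ (Blackman & Vigna), seeded through splitmix64
struct Rng {
    uint64_t s[4];
    explicit Rng(uint64_t seed) {
        for (int i = 0; i < 4; ++i) {
            seed += 0x9E3779B97F4A7C15ULL;
            uint64_t z = seed;
            z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
            z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
            s[i] = z ^ (z >> 31);
        }
    }
    static inline uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }
    inline uint64_t next() {
        uint64_t result = rotl(s[0] + s[3], 23) + s[0];
        uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t; s[3] = rotl(s[3], 45);
        return result;
    }
    // uniform on the open interval (0,1); -log(u) is always finite
    inline double unif() {
        return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    }
};

inline uint64_t sm64(uint64_t z) {
    z += 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

// independent stream per (base seed, temperature index, run index)
inline uint64_t stream_seed(uint64_t base, uint64_t a, uint64_t b) {
    return sm64(sm64(base) ^ sm64(a * 0x8000000000000001ULL + 0x5851F42D4C957F2DULL) ^
                sm64(b + 0xDA942042E4DD58B5ULL));
}

struct Chain {
    int N;
    int t[MAXN];
    int eps[2][2];
    int px[MAXN], py[MAXN], pz[MAXN];
    std::vector<Site> grid;
    double wtab[2 * WOFF + 1];
    long long E;

    // proposal arrays (rebuilt every event)
    int pb[MAXK], pk[MAXK], ptx[MAXK], pty[MAXK], ptz[MAXK], pdE[MAXK];
    double pW[MAXK];
    int K;

    Chain(const IntegerVector& types, const IntegerVector& e3, double T)
        : N(types.size()), grid(GSIZE) {
        if (N < 3 || N > MAXN) stop("KMC engine supports 3..31 beads");
        for (int i = 0; i < N; ++i) t[i] = types[i];
        eps[0][0] = e3[0]; eps[0][1] = e3[1];
        eps[1][0] = e3[1]; eps[1][1] = e3[2];
        int emax = std::max(std::abs((int)e3[0]), std::abs((int)e3[2]));
        if (10 * emax > WOFF) stop("contact energies too large for the rate table");
        for (int d = -WOFF; d <= WOFF; ++d)
            wtab[d + WOFF] = d <= 0 ? 1.0 : std::exp(-d / T);
    }

    void reset(const IntegerMatrix& coords) {
        Site empty; empty.bead = -1; empty.nH = 0; empty.nP = 0; empty.pad = 0;
        std::fill(grid.begin(), grid.end(), empty);
        for (int i = 0; i < N; ++i) {
            px[i] = coords(i, 0); py[i] = coords(i, 1); pz[i] = coords(i, 2);
            grid[gidx(px[i], py[i], pz[i])].bead = (int8_t)i;
        }
        for (int i = 0; i < N; ++i)
            for (int d = 0; d < 6; ++d) {
                Site& s = grid[gidx(px[i] + DX[d], py[i] + DY[d], pz[i] + DZ[d])];
                if (t[i] == 0) s.nH += 1; else s.nP += 1;
            }
        E = totalEnergy();
    }

    long long totalEnergy() const {
        long long e = 0;
        for (int i = 0; i < N; ++i)
            for (int j = i + 3; j < N; j += 2) {
                int d = std::abs(px[i] - px[j]) + std::abs(py[i] - py[j]) +
                        std::abs(pz[i] - pz[j]);
                if (d == 1) e += eps[t[i]][t[j]];
            }
        return e;
    }

    // dE of moving bead i between two sites; both bonded neighbours are
    // adjacent to either site, so their count contributions cancel
    inline int flipDE(int i, const Site& to, const Site& from) const {
        return eps[t[i]][0] * ((int)to.nH - (int)from.nH) +
               eps[t[i]][1] * ((int)to.nP - (int)from.nP);
    }

    inline void propose(int i, int kind, int tx, int ty, int tz,
                        const Site& from) {
        const Site& to = grid[gidx(tx, ty, tz)];
        if (to.bead >= 0) return;
        int dE = flipDE(i, to, from);
        pb[K] = i; pk[K] = kind; ptx[K] = tx; pty[K] = ty; ptz[K] = tz;
        pdE[K] = dE; pW[K] = wtab[dE + WOFF];
        ++K;
    }

    double rebuild() {
        K = 0;
        for (int i = 1; i < N - 1; ++i) {
            int tx = px[i - 1] + px[i + 1] - px[i];
            int ty = py[i - 1] + py[i + 1] - py[i];
            int tz = pz[i - 1] + pz[i + 1] - pz[i];
            if (tx == px[i] && ty == py[i] && tz == pz[i]) continue; // collinear
            propose(i, 0, tx, ty, tz, grid[gidx(px[i], py[i], pz[i])]);
        }
        for (int endSel = 0; endSel < 2; ++endSel) {
            int i = endSel == 0 ? 0 : N - 1;
            int nb = endSel == 0 ? 1 : N - 2;
            int bx = px[i] - px[nb], by = py[i] - py[nb], bz = pz[i] - pz[nb];
            const Site& from = grid[gidx(px[i], py[i], pz[i])];
            for (int d = 0; d < 6; ++d) {
                if (DX[d] == bx && DY[d] == by && DZ[d] == bz) continue;   // stay
                if (DX[d] == -bx && DY[d] == -by && DZ[d] == -bz) continue; // 180
                propose(i, 1, px[nb] + DX[d], py[nb] + DY[d], pz[nb] + DZ[d], from);
            }
        }
        double WT = 0.0;
        for (int i = 0; i < K; ++i) WT += pW[i];
        return WT;
    }

    inline void apply(int m) {
        int i = pb[m];
        grid[gidx(px[i], py[i], pz[i])].bead = -1;
        if (t[i] == 0) {
            for (int d = 0; d < 6; ++d)
                grid[gidx(px[i] + DX[d], py[i] + DY[d], pz[i] + DZ[d])].nH -= 1;
        } else {
            for (int d = 0; d < 6; ++d)
                grid[gidx(px[i] + DX[d], py[i] + DY[d], pz[i] + DZ[d])].nP -= 1;
        }
        px[i] = ptx[m]; py[i] = pty[m]; pz[i] = ptz[m];
        grid[gidx(px[i], py[i], pz[i])].bead = (int8_t)i;
        if (t[i] == 0) {
            for (int d = 0; d < 6; ++d)
                grid[gidx(px[i] + DX[d], py[i] + DY[d], pz[i] + DZ[d])].nH += 1;
        } else {
            for (int d = 0; d < 6; ++d)
                grid[gidx(px[i] + DX[d], py[i] + DY[d], pz[i] + DZ[d])].nP += 1;
        }
        E += pdE[m];
    }
};

IntegerMatrix rodCoords(int N) {
    IntegerMatrix m(N, 3);
    for (int i = 0; i < N; ++i) { m(i, 0) = i; m(i, 1) = 0; m(i, 2) = 0; }
    return m;
}

// one full trajectory; returns reached flag and writes time/events
inline bool trajectory(Chain& ch, Rng& rng, long long e0, double max_events,
                       double& time, double& events, bool& trapped) {
    time = 0.0; events = 0.0; trapped = false;
    if (ch.E == e0) return true;
    while (events < max_events) {
        double WT = ch.rebuild();
        if (ch.K == 0) { trapped = true; return false; }
        double r = rng.unif() * WT;
        int pick = ch.K - 1;
        for (int i = 0; i < ch.K; ++i) {
            r -= ch.pW[i];
            if (r <= 0.0) { pick = i; break; }
        }
        time += -std::log(rng.unif()) / WT;
        ch.apply(pick);
        events += 1.0;
        if (ch.E == e0) return true;
    }
    return false;
}

} // namespace

// [[Rcpp::export(name = ".kmc_catalog_cpp")]]
DataFrame kmc_catalog_cpp(IntegerMatrix coords, IntegerVector types,
                          IntegerVector eps, double temperature) {
    Chain ch(types, eps, temperature);
    ch.reset(coords);
    ch.rebuild();
    int K = ch.K;
    IntegerVector bead(K), tx(K), ty(K), tz(K), dE(K);
    CharacterVector kind(K);
    NumericVector W(K);
    for (int i = 0; i < K; ++i) {
        bead[i] = ch.pb[i] + 1;
        kind[i] = ch.pk[i] == 0 ? "corner" : "end";
        tx[i] = ch.ptx[i]; ty[i] = ch.pty[i]; tz[i] = ch.ptz[i];
        dE[i] = ch.pdE[i]; W[i] = ch.pW[i];
    }
    DataFrame out = DataFrame::create(
        _["kind"] = kind, _["bead"] = bead, _["tx"] = tx, _["ty"] = ty,
        _["tz"] = tz, _["d_e"] = dE, _["w"] = W,
        _["stringsAsFactors"] = false);
    out.attr("energy") = (double)ch.E;
    return out;
}

// energy-bookkeeping probe: runs a seeded trajectory and compares the
// incrementally tracked energy with a from-scratch recomputation after
// every event; returns the number of disagreements (0 when exact)
// [[Rcpp::export(name = ".kmc_energy_audit_cpp")]]
List kmc_energy_audit_cpp(IntegerVector types, IntegerVector eps,
                          double temperature, double n_events, double seed) {
    Chain ch(types, eps, temperature);
    ch.reset(rodCoords(types.size()));
    Rng rng(stream_seed((uint64_t)seed, 7, 7));
    int bad = 0;
    double ev = 0;
    for (; ev < n_events; ++ev) {
        double WT = ch.rebuild();
        if (ch.K == 0) break;
        double r = rng.unif() * WT;
        int pick = ch.K - 1;
        for (int i = 0; i < ch.K; ++i) {
            r -= ch.pW[i];
            if (r <= 0.0) { pick = i; break; }
        }
        rng.unif();   // waiting-time draw, kept for stream parity
        ch.apply(pick);
        if (ch.E != ch.totalEnergy()) ++bad;
    }
    return List::create(_["mismatches"] = bad, _["events"] = ev,
                        _["final_energy"] = (double)ch.E);
}

// [[Rcpp::export(name = ".kmc_run_cpp")]]
List kmc_run_cpp(IntegerVector types, IntegerVector eps, double temperature,
                 double target_energy, double max_events,
                 double seed, double stream_a, double stream_b,
                 Nullable<IntegerMatrix> start = R_NilValue) {
    Chain ch(types, eps, temperature);
    IntegerMatrix init = start.isNotNull() ? IntegerMatrix(start)
                                           : rodCoords(types.size());
    ch.reset(init);
    Rng rng(stream_seed((uint64_t)seed, (uint64_t)stream_a, (uint64_t)stream_b));
    double time, events;
    bool trapped;
    bool reached = trajectory(ch, rng, (long long)target_energy, max_events,
                              time, events, trapped);
    IntegerMatrix fin(ch.N, 3);
    for (int i = 0; i < ch.N; ++i) {
        fin(i, 0) = ch.px[i]; fin(i, 1) = ch.py[i]; fin(i, 2) = ch.pz[i];
    }
    return List::create(
        _["fpt"] = reached ? time : NA_REAL,
        _["time"] = time,
        _["events"] = events,
        _["reached"] = reached,
        _["censored"] = !reached && !trapped,
        _["trapped"] = trapped,
        _["final_energy"] = (double)ch.E,
        _["final_coords"] = fin);
}

// [[Rcpp::export(name = ".kmc_many_cpp")]]
List kmc_many_cpp(IntegerVector types, IntegerVector eps, double temperature,
                  double target_energy, int runs, double max_events,
                  double seed, double temp_index) {
    NumericVector fpt(runs), events(runs);
    LogicalVector reached(runs);
    Chain ch(types, eps, temperature);
    IntegerMatrix init = rodCoords(types.size());
    long long e0 = (long long)target_energy;

    for (int run = 0; run < runs; ++run) {
        ch.reset(init);
        Rng rng(stream_seed((uint64_t)seed, (uint64_t)temp_index, (uint64_t)run));
        double time, ev;
        bool trapped;
        bool ok = trajectory(ch, rng, e0, max_events, time, ev, trapped);
        if (trapped) stop("trapped state encountered: no legal moves at run %d", run + 1);
        fpt[run] = ok ? time : NA_REAL;
        events[run] = ev;
        reached[run] = ok;
        Rcpp::checkUserInterrupt();
    }
    return List::create(_["fpt"] = fpt, _["events"] = events,
                        _["reached"] = reached);
}

// sampling kernels exposed for distributional tests ------------------------

// [[Rcpp::export(name = ".kmc_draw_wait_cpp")]]
NumericVector kmc_draw_wait_cpp(double total_rate, int n, double seed) {
    Rng rng(stream_seed((uint64_t)seed, 0, 0));
    NumericVector out(n);
    for (int i = 0; i < n; ++i) out[i] = -std::log(rng.unif()) / total_rate;
    return out;
}

// [[Rcpp::export(name = ".kmc_draw_select_cpp")]]
IntegerVector kmc_draw_select_cpp(NumericVector w, int n, double seed) {
    Rng rng(stream_seed((uint64_t)seed, 0, 1));
    int K = w.size();
    double WT = 0.0;
    for (int i = 0; i < K; ++i) WT += w[i];
    IntegerVector counts(K);
    for (int i = 0; i < n; ++i) {
        double r = rng.unif() * WT;
        int pick = K - 1;
        for (int j = 0; j < K; ++j) {
            r -= w[j];
            if (r <= 0.0) { pick = j; break; }
        }
        counts[pick] += 1;
    }
    return counts;
}
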