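#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Exact enumeration of self-avoiding walks on the simple cubic lattice with
// incremental contact-energy bookkeeping.  Conformations are counted under the
// fixed-first-step convention (first bond +x), either directly or via
// symmetry-reduced enumeration (first bond +x, first non-x bond +y, first
// out-of-plane bond +z) with orbit weights 1 (linear), 4 (planar), 8 (3-D).

namespace {

struct DosEnum {
    int N;
    int L, L2;                    // grid side and side^2
    std::vector<int8_t> grid;     // bead index at site, -1 if empty
    std::vector<int> t;           // residue type per bead: 0 = H, 1 = P
    int eps[2][2];
    int offs[6];
    std::vector<int64_t> hist;    // index m = -E
    int maxM;

    DosEnum(const IntegerVector& types, const IntegerVector& e3) {
        N = types.size();
        L = 2 * N + 3;
        L2 = L * L;
        grid.assign((size_t)L * L2, -1);
        t.assign(types.begin(), types.end());
        eps[0][0] = e3[0]; eps[0][1] = e3[1];
        eps[1][0] = e3[1]; eps[1][1] = e3[2];
        offs[0] = 1; offs[1] = -1;
        offs[2] = L; offs[3] = -L;
        offs[4] = L2; offs[5] = -L2;
        // worst case every bead in max contacts; generous bound on -E
        maxM = 1 + (-e3[0]) * 2 * N;
        hist.assign(maxM + 1, 0);
    }

    inline int center() const { return (N + 1) * (1 + L + L2); }

    // energy gained by placing bead k at site p (grid not yet marked at p)
    inline int dE(int k, int p) const {
        int e = 0;
        const int tk = t[k];
        for (int d = 0; d < 6; ++d) {
            int j = grid[p + offs[d]];
            if (j >= 0 && j != k - 1) e += eps[tk][t[j]];
        }
        return e;
    }

    // mode: 0 = fixed first step (+x), every later step free
    void growFixed(int k, int p, int E) {
        if (k == N) { hist[-E] += 1; return; }
        for (int d = 0; d < 6; ++d) {
            int q = p + offs[d];
            if (grid[q] >= 0) continue;
            int e2 = E + dE(k, q);
            grid[q] = (int8_t)k;
            growFixed(k + 1, q, e2);
            grid[q] = -1;
        }
    }

    // mode 1: symmetry-reduced; dim = 1 axial, 2 planar, 3 three-dimensional
    void growSym(int k, int p, int E, int dim) {
        if (k == N) { hist[-E] += (dim == 1 ? 1 : (dim == 2 ? 4 : 8)); return; }
        int nd = (dim == 1) ? 3 : (dim == 2 ? 5 : 6);
        for (int d = 0; d < nd; ++d) {
            int q = p + offs[d];
            if (grid[q] >= 0) continue;
            int dim2 = dim;
            if (dim == 1 && d >= 2) dim2 = 2;
            else if (dim == 2 && d >= 4) dim2 = 3;
            int e2 = E + dE(k, q);
            grid[q] = (int8_t)k;
            growSym(k + 1, q, e2, dim2);
            grid[q] = -1;
        }
    }

    void run(int mode) {
        int p0 = center();
        grid[p0] = 0;
        int p1 = p0 + offs[0];
        grid[p1] = 1;
        if (N == 1) { hist[0] = 1; return; }
        if (N == 2) { hist[0] = 1; return; }
        if (mode == 0) growFixed(2, p1, 0);
        else growSym(2, p1, 0, 1);
    }
};

} // namespace

// [[Rcpp::export(name = ".enum_dos_cpp")]]
List enum_dos_cpp(IntegerVector types, IntegerVector eps, int mode) {
    DosEnum en(types, eps);
    en.run(mode);
    std::vector<double> cnt;
    std::vector<int> energy;
    for (int m = en.maxM; m >= 0; --m) {
        if (en.hist[m] > 0) {
            energy.push_back(-m);
            cnt.push_back((double)en.hist[m]);
        }
    }
    return List::create(_["energy"] = wrap(energy), _["count"] = wrap(cnt));
}

// ---------------------------------------------------------------------------
// Ground-state representative: depth-first search that keeps one minimum-energy
// conformation (as a direction string over the canonical first-step frame).

namespace {

struct GsEnum : DosEnum {
    int bestE;
    std::vector<int> dirs, bestDirs;

    GsEnum(const IntegerVector& types, const IntegerVector& e3)
        : DosEnum(types, e3), bestE(1) {
        dirs.assign(N - 1, 0);
        bestDirs.assign(N - 1, 0);
    }

    void grow(int k, int p, int E, int dim) {
        if (k == N) {
            if (E < bestE) { bestE = E; bestDirs = dirs; }
            return;
        }
        int nd = (dim == 1) ? 3 : (dim == 2 ? 5 : 6);
        for (int d = 0; d < nd; ++d) {
            int q = p + offs[d];
            if (grid[q] >= 0) continue;
            int dim2 = dim;
            if (dim == 1 && d >= 2) dim2 = 2;
            else if (dim == 2 && d >= 4) dim2 = 3;
            dirs[k - 1] = d;
            grid[q] = (int8_t)k;
            grow(k + 1, q, E + dE(k, q), dim2);
            grid[q] = -1;
        }
    }
};

} // namespace

// [[Rcpp::export(name = ".gs_conformation_cpp")]]
IntegerVector gs_conformation_cpp(IntegerVector types, IntegerVector eps) {
    GsEnum en(types, eps);
    int p0 = en.center();
    en.grid[p0] = 0;
    int p1 = p0 + en.offs[0];
    en.grid[p1] = 1;
    en.dirs[0] = 0;
    en.grow(2, p1, 0, 1);
    IntegerVector out(en.N - 1);
    for (int i = 0; i < en.N - 1; ++i) out[i] = en.bestDirs[i];
    out.attr("energy") = en.bestE;
    return out;
}

// ---------------------------------------------------------------------------
// Sequence screen: one symmetry-weighted enumeration pass aggregates
// conformation counts keyed by the contact-pair set (a bitmask over the
// geometrically admissible nonconsecutive pairs), then every sequence of the
// 2^N sequence space is evaluated against the distinct signatures with
// popcount arithmetic.  Signatures are scanned in decreasing contact count so
// the scan can stop once -eHH * c can no longer reach the running minimum.

namespace {

struct FlatMap {
    // open-addressing hash map uint64 -> int64 count
    std::vector<uint64_t> keys;
    std::vector<int64_t> vals;
    std::vector<uint8_t> used;
    size_t mask, n, cap;

    explicit FlatMap(size_t cap2) {
        cap = ((size_t)1) << cap2;
        mask = cap - 1;
        keys.assign(cap, 0); vals.assign(cap, 0); used.assign(cap, 0);
        n = 0;
    }
    static inline uint64_t mix(uint64_t x) {
        x ^= x >> 33; x *= 0xff51afd7ed558ccdULL;
        x ^= x >> 33; x *= 0xc4ceb9fe1a85ec53ULL;
        x ^= x >> 33; return x;
    }
    void grow() {
        FlatMap big(0);
        big.cap = cap << 1; big.mask = big.cap - 1;
        big.keys.assign(big.cap, 0); big.vals.assign(big.cap, 0);
        big.used.assign(big.cap, 0); big.n = 0;
        for (size_t i = 0; i < cap; ++i)
            if (used[i]) big.add(keys[i], vals[i]);
        keys.swap(big.keys); vals.swap(big.vals); used.swap(big.used);
        cap = big.cap; mask = big.mask;
    }
    inline void add(uint64_t k, int64_t w) {
        size_t i = mix(k) & mask;
        for (;;) {
            if (!used[i]) {
                if (n * 2 >= cap) { grow(); add(k, w); return; }
                used[i] = 1; keys[i] = k; vals[i] = w; ++n;
                return;
            }
            if (keys[i] == k) { vals[i] += w; return; }
            i = (i + 1) & mask;
        }
    }
};

struct SigEnum {
    int N, L, L2;
    std::vector<int8_t> grid;
    int offs[6];
    std::vector<int> pairBit;     // pairBit[i*N+j] = bit index or -1
    int nPairs;
    FlatMap map;

    explicit SigEnum(int n) : N(n), map(22) {
        L = 2 * N + 3; L2 = L * L;
        grid.assign((size_t)L * L2, -1);
        offs[0] = 1; offs[1] = -1; offs[2] = L; offs[3] = -L;
        offs[4] = L2; offs[5] = -L2;
        pairBit.assign(N * N, -1);
        nPairs = 0;
        for (int i = 0; i < N; ++i)
            for (int j = i + 3; j < N; j += 2)
                pairBit[i * N + j] = nPairs++;
        if (nPairs > 64) stop("chain too long for 64-bit contact signatures");
    }

    void grow(int k, int p, uint64_t sig, int dim) {
        if (k == N) { map.add(sig, dim == 1 ? 1 : (dim == 2 ? 4 : 8)); return; }
        int nd = (dim == 1) ? 3 : (dim == 2 ? 5 : 6);
        for (int d = 0; d < nd; ++d) {
            int q = p + offs[d];
            if (grid[q] >= 0) continue;
            int dim2 = dim;
            if (dim == 1 && d >= 2) dim2 = 2;
            else if (dim == 2 && d >= 4) dim2 = 3;
            uint64_t s2 = sig;
            for (int dd = 0; dd < 6; ++dd) {
                int j = grid[q + offs[dd]];
                if (j >= 0 && j != k - 1)
                    s2 |= (1ULL << pairBit[j * N + k]);
            }
            grid[q] = (int8_t)k;
            grow(k + 1, q, s2, dim2);
            grid[q] = -1;
        }
    }

    void run() {
        int p0 = (N + 1) * (1 + L + L2);
        grid[p0] = 0;
        grid[p0 + offs[0]] = 1;
        grow(2, p0 + offs[0], 0, 1);
    }
};

} // namespace

// Returns, for every sequence index s in 0..2^N-1 (bit i set = residue i is H),
// the ground-state energy and its degeneracy under the fixed-first-step count.
// [[Rcpp::export(name = ".screen_cpp")]]
List screen_cpp(int N, IntegerVector eps, bool progress = false) {
    SigEnum en(N);
    en.run();

    // collect signatures bucketed by contact count, descending
    struct Sig { uint64_t key; int64_t w; };
    std::vector<std::vector<Sig>> buckets(en.nPairs + 1);
    for (size_t i = 0; i < en.map.cap; ++i)
        if (en.map.used[i]) {
            int c = __builtin_popcountll(en.map.keys[i]);
            buckets[c].push_back({en.map.keys[i], en.map.vals[i]});
        }
    int cmax = en.nPairs;
    while (cmax > 0 && buckets[cmax].empty()) --cmax;

    const int eHH = eps[0], eHP = eps[1], ePP = eps[2];
    const size_t nSeq = ((size_t)1) << N;
    std::vector<int> e0(nSeq, 0);
    std::vector<double> ne0(nSeq, 0.0);

    // pair endpoint tables
    std::vector<int> pi(en.nPairs), pj(en.nPairs);
    for (int i = 0; i < N; ++i)
        for (int j = i + 3; j < N; j += 2) {
            int b = en.pairBit[i * N + j];
            pi[b] = i; pj[b] = j;
        }

    for (size_t s = 0; s < nSeq; ++s) {
        // sequence reversal symmetry: DoS(s) == DoS(reverse(s))
        size_t rev = 0;
        for (int i = 0; i < N; ++i)
            if (s & (((size_t)1) << i)) rev |= ((size_t)1) << (N - 1 - i);
        if (rev < s) { e0[s] = e0[rev]; ne0[s] = ne0[rev]; continue; }

        uint64_t hh = 0, hp = 0;
        for (int b = 0; b < en.nPairs; ++b) {
            bool ih = (s >> pi[b]) & 1, jh = (s >> pj[b]) & 1;
            if (ih && jh) hh |= (1ULL << b);
            else if (ih || jh) hp |= (1ULL << b);
        }
        int best = 0;        // straight rod always exists at E = 0
        double cnt = 0.0;    // counted below; rod included in c = 0 bucket
        for (int c = cmax; c >= 0; --c) {
            if ((int64_t)eHH * c > best) break;   // -|eHH|*c can't reach best
            for (const auto& sg : buckets[c]) {
                int nhh = __builtin_popcountll(sg.key & hh);
                int nhp = __builtin_popcountll(sg.key & hp);
                int E = eHH * nhh + eHP * nhp + ePP * (c - nhh - nhp);
                if (E < best) { best = E; cnt = (double)sg.w; }
                else if (E == best) cnt += (double)sg.w;
            }
        }
        e0[s] = best; ne0[s] = cnt;
        if (progress && (s & 0xFFF) == 0) Rcpp::checkUserInterrupt();
    }

    return List::create(_["e0"] = wrap(e0), _["ne0"] = wrap(ne0),
                        _["n_signatures"] = (double)en.map.n);
}
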