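#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <deque>
#include <string>
#include <vector>

using namespace Rcpp;

typedef unsigned __int128 u128;

// Per-base 64-bit constants for the strand-symmetric rolling hash
// (ntHash-style published values for A, C, G, T).
static const uint64_t SEED_TAB[4] = {
    0x3c8bfbb395c60474ULL,  // A
    0x3193c18562a02b4cULL,  // C
    0x20323ed082572324ULL,  // G
    0x295549f54be24456ULL   // T
};

static inline int base_code(char c) {
    switch (c) {
        case 'A': return 0;
        case 'C': return 1;
        case 'G': return 2;
        case 'T': return 3;
    }
    return -1;
}

static inline char comp_base(char c) {
    switch (c) {
        case 'A': return 'T';
        case 'C': return 'G';
        case 'G': return 'C';
        case 'T': return 'A';
    }
    return 'N';
}

static void check_acgt(const std::string& s, const char* where) {
    for (size_t i = 0; i < s.size(); ++i) {
        if (base_code(s[i]) < 0) {
            stop("%s: character '%c' at position %d is outside the A/C/G/T alphabet",
                 where, s[i], (int)(i + 1));
        }
    }
}

static inline uint64_t rol64(uint64_t v, unsigned s) {
    s &= 63u;
    return s ? (v << s) | (v >> (64u - s)) : v;
}

static inline uint64_t ror64(uint64_t v, unsigned s) {
    s &= 63u;
    return s ? (v >> s) | (v << (64u - s)) : v;
}

// Avalanche finalizer (splitmix64-style). The raw rotate/xor rolling hash
// leaves rank correlations between adjacent positions that bias minimizer
// density; a bijective mix restores effectively random order while keeping
// the O(1) rolling update and strand symmetry.
static inline uint64_t mix64(uint64_t x) {
    x ^= x >> 30;
    x *= 0xbf58476d1ce4e5b9ULL;
    x ^= x >> 27;
    x *= 0x94d049bb133111ebULL;
    x ^= x >> 31;
    return x;
}

static std::string hex64(uint64_t v) {
    char buf[17];
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)v);
    return std::string(buf);
}

// ---------------------------------------------------------------------------
// Homopolymer compression / expansion
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_hpc_compress(std::string seq) {
    if (seq.empty()) stop("hpc_compress: empty sequence");
    check_acgt(seq, "hpc_compress");
    std::string chars;
    std::vector<int> runs;
    chars.reserve(seq.size());
    size_t i = 0;
    while (i < seq.size()) {
        size_t j = i + 1;
        while (j < seq.size() && seq[j] == seq[i]) ++j;
        chars.push_back(seq[i]);
        runs.push_back((int)(j - i));
        i = j;
    }
    return List::create(_["chars"] = chars,
                        _["run_lengths"] = IntegerVector(runs.begin(), runs.end()));
}

// [[Rcpp::export]]
std::string cpp_hpc_expand(std::string chars, IntegerVector run_lengths) {
    if ((size_t)run_lengths.size() != chars.size())
        stop("hpc_expand: chars length (%d) != run_lengths length (%d)",
             (int)chars.size(), (int)run_lengths.size());
    size_t total = 0;
    for (int i = 0; i < run_lengths.size(); ++i) {
        if (run_lengths[i] < 1) stop("hpc_expand: run length < 1 at position %d", i + 1);
        total += (size_t)run_lengths[i];
    }
    std::string out;
    out.reserve(total);
    for (size_t i = 0; i < chars.size(); ++i)
        out.append((size_t)run_lengths[i], chars[i]);
    return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string seq) {
    std::string out(seq.size(), 'N');
    for (size_t i = 0; i < seq.size(); ++i) {
        char c = comp_base(seq[seq.size() - 1 - i]);
        if (c == 'N') stop("revcomp: non-ACGT character");
        out[i] = c;
    }
    return out;
}

// ---------------------------------------------------------------------------
// Strand-symmetric rolling hash (winnowing order)
// ---------------------------------------------------------------------------

// Canonical winnow value per k-mer start position: min(forward, rev-comp)
// of an ntHash-style rolling hash.  O(L) after O(k) initialization.
static std::vector<uint64_t> winnow_values(const std::string& s, int k) {
    int n = (int)s.size() - k + 1;
    std::vector<uint64_t> out;
    if (n <= 0) return out;
    out.resize(n);
    std::vector<int> code(s.size());
    for (size_t i = 0; i < s.size(); ++i) {
        code[i] = base_code(s[i]);
        if (code[i] < 0) stop("winnow hash: non-ACGT character at position %d", (int)(i + 1));
    }
    uint64_t fh = 0, rh = 0;
    for (int i = 0; i < k; ++i) {
        fh ^= rol64(SEED_TAB[code[i]], (unsigned)(k - 1 - i));
        rh ^= rol64(SEED_TAB[3 - code[i]], (unsigned)i);
    }
    out[0] = mix64(fh < rh ? fh : rh);
    for (int i = 1; i < n; ++i) {
        int out_c = code[i - 1], in_c = code[i + k - 1];
        fh = rol64(fh, 1) ^ rol64(SEED_TAB[out_c], (unsigned)k) ^ SEED_TAB[in_c];
        rh = ror64(rh ^ SEED_TAB[3 - out_c], 1) ^ rol64(SEED_TAB[3 - in_c], (unsigned)(k - 1));
        out[i] = mix64(fh < rh ? fh : rh);
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_rolling_hashes(std::string seq, int k) {
    if (k < 2) stop("k must be >= 2");
    std::vector<uint64_t> v = winnow_values(seq, k);
    CharacterVector out(v.size());
    for (size_t i = 0; i < v.size(); ++i) out[i] = hex64(v[i]);
    return out;
}

// Direct per-window recomputation from the definitional formulas, no rolling
// update; used as an independent check of the rolling recurrence.
// [[Rcpp::export]]
CharacterVector cpp_window_hashes_direct(std::string seq, int k) {
    int n = (int)seq.size() - k + 1;
    if (n <= 0) return CharacterVector(0);
    CharacterVector out(n);
    for (int p = 0; p < n; ++p) {
        uint64_t fh = 0, rh = 0;
        for (int i = 0; i < k; ++i) {
            int c = base_code(seq[p + i]);
            if (c < 0) stop("non-ACGT character");
            fh ^= rol64(SEED_TAB[c], (unsigned)(k - 1 - i));
            rh ^= rol64(SEED_TAB[3 - c], (unsigned)i);
        }
        out[p] = hex64(mix64(fh < rh ? fh : rh));
    }
    return out;
}

// ---------------------------------------------------------------------------
// Minimizer selection
// ---------------------------------------------------------------------------

// A position is selected iff it is the (leftmost) minimum of at least one
// window of w consecutive k-mer start positions.  If fewer than w positions
// exist, the whole range is one window.  Monotonic-deque sweep, O(L).
static std::vector<int> select_positions(const std::vector<uint64_t>& v, int w) {
    std::vector<int> sel;
    int n = (int)v.size();
    if (n == 0) return sel;
    if (w < 1) stop("w must be >= 1");
    int weff = w > n ? n : w;
    std::deque<int> dq;
    int last = -1;
    for (int j = 0; j < n; ++j) {
        while (!dq.empty() && v[dq.back()] > v[j]) dq.pop_back();
        dq.push_back(j);
        int i = j - weff + 1;  // window start
        if (i < 0) continue;
        while (dq.front() < i) dq.pop_front();
        int m = dq.front();  // leftmost minimum of window [i, i+weff)
        if (m != last) {
            sel.push_back(m);
            last = m;
        }
    }
    return sel;
}

// [[Rcpp::export]]
IntegerVector cpp_select_minimizers(std::string seq, int k, int w) {
    if (k < 2) stop("k must be >= 2");
    std::vector<uint64_t> v = winnow_values(seq, k);
    std::vector<int> sel = select_positions(v, w);
    return IntegerVector(sel.begin(), sel.end());
}

// ---------------------------------------------------------------------------
// 128-bit identity hash (node names)
// ---------------------------------------------------------------------------

static u128 fnv1a_128(const std::string& s) {
    u128 h = ((u128)0x6c62272e07bb0142ULL << 64) | 0x62b821756295c58dULL;
    const u128 prime = ((u128)0x0000000001000000ULL << 64) | 0x000000000000013bULL;
    for (size_t i = 0; i < s.size(); ++i) {
        h ^= (u128)(unsigned char)s[i];
        h *= prime;
    }
    return h;
}

static std::string hex128(u128 v) {
    char buf[33];
    snprintf(buf, sizeof(buf), "%016llx%016llx",
             (unsigned long long)(uint64_t)(v >> 64),
             (unsigned long long)(uint64_t)v);
    return std::string(buf);
}

// [[Rcpp::export]]
std::string cpp_fnv128_hex(std::string s) {
    return hex128(fnv1a_128(s));
}

// ---------------------------------------------------------------------------
// Minimizer chain of one HPC sequence: positions plus canonical identities
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_chain(std::string seq, int k, int w) {
    check_acgt(seq, "chain");
    std::vector<uint64_t> v = winnow_values(seq, k);
    std::vector<int> sel = select_positions(v, w);
    int m = (int)sel.size();
    IntegerVector pos(m);
    CharacterVector hash(m), kmer(m);
    LogicalVector fwd(m);
    for (int i = 0; i < m; ++i) {
        int p = sel[i];
        std::string km = seq.substr((size_t)p, (size_t)k);
        std::string rc = cpp_revcomp(km);
        bool is_fwd = km <= rc;  // palindrome -> forward
        const std::string& can = is_fwd ? km : rc;
        pos[i] = p;
        fwd[i] = is_fwd;
        kmer[i] = can;
        hash[i] = hex128(fnv1a_128(can));
    }
    return List::create(_["positions"] = pos, _["hash"] = hash,
                        _["forward"] = fwd, _["kmer"] = kmer);
}
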