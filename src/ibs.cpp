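#include <Rcpp.h>
#include <cstring>
#include <cstdint>

using namespace Rcpp;

// Packed-genotype IBS kernel.
//
// Genotypes are held as three bitplanes per individual (see pack_genotypes()):
//   p1: bit set iff g >= 1
//   p2: bit set iff g == 2
//   mm: bit set iff genotype missing (padding bits beyond the last locus are
//       flagged missing at pack time, so they drop out here automatically)
// With this unary 2-bit code, |g_i - g_j| at a locus equals the number of
// planes in which the bits differ, so the per-pair mismatch total is
// popcount(xor(p1)) + popcount(xor(p2)) over jointly non-missing loci.

static inline uint64_t load_word(const unsigned char* p, int nbytes) {
    uint64_t w = 0;
    std::memcpy(&w, p, nbytes);
    return w;
}

// [[Rcpp::export(name = ".ibs_packed_cpp")]]
List ibs_packed_cpp(RawVector p1, RawVector p2, RawVector mm,
                    int n_ind, int bytes_per_ind) {
    const unsigned char* b1 = RAW(p1);
    const unsigned char* b2 = RAW(p2);
    const unsigned char* bm = RAW(mm);

    NumericMatrix mism(n_ind, n_ind);   // sum |g_i - g_j| over shared loci
    IntegerMatrix nshared(n_ind, n_ind);

    const int nw = bytes_per_ind / 8;
    const int rem = bytes_per_ind - 8 * nw;

    for (int i = 0; i < n_ind; ++i) {
        const unsigned char* i1 = b1 + (size_t)i * bytes_per_ind;
        const unsigned char* i2 = b2 + (size_t)i * bytes_per_ind;
        const unsigned char* im = bm + (size_t)i * bytes_per_ind;
        for (int j = i; j < n_ind; ++j) {
            const unsigned char* j1 = b1 + (size_t)j * bytes_per_ind;
            const unsigned char* j2 = b2 + (size_t)j * bytes_per_ind;
            const unsigned char* jm = bm + (size_t)j * bytes_per_ind;
            long long diff = 0, shared = 0;
            int off = 0;
            for (int w = 0; w <= nw; ++w) {
                int nb = (w < nw) ? 8 : rem;
                if (nb == 0) break;
                uint64_t valid = ~(load_word(im + off, nb) | load_word(jm + off, nb));
                if (nb < 8) valid &= (nb == 8) ? ~0ULL : ((1ULL << (8 * nb)) - 1);
                uint64_t x1 = (load_word(i1 + off, nb) ^ load_word(j1 + off, nb)) & valid;
                uint64_t x2 = (load_word(i2 + off, nb) ^ load_word(j2 + off, nb)) & valid;
                shared += __builtin_popcountll(valid);
                diff   += __builtin_popcountll(x1) + __builtin_popcountll(x2);
                off += nb;
            }
            mism(i, j) = mism(j, i) = (double)diff;
            nshared(i, j) = nshared(j, i) = (int)shared;
        }
    }
    return List::create(_["mismatch"] = mism, _["n_shared"] = nshared);
}
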