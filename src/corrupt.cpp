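#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Phred+33 quality strings: per-read mean plus per-base Gaussian jitter,
// rounded and clamped to [2, 40]. Uses R's RNG.
// [[Rcpp::export(name = ".phred_strings")]]
CharacterVector phred_strings(IntegerVector lens, NumericVector readMean,
                              double jitterSd) {
    R_xlen_t n = lens.size();
    if (readMean.size() != n) stop("length mismatch");
    CharacterVector out(n);
    RNGScope scope;
    std::string buf;
    for (R_xlen_t k = 0; k < n; ++k) {
        int len = lens[k];
        buf.resize((size_t)len);
        for (int i = 0; i < len; ++i) {
            double q = std::floor(readMean[k] + norm_rand() * jitterSd + 0.5);
            if (q < 2) q = 2;
            if (q > 40) q = 40;
            buf[i] = (char)((int)q + 33);
        }
        out[k] = buf;
    }
    return out;
}

static inline bool is_base(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Apply the 454-style error model to each read: per-base substitutions and
// N calls (one uniform per base against stacked thresholds), then one
// +/-1 length error per homopolymer run of length >= 2, drawn per run.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".corrupt_reads")]]
CharacterVector corrupt_reads(CharacterVector seqs, double subRate,
                              double nRate, double homRate) {
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    RNGScope scope;
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    std::string buf, res;
    for (R_xlen_t k = 0; k < n; ++k) {
        const char *s = CHAR(STRING_ELT(seqs, k));
        size_t len = strlen(s);
        buf.assign(s, len);
        if (subRate > 0 || nRate > 0) {
            for (size_t i = 0; i < len; ++i) {
                double u = unif_rand();
                if (u < subRate) {
                    if (!is_base(buf[i])) continue;
                    // uniform over the three other bases
                    int j = (int)(unif_rand() * 3.0);
                    if (j > 2) j = 2;
                    for (int b = 0; b < 4; ++b) {
                        if (bases[b] == buf[i]) continue;
                        if (j-- == 0) { buf[i] = bases[b]; break; }
                    }
                } else if (u < subRate + nRate) {
                    buf[i] = 'N';
                }
            }
        }
        if (homRate > 0) {
            res.clear();
            res.reserve(len + 8);
            size_t i = 0;
            while (i < len) {
                size_t j = i;
                while (j < len && buf[j] == buf[i]) ++j;
                long run = (long)(j - i);
                if (run >= 2 && is_base(buf[i]) && unif_rand() < homRate)
                    run += (unif_rand() < 0.5) ? -1 : 1;
                res.append((size_t)run, buf[i]);
                i = j;
            }
            out[k] = res;
        } else {
            out[k] = buf;
        }
    }
    return out;
}
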