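#include <Rcpp.h>
using namespace Rcpp;

// Greedy scan: is every character of `shorter[k]` found, in order, inside
// `longer[k]`? Equivalent to LCS(shorter, longer) == nchar(shorter), i.e.
// the two sequences can be aligned with indels only and zero substitutions
// at the minimal indel cost.
// [[Rcpp::export(name = ".is_subsequence")]]
LogicalVector is_subsequence(CharacterVector shorter, CharacterVector longer) {
    R_xlen_t n = shorter.size();
    if (longer.size() != n) stop("length mismatch");
    LogicalVector out(n);
    for (R_xlen_t k = 0; k < n; ++k) {
        const char *s = CHAR(STRING_ELT(shorter, k));
        const char *t = CHAR(STRING_ELT(longer, k));
        while (*s && *t) {
            if (*s == *t) ++s;
            ++t;
        }
        out[k] = (*s == '\0');
    }
    return out;
}
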