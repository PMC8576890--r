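#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Banded local alignment with affine gaps (Smith-Waterman restricted
// to diagonals dmin..dmax, where diagonal d = j - i for pattern
// position i and subject position j, both 1-based). The first base of
// a gap costs gap_open + gap_extend, each further base gap_extend.
//
// Returns score, 1-based end-inclusive coordinates of the aligned
// region on both sequences, column counts (match/mismatch/ins/del;
// "ins" = gap in pattern, "del" = gap in subject) and the gapped
// aligned strings.
// [[Rcpp::export(name = ".bandedLocalAlign")]]
List banded_local_align(std::string pattern, std::string subject,
                        double match, double mismatch,
                        double gap_open, double gap_extend,
                        int dmin, int dmax) {
    const int m = (int) pattern.size();
    const int n = (int) subject.size();
    List empty = List::create(
        _["score"] = 0.0, _["pStart"] = 0, _["pEnd"] = 0,
        _["sStart"] = 0, _["sEnd"] = 0, _["nMatch"] = 0,
        _["nMismatch"] = 0, _["nIns"] = 0, _["nDel"] = 0,
        _["alignedPattern"] = "", _["alignedSubject"] = "");
    if (m == 0 || n == 0) return empty;
    if (dmin > dmax) stop("dmin must be <= dmax");
    dmin = std::max(dmin, 1 - m);
    dmax = std::min(dmax, n - 1);
    if (dmin > dmax) return empty;
    const int w = dmax - dmin + 1;
    const double NEG = -1e30;
    const double go = gap_open + gap_extend;

    std::vector<double> H((size_t)(m + 1) * w, 0.0);
    std::vector<double> E((size_t)(m + 1) * w, NEG);
    std::vector<double> F((size_t)(m + 1) * w, NEG);
    std::vector<unsigned char> TB((size_t)(m + 1) * w, 0);

    double best = 0.0; int bi = -1, bc = -1;
    for (int i = 1; i <= m; ++i) {
        const char pc = pattern[i - 1];
        const size_t row = (size_t) i * w, prow = (size_t)(i - 1) * w;
        for (int c = 0; c < w; ++c) {
            const int j = i + dmin + c;
            if (j < 1 || j > n) { H[row + c] = NEG; continue; }
            // E: gap in pattern, predecessor (i, j-1) at column c-1
            double e = NEG; int de = 0;
            if (c > 0 && j - 1 >= 1) {
                double hprev = H[row + c - 1];
                double fromH = (hprev <= NEG / 2) ? NEG : hprev - go;
                double fromE = E[row + c - 1] - gap_extend;
                if (fromE > fromH) { e = fromE; de = 1; } else e = fromH;
            }
            // F: gap in subject, predecessor (i-1, j) at column c+1
            double f = NEG; int df = 0;
            if (c < w - 1 && i - 1 >= 1 && j <= n) {
                double hprev = H[prow + c + 1];
                double fromH = (hprev <= NEG / 2) ? NEG : hprev - go;
                double fromF = F[prow + c + 1] - gap_extend;
                if (fromF > fromH) { f = fromF; df = 1; } else f = fromH;
            }
            // diagonal predecessor (i-1, j-1) at column c
            double dprev;
            if (i - 1 == 0 || j - 1 == 0) dprev = 0.0;
            else { dprev = H[prow + c]; if (dprev <= NEG / 2) dprev = NEG; }
            double s = (pc == subject[j - 1]) ? match : mismatch;
            double dscore = (dprev <= NEG / 2) ? NEG : dprev + s;

            double h = 0.0; int dh = 0;
            if (dscore > h) { h = dscore; dh = 1; }
            if (e > h) { h = e; dh = 2; }
            if (f > h) { h = f; dh = 3; }
            H[row + c] = h; E[row + c] = e; F[row + c] = f;
            TB[row + c] = (unsigned char)(dh | (de << 2) | (df << 3));
            if (h > best) { best = h; bi = i; bc = c; }
        }
    }
    if (best <= 0.0 || bi < 0) return empty;

    // traceback
    std::string ap, as;
    int i = bi, c = bc;
    int nMatch = 0, nMismatch = 0, nIns = 0, nDel = 0;
    int pEnd = bi, sEnd = bi + dmin + bc, pStart = bi, sStart = sEnd;
    char state = 'H';
    while (true) {
        size_t idx = (size_t) i * w + c;
        int j = i + dmin + c;
        if (state == 'H') {
            if (i <= 0 || j <= 0 || H[idx] <= 0.0) break;
            int dh = TB[idx] & 3;
            if (dh == 1) {
                char a = pattern[i - 1], b = subject[j - 1];
                ap.push_back(a); as.push_back(b);
                if (a == b) ++nMatch; else ++nMismatch;
                pStart = i; sStart = j;
                i -= 1; // c unchanged (j also -1)
            } else if (dh == 2) {
                state = 'E';
            } else if (dh == 3) {
                state = 'F';
            } else {
                break;
            }
        } else if (state == 'E') {
            ap.push_back('-'); as.push_back(subject[j - 1]);
            ++nIns;
            sStart = j;
            int de = (TB[idx] >> 2) & 1;
            c -= 1;
            state = de ? 'E' : 'H';
        } else { // F
            ap.push_back(pattern[i - 1]); as.push_back('-');
            ++nDel;
            pStart = i;
            int df = (TB[idx] >> 3) & 1;
            i -= 1; c += 1;
            state = df ? 'F' : 'H';
        }
    }
    std::reverse(ap.begin(), ap.end());
    std::reverse(as.begin(), as.end());
    return List::create(
        _["score"] = best, _["pStart"] = pStart, _["pEnd"] = pEnd,
        _["sStart"] = sStart, _["sEnd"] = sEnd,
        _["nMatch"] = nMatch, _["nMismatch"] = nMismatch,
        _["nIns"] = nIns, _["nDel"] = nDel,
        _["alignedPattern"] = ap, _["alignedSubject"] = as);
}
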