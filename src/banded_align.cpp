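#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Banded global alignment with affine gaps (three-state Gotoh).
// Gap of length L costs gap_open + gap_ext * L. Cells outside the band are
// unreachable; the band is widened automatically by the length difference so
// the corner cell (n, m) is always reachable.

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_ext,
                      int band) {
    const int n = (int)a.size();
    const int m = (int)b.size();
    const int Wl = band + std::max(0, n - m);
    const int Wr = band + std::max(0, m - n);
    const int width = Wl + Wr + 1;

    auto lo = [&](int i) { return std::max(0, i - Wl); };
    auto hi = [&](int i) { return std::min(m, i + Wr); };

    // score rows (previous + current) per state
    std::vector<double> Mprev(width, NEG_INF), Xprev(width, NEG_INF), Yprev(width, NEG_INF);
    std::vector<double> Mcur(width, NEG_INF), Xcur(width, NEG_INF), Ycur(width, NEG_INF);
    // traceback: predecessor state (0=M,1=X,2=Y, 3=none) per cell per state
    std::vector<unsigned char> Mptr((size_t)(n + 1) * width, 3);
    std::vector<unsigned char> Xptr((size_t)(n + 1) * width, 3);
    std::vector<unsigned char> Yptr((size_t)(n + 1) * width, 3);

    auto idx = [&](int i, int j) { return (size_t)i * width + (j - lo(i)); };

    // row 0
    {
        int l0 = lo(0), h0 = hi(0);
        for (int j = l0; j <= h0; ++j) {
            int k = j - l0;
            if (j == 0) {
                Mprev[k] = 0.0;
            } else {
                Yprev[k] = -(gap_open + gap_ext * j);
                Yptr[idx(0, j)] = (j == 1) ? 0 : 2;
            }
        }
    }

    for (int i = 1; i <= n; ++i) {
        int li = lo(i), hij = hi(i);
        int lp = lo(i - 1), hp = hi(i - 1);
        std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
        std::fill(Xcur.begin(), Xcur.end(), NEG_INF);
        std::fill(Ycur.begin(), Ycur.end(), NEG_INF);

        auto prevM = [&](int j) { return (j >= lp && j <= hp) ? Mprev[j - lp] : NEG_INF; };
        auto prevX = [&](int j) { return (j >= lp && j <= hp) ? Xprev[j - lp] : NEG_INF; };
        auto prevY = [&](int j) { return (j >= lp && j <= hp) ? Yprev[j - lp] : NEG_INF; };

        for (int j = li; j <= hij; ++j) {
            int k = j - li;
            // X: gap in b (consume a[i-1])
            {
                double fromM = prevM(j) - (gap_open + gap_ext);
                double fromX = prevX(j) - gap_ext;
                double fromY = prevY(j) - (gap_open + gap_ext);
                double best = fromM; unsigned char p = 0;
                if (fromX > best) { best = fromX; p = 1; }
                if (fromY > best) { best = fromY; p = 2; }
                if (best > NEG_INF / 2) { Xcur[k] = best; Xptr[idx(i, j)] = p; }
            }
            if (j > 0) {
                // M: align a[i-1] with b[j-1]
                double s = (a[(size_t)i - 1] == b[(size_t)j - 1]) ? match : mismatch;
                double dM = prevM(j - 1), dX = prevX(j - 1), dY = prevY(j - 1);
                double best = dM; unsigned char p = 0;
                if (dX > best) { best = dX; p = 1; }
                if (dY > best) { best = dY; p = 2; }
                if (best > NEG_INF / 2) { Mcur[k] = best + s; Mptr[idx(i, j)] = p; }
                // Y: gap in a (consume b[j-1]) -- horizontal, same row
                double hM = (j - 1 >= li) ? Mcur[k - 1] : NEG_INF;
                double hX = (j - 1 >= li) ? Xcur[k - 1] : NEG_INF;
                double hY = (j - 1 >= li) ? Ycur[k - 1] : NEG_INF;
                double fromM = hM - (gap_open + gap_ext);
                double fromX = hX - (gap_open + gap_ext);
                double fromY = hY - gap_ext;
                double bestY = fromM; unsigned char pY = 0;
                if (fromX > bestY) { bestY = fromX; pY = 1; }
                if (fromY > bestY) { bestY = fromY; pY = 2; }
                if (bestY > NEG_INF / 2) { Ycur[k] = bestY; Yptr[idx(i, j)] = pY; }
            }
        }
        std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
    }

    // final cell
    int lf = lo(n);
    double sM = Mprev[m - lf], sX = Xprev[m - lf], sY = Yprev[m - lf];
    int state = 0; double score = sM;
    if (sX > score) { score = sX; state = 1; }
    if (sY > score) { score = sY; state = 2; }

    // traceback
    std::string ra, rb;
    ra.reserve(n + m); rb.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
        if (state == 0) {
            unsigned char p = Mptr[idx(i, j)];
            ra.push_back(a[(size_t)i - 1]); rb.push_back(b[(size_t)j - 1]);
            --i; --j; state = p;
        } else if (state == 1) {
            unsigned char p = Xptr[idx(i, j)];
            ra.push_back(a[(size_t)i - 1]); rb.push_back('-');
            --i; state = p;
        } else {
            unsigned char p = Yptr[idx(i, j)];
            ra.push_back('-'); rb.push_back(b[(size_t)j - 1]);
            --j; state = p;
        }
        if (i == 0 && j > 0) state = 2;
        if (j == 0 && i > 0) state = 1;
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());

    return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score);
}
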