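#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman with Gotoh recurrences).
// A gap of length L costs gap_open + L * gap_extend on either sequence.
// Sequences arrive as 0-based integer codes into the scoring matrix.
//
// Traceback state codes: 0 = stop (local start), 1 = diagonal, 2 = gap in
// target (consume query, E), 3 = gap in query (consume target, F).

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector t, NumericMatrix mat,
                  double gap_open, double gap_extend) {
    const int m = q.size(), n = t.size();
    const double go = gap_open + gap_extend;  // cost of opening a length-1 gap
    const double ge = gap_extend;

    // Full DP with per-cell traceback. Rows = query (m), cols = target (n).
    std::vector<double> H((m + 1) * (n + 1), 0.0);
    std::vector<double> E((m + 1) * (n + 1), NEG_INF);  // gap in target (up)
    std::vector<double> F((m + 1) * (n + 1), NEG_INF);  // gap in query (left)
    std::vector<unsigned char> TH((m + 1) * (n + 1), 0);
    std::vector<unsigned char> TE((m + 1) * (n + 1), 0);  // 1 = open, 0 = extend
    std::vector<unsigned char> TF((m + 1) * (n + 1), 0);

    double best = 0.0;
    int bi = 0, bj = 0;
    const int W = n + 1;

    for (int i = 1; i <= m; ++i) {
        const int qi = q[i - 1];
        for (int j = 1; j <= n; ++j) {
            const int idx = i * W + j;
            // E: gap in target (query residue aligned to nothing)
            double e_open = H[(i - 1) * W + j] - go;
            double e_ext  = E[(i - 1) * W + j] - ge;
            if (e_open >= e_ext) { E[idx] = e_open; TE[idx] = 1; }
            else                 { E[idx] = e_ext;  TE[idx] = 0; }
            // F: gap in query
            double f_open = H[i * W + (j - 1)] - go;
            double f_ext  = F[i * W + (j - 1)] - ge;
            if (f_open >= f_ext) { F[idx] = f_open; TF[idx] = 1; }
            else                 { F[idx] = f_ext;  TF[idx] = 0; }
            // H
            double diag = H[(i - 1) * W + (j - 1)] + mat(qi, t[j - 1]);
            double h = 0.0; unsigned char tb = 0;
            if (diag > h)   { h = diag;   tb = 1; }
            if (E[idx] > h) { h = E[idx]; tb = 2; }
            if (F[idx] > h) { h = F[idx]; tb = 3; }
            H[idx] = h; TH[idx] = tb;
            // Track max; strictly greater keeps the earliest (smallest target
            // end, then smallest query end) cell: deterministic tie-break.
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }

    if (best <= 0.0) {
        return List::create(_["score"] = 0.0,
                            _["q_start"] = 0, _["q_end"] = 0,
                            _["t_start"] = 0, _["t_end"] = 0,
                            _["q_aln"] = IntegerVector(0),
                            _["t_aln"] = IntegerVector(0));
    }

    // Traceback from (bi, bj) until a zero cell; build aligned index vectors
    // (-1 marks a gap position).
    std::vector<int> qa, ta;
    int i = bi, j = bj;
    int state = 1;  // start in H
    while (i > 0 && j > 0) {
        const int idx = i * W + j;
        if (state == 1) {
            unsigned char tb = TH[idx];
            if (tb == 0) break;
            if (tb == 1) { qa.push_back(q[i - 1]); ta.push_back(t[j - 1]); --i; --j; }
            else state = tb;  // move into E (2) or F (3)
        } else if (state == 2) {
            qa.push_back(q[i - 1]); ta.push_back(-1);
            unsigned char open = TE[idx];
            --i;
            if (open) state = 1;
        } else {
            qa.push_back(-1); ta.push_back(t[j - 1]);
            unsigned char open = TF[idx];
            --j;
            if (open) state = 1;
        }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(ta.begin(), ta.end());

    return List::create(_["score"] = best,
                        _["q_start"] = i, _["q_end"] = bi,
                        _["t_start"] = j, _["t_end"] = bj,
                        _["q_aln"] = IntegerVector(qa.begin(), qa.end()),
                        _["t_aln"] = IntegerVector(ta.begin(), ta.end()));
}

// Score-only variant for classification (no traceback matrices kept).
// [[Rcpp::export(name = ".sw_score_cpp")]]
double sw_score_cpp(IntegerVector q, IntegerVector t, NumericMatrix mat,
                    double gap_open, double gap_extend) {
    const int m = q.size(), n = t.size();
    const double go = gap_open + gap_extend;
    const double ge = gap_extend;
    std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
    std::vector<double> Eprev(n + 1, NEG_INF), Ecur(n + 1, NEG_INF);
    double best = 0.0;
    for (int i = 1; i <= m; ++i) {
        const int qi = q[i - 1];
        double f = NEG_INF;
        Hcur[0] = 0.0; Ecur[0] = NEG_INF;
        for (int j = 1; j <= n; ++j) {
            double e = std::max(Hprev[j] - go, Eprev[j] - ge);
            f = std::max(Hcur[j - 1] - go, f - ge);
            double h = Hprev[j - 1] + mat(qi, t[j - 1]);
            if (e > h) h = e;
            if (f > h) h = f;
            if (h < 0.0) h = 0.0;
            Hcur[j] = h; Ecur[j] = e;
            if (h > best) best = h;
        }
        std::swap(Hprev, Hcur); std::swap(Eprev, Ecur);
    }
    return best;
}

// Rolling-array endpoint finder: best local score plus its (q,t) end, then
// a reverse pass recovers the start. No traceback matrices, so screening
// long frame translations stays memory-light.
static void sw_best_end(const int* q, int m, const int* t, int n,
                        const double* M, int nr, double go, double ge,
                        double& best, int& bi, int& bj) {
    std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
    std::vector<double> Eprev(n + 1, NEG_INF), Ecur(n + 1, NEG_INF);
    best = 0.0; bi = 0; bj = 0;
    for (int i = 1; i <= m; ++i) {
        const double* mrow = M + q[i - 1];
        double f = NEG_INF;
        Hcur[0] = 0.0; Ecur[0] = NEG_INF;
        for (int j = 1; j <= n; ++j) {
            double e = std::max(Hprev[j] - go, Eprev[j] - ge);
            f = std::max(Hcur[j - 1] - go, f - ge);
            double h = Hprev[j - 1] + mrow[(size_t)nr * t[j - 1]];
            if (e > h) h = e;
            if (f > h) h = f;
            if (h < 0.0) h = 0.0;
            Hcur[j] = h; Ecur[j] = e;
            if (h > best) { best = h; bi = i; bj = j; }
        }
        std::swap(Hprev, Hcur); std::swap(Eprev, Ecur);
    }
}

// [[Rcpp::export(name = ".sw_endpoints_cpp")]]
List sw_endpoints_cpp(IntegerVector q, IntegerVector t, NumericMatrix mat,
                      double gap_open, double gap_extend) {
    const int m = q.size(), n = t.size();
    const double go = gap_open + gap_extend, ge = gap_extend;
    const double* M = mat.begin();
    const int nr = mat.nrow();
    double best; int bi, bj;
    sw_best_end(&q[0], m, &t[0], n, M, nr, go, ge, best, bi, bj);
    if (best <= 0.0)
        return List::create(_["score"] = 0.0, _["q_start"] = 0,
                            _["q_end"] = 0, _["t_start"] = 0,
                            _["t_end"] = 0);
    // reverse pass over the prefixes ending at (bi, bj)
    std::vector<int> qr(bi), tr(bj);
    for (int i = 0; i < bi; ++i) qr[i] = q[bi - 1 - i];
    for (int j = 0; j < bj; ++j) tr[j] = t[bj - 1 - j];
    double best2; int ri, rj;
    sw_best_end(qr.data(), bi, tr.data(), bj, M, nr, go, ge, best2, ri, rj);
    return List::create(_["score"] = best,
                        _["q_start"] = bi - ri, _["q_end"] = bi,
                        _["t_start"] = bj - rj, _["t_end"] = bj);
}
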