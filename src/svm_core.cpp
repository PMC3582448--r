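#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

// RBF kernel matrix between rows of A (na x d) and rows of B (nb x d).
static inline double rbf(const double *a, const double *b, int d, double gamma) {
    double s = 0.0;
    for (int k = 0; k < d; ++k) {
        double diff = a[k] - b[k];
        s += diff * diff;
    }
    return std::exp(-gamma * s);
}

// [[Rcpp::export(name = ".rbf_kernel")]]
NumericMatrix rbf_kernel(NumericMatrix A, NumericMatrix B, double gamma) {
    int na = A.nrow(), nb = B.nrow(), d = A.ncol();
    if (B.ncol() != d) stop("dimension mismatch in kernel computation");
    // column-major: copy rows into contiguous buffers
    std::vector<double> av(na * d), bv(nb * d);
    for (int i = 0; i < na; ++i)
        for (int k = 0; k < d; ++k) av[i * d + k] = A(i, k);
    for (int j = 0; j < nb; ++j)
        for (int k = 0; k < d; ++k) bv[j * d + k] = B(j, k);
    NumericMatrix K(na, nb);
    for (int j = 0; j < nb; ++j)
        for (int i = 0; i < na; ++i)
            K(i, j) = rbf(&av[i * d], &bv[j * d], d, gamma);
    return K;
}

// C-SVC dual solver: sequential minimal optimization with maximal-violating-pair
// working-set selection (Fan, Chen & Lin 2005, WSS1), identical stopping rule to
// LIBSVM at tolerance eps. Returns alpha (box-constrained duals) and rho so that
// the decision value is f(x) = sum_i alpha_i y_i K(x_i, x) - rho.
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix X, IntegerVector y, double C, double gamma,
               double eps, int max_iter) {
    int n = X.nrow(), d = X.ncol();
    if (y.size() != n) stop("label/feature length mismatch");

    std::vector<double> xv(n * d);
    for (int i = 0; i < n; ++i)
        for (int k = 0; k < d; ++k) xv[i * d + k] = X(i, k);

    // full kernel matrix; n is capped upstream by the grid-search subsample
    std::vector<double> K((size_t)n * n);
    for (int i = 0; i < n; ++i) {
        K[(size_t)i * n + i] = 1.0; // exp(0)
        for (int j = i + 1; j < n; ++j) {
            double k = rbf(&xv[i * d], &xv[j * d], d, gamma);
            K[(size_t)i * n + j] = k;
            K[(size_t)j * n + i] = k;
        }
    }

    std::vector<double> alpha(n, 0.0), G(n, -1.0); // gradient of the dual
    const double TAU = 1e-12;
    int iter = 0;
    bool converged = false;

    while (iter < max_iter) {
        // working-set selection: maximal violating pair
        int i = -1, j = -1;
        double Gmax = -INFINITY, Gmin = INFINITY;
        for (int t = 0; t < n; ++t) {
            double v = -y[t] * G[t];
            bool in_up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
            bool in_low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
            if (in_up && v > Gmax) { Gmax = v; i = t; }
            if (in_low && v < Gmin) { Gmin = v; j = t; }
        }
        if (i < 0 || j < 0 || Gmax - Gmin < eps) { converged = true; break; }

        const double *Ki = &K[(size_t)i * n];
        const double *Kj = &K[(size_t)j * n];
        double old_ai = alpha[i], old_aj = alpha[j];

        if (y[i] != y[j]) {
            double quad = Ki[i] + Kj[j] + 2.0 * Ki[j];
            if (quad <= 0) quad = TAU;
            double delta = (-G[i] - G[j]) / quad;
            double diff = alpha[i] - alpha[j];
            alpha[i] += delta;
            alpha[j] += delta;
            if (diff > 0) {
                if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
            } else {
                if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
            }
            if (diff > 0) {
                if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
            } else {
                if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
            }
        } else {
            double quad = Ki[i] + Kj[j] - 2.0 * Ki[j];
            if (quad <= 0) quad = TAU;
            double delta = (G[i] - G[j]) / quad;
            double sum = alpha[i] + alpha[j];
            alpha[i] -= delta;
            alpha[j] += delta;
            if (sum > C) {
                if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
            } else {
                if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
            }
            if (sum > C) {
                if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
            } else {
                if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
            }
        }

        double dai = y[i] * (alpha[i] - old_ai);
        double daj = y[j] * (alpha[j] - old_aj);
        for (int t = 0; t < n; ++t)
            G[t] += y[t] * (Ki[t] * dai + Kj[t] * daj);
        ++iter;
    }

    // rho as in LIBSVM: average y_i * G_i over free support vectors,
    // midpoint of the bound interval otherwise
    double ub = INFINITY, lb = -INFINITY, sum_free = 0.0;
    int n_free = 0;
    for (int t = 0; t < n; ++t) {
        double yG = y[t] * G[t];
        if (alpha[t] >= C) {
            if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
        } else if (alpha[t] <= 0) {
            if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
        } else {
            ++n_free;
            sum_free += yG;
        }
    }
    double rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;

    return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                        _["rho"] = rho,
                        _["iterations"] = iter,
                        _["converged"] = converged);
}

// Longest ORF: ATG through first in-frame stop (stop included), any of the three
// forward frames of the already 5'->3' oriented transcript. A codon containing N
// aborts the candidate. Ties go to the 5'-most start. Returns 0-based start and
// exclusive end, or found = FALSE.
// [[Rcpp::export(name = ".longest_orf")]]
List longest_orf(std::string seq) {
    int n = (int)seq.size();
    int best_start = -1, best_len = 0;
    // per frame: classify each in-frame codon once, then sweep starts
    for (int f = 0; f < 3; ++f) {
        int open_start = -1; // current candidate ATG (5'-most open one)
        for (int p = f; p + 3 <= n; p += 3) {
            char a = seq[p], b = seq[p + 1], c = seq[p + 2];
            bool has_n = (a == 'N' || b == 'N' || c == 'N');
            bool is_stop = !has_n &&
                ((a == 'T' && b == 'A' && (c == 'A' || c == 'G')) ||
                 (a == 'T' && b == 'G' && c == 'A'));
            bool is_atg = (a == 'A' && b == 'T' && c == 'G');
            if (has_n) {
                open_start = -1; // invalidates every candidate crossing this codon
            } else if (is_stop) {
                if (open_start >= 0) {
                    int len = p + 3 - open_start;
                    if (len > best_len ||
                        (len == best_len && open_start < best_start)) {
                        best_len = len;
                        best_start = open_start;
                    }
                    open_start = -1;
                }
            } else if (is_atg && open_start < 0) {
                // a later in-frame ATG before the same stop is always shorter
                open_start = p;
            }
        }
    }
    if (best_start < 0)
        return List::create(_["found"] = false, _["start"] = NA_INTEGER,
                            _["end"] = NA_INTEGER, _["length_nt"] = 0);
    return List::create(_["found"] = true, _["start"] = best_start,
                        _["end"] = best_start + best_len,
                        _["length_nt"] = best_len);
}
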