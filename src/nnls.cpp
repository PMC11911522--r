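// Active-set non-negative least squares on normal equations
// (Lawson & Hanson / fast-combinatorial style: the Gram matrix is shared
// across all right-hand sides), plus the alternating constrained
// least-squares factorization loop built on it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve min ||A x - b||^2 s.t. x >= 0 given AtA = A'A and Atb = A'b.
// k is small (number of cell types), so the active-set loop is cheap.
static vec nnls_gram_single(const mat& AtA, const vec& Atb)
{
    const uword k = AtA.n_rows;
    vec x(k, fill::zeros);
    uvec passive(k, fill::zeros); // 1 = in passive (free) set
    vec w = Atb;                  // gradient: Atb - AtA x (x = 0)

    const double tol = 1e-12 * std::max(1.0, abs(Atb).max());
    const uword max_outer = 3 * k + 30;

    for (uword outer = 0; outer < max_outer; ++outer) {
        // most violated zero coordinate
        double wmax = tol;
        sword jmax = -1;
        for (uword j = 0; j < k; ++j)
            if (!passive(j) && w(j) > wmax) { wmax = w(j); jmax = j; }
        if (jmax < 0) break;
        passive(jmax) = 1;

        for (uword inner = 0; inner < max_outer; ++inner) {
            uvec P = find(passive == 1);
            vec s;
            bool ok = solve(s, AtA.submat(P, P), Atb.elem(P),
                            solve_opts::likely_sympd + solve_opts::no_approx);
            if (!ok) // degenerate subproblem: tiny ridge
                s = solve(AtA.submat(P, P) +
                          1e-10 * eye(P.n_elem, P.n_elem), Atb.elem(P));
            if (s.min() > 0) {
                x.zeros();
                x.elem(P) = s;
                break;
            }
            // step toward s until the first passive coordinate hits zero
            double alpha = datum::inf;
            for (uword i = 0; i < P.n_elem; ++i)
                if (s(i) <= 0) {
                    double a = x(P(i)) / (x(P(i)) - s(i));
                    if (a < alpha) alpha = a;
                }
            for (uword i = 0; i < P.n_elem; ++i)
                x(P(i)) += alpha * (s(i) - x(P(i)));
            for (uword i = 0; i < P.n_elem; ++i)
                if (x(P(i)) <= 1e-14) { x(P(i)) = 0; passive(P(i)) = 0; }
        }
        w = Atb - AtA * x;
    }
    return x;
}

// [[Rcpp::export(name = ".nnlsGram")]]
arma::mat nnls_gram(const arma::mat& AtA, const arma::mat& AtB)
{
    mat X(AtA.n_rows, AtB.n_cols);
    for (uword j = 0; j < AtB.n_cols; ++j)
        X.col(j) = nnls_gram_single(AtA, AtB.col(j));
    return X;
}

// [[Rcpp::export(name = ".nnlsMulti")]]
arma::mat nnls_multi(const arma::mat& A, const arma::mat& B)
{
    return nnls_gram(A.t() * A, A.t() * B);
}

// Alternating constrained least squares: Y ~ M H with M >= 0 and H
// column-stochastic. H-update solves, per spot, an NNLS with a weighted
// sum-to-one row appended, then renormalizes exactly; M-update is exact
// row-wise NNLS. Exits when the iteration count reaches max_iter or
// ||Y - MH||_F <= tol.
// [[Rcpp::export(name = ".deconfCore")]]
Rcpp::List deconf_core(const arma::mat& Y, const arma::mat& H0,
                       const int max_iter, const double tol,
                       const double sum_weight, const bool sum_to_one)
{
    const uword K = H0.n_rows, S = Y.n_cols;
    mat H = H0, M;
    std::vector<double> trace;
    trace.reserve(max_iter);
    double err = datum::inf;
    int it = 0, nreinit = 0;
    bool converged = false;

    for (it = 0; it < max_iter; ++it) {
        // M-update: rows of M from NNLS on H H' (given current H)
        mat HHt = H * H.t();
        M = nnls_gram(HHt, H * Y.t()).t(); // L x K

        // guard: a type column of M collapsed to zero -> tiny uniform mass
        for (uword k = 0; k < K; ++k)
            if (accu(M.col(k)) == 0) { M.col(k).fill(1e-8); ++nreinit; }

        if (sum_to_one) {
            // H-update with weighted sum-to-one row
            double w = sum_weight * std::sqrt(accu(square(M)) / K);
            mat AtA = M.t() * M + (w * w) * ones(K, K);
            mat AtB = M.t() * Y + (w * w) * ones(K, S);
            H = nnls_gram(AtA, AtB);

            // exact renormalization (and rank-collapse guard)
            for (uword k = 0; k < K; ++k)
                if (accu(H.row(k)) == 0) { H.row(k).fill(1e-8); ++nreinit; }
            rowvec cs = sum(H, 0);
            for (uword j = 0; j < S; ++j) {
                if (cs(j) <= 0) { H.col(j).fill(1.0 / K); ++nreinit; }
                else H.col(j) /= cs(j);
            }
        } else {
            // plain non-negative H (model-order stage)
            H = nnls_gram(M.t() * M, M.t() * Y);
            for (uword k = 0; k < K; ++k)
                if (accu(H.row(k)) == 0) { H.row(k).fill(1e-8); ++nreinit; }
        }

        err = norm(Y - M * H, "fro");
        trace.push_back(err);
        if (err <= tol) { converged = true; ++it; break; }
    }

    return Rcpp::List::create(
        Rcpp::Named("M") = M, Rcpp::Named("H") = H,
        Rcpp::Named("errTrace") = trace, Rcpp::Named("nIter") = it,
        Rcpp::Named("frobErr") = err, Rcpp::Named("converged") = converged,
        Rcpp::Named("nReinit") = nreinit);
}
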