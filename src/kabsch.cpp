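#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Optimal rotation R (row-vector convention: aligned = Xc * R + yc) maximising
// tr(R^T C) with C = Xc^T W Yc, det(R) = +1 enforced via the smallest singular value.
static void kabsch_core(const mat& X, const mat& Y, const vec& w, double wsum,
                        mat& R, rowvec& xc, rowvec& yc, double& rmsd) {
    xc = (w.t() * X) / wsum;
    yc = (w.t() * Y) / wsum;
    mat Xc = X.each_row() - xc;
    mat Yc = Y.each_row() - yc;
    mat C = Xc.t() * (Yc.each_col() % w);
    mat U, V;
    vec s;
    svd(U, s, V, C);
    double d = det(U) * det(V);
    vec sgn = {1.0, 1.0, d < 0 ? -1.0 : 1.0};
    R = U * diagmat(sgn) * V.t();
    // residual-based RMSD (the trace formula suffers cancellation for
    // near-exact rigid motions)
    mat D = Xc * R - Yc;
    rmsd = std::sqrt(dot(w, sum(D % D, 1)) / wsum);
}

// [[Rcpp::export]]
double kabschRmsdCpp(const arma::mat& X, const arma::mat& Y, const arma::vec& w) {
    mat R;
    rowvec xc, yc;
    double rmsd;
    kabsch_core(X, Y, w, accu(w), R, xc, yc, rmsd);
    return rmsd;
}

// Condensed (lower-triangle, column-major as in stats::dist) pairwise
// superposition-minimised weighted RMSD over the F slices of an N x 3 x F cube.
// [[Rcpp::export]]
arma::vec pairwiseRmsdCpp(const arma::cube& frames, const arma::vec& w) {
    const uword F = frames.n_slices;
    const double wsum = accu(w);
    vec out(F * (F - 1) / 2);
    uword idx = 0;
    mat R;
    rowvec xc, yc;
    double rmsd;
    for (uword i = 0; i < F - 1; ++i) {
        const mat Xi = frames.slice(i);
        for (uword j = i + 1; j < F; ++j) {
            kabsch_core(frames.slice(j), Xi, w, wsum, R, xc, yc, rmsd);
            out(idx++) = rmsd;
        }
    }
    return out;
}

// Superpose every frame onto ref (weighted Kabsch); returns the aligned cube.
// [[Rcpp::export]]
arma::cube alignFramesCpp(const arma::cube& frames, const arma::mat& ref,
                          const arma::vec& w) {
    const uword F = frames.n_slices;
    const double wsum = accu(w);
    cube out(arma::size(frames));
    mat R;
    rowvec xc, yc;
    double rmsd;
    for (uword t = 0; t < F; ++t) {
        kabsch_core(frames.slice(t), ref, w, wsum, R, xc, yc, rmsd);
        mat Xc = frames.slice(t).each_row() - xc;
        out.slice(t) = Xc * R;
        out.slice(t).each_row() += yc;
    }
    return out;
}

// Per-frame RMSD series: fit on fit-atom rows, report weighted RMSD over
// report-atom rows (indices 1-based from R).
// [[Rcpp::export]]
arma::vec rmsdSeriesCpp(const arma::cube& frames, const arma::mat& ref,
                        const arma::uvec& fitIdx, const arma::uvec& reportIdx,
                        const arma::vec& wFit, const arma::vec& wRep) {
    const uword F = frames.n_slices;
    const uvec fi = fitIdx - 1, ri = reportIdx - 1;
    const mat refFit = ref.rows(fi), refRep = ref.rows(ri);
    const double wsumFit = accu(wFit), wsumRep = accu(wRep);
    vec out(F);
    mat R;
    rowvec xc, yc;
    double rmsd;
    for (uword t = 0; t < F; ++t) {
        mat Xf = frames.slice(t).rows(fi);
        kabsch_core(Xf, refFit, wFit, wsumFit, R, xc, yc, rmsd);
        mat Xr = frames.slice(t).rows(ri);
        Xr.each_row() -= xc;
        Xr = Xr * R;
        Xr.each_row() += yc;
        mat D = Xr - refRep;
        out(t) = std::sqrt(dot(wRep, sum(D % D, 1)) / wsumRep);
    }
    return out;
}
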