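// EEM linear-system assembly and solvers, plus the cell-grid spatial index
// backing the fragment (cutoff / cover) approximations.
//
// Unknowns of the full system are the N partial charges plus the equalized
// molecular electronegativity chi_bar; the last row carries the total-charge
// constraint sum(q) = Q.

#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double kDegenerateDist = 1e-4; // Angstrom; below this two atoms
                                            // are treated as coincident

// ---------------------------------------------------------------------------
// Dense EEM solve over a member subset, templated on the storage type so the
// 32-bit mode genuinely assembles and factorizes in single precision.
// ---------------------------------------------------------------------------
template <typename eT>
static arma::Col<eT> solve_members(const arma::mat& X,
                                   const arma::vec& Apar,
                                   const arma::vec& Bpar,
                                   double kappa,
                                   double Qfrag,
                                   const arma::uvec& members,
                                   eT& chi_bar)
{
    const arma::uword m = members.n_elem;
    arma::Mat<eT> coords(m, 3);
    for (arma::uword i = 0; i < m; ++i) {
        coords(i, 0) = static_cast<eT>(X(members(i), 0));
        coords(i, 1) = static_cast<eT>(X(members(i), 1));
        coords(i, 2) = static_cast<eT>(X(members(i), 2));
    }

    arma::Mat<eT> M(m + 1, m + 1, arma::fill::zeros);
    arma::Col<eT> b(m + 1);
    const eT k = static_cast<eT>(kappa);

    for (arma::uword i = 0; i < m; ++i) {
        M(i, i) = static_cast<eT>(Bpar(members(i)));
        b(i)    = static_cast<eT>(-Apar(members(i)));
        for (arma::uword j = i + 1; j < m; ++j) {
            const eT dx = coords(i, 0) - coords(j, 0);
            const eT dy = coords(i, 1) - coords(j, 1);
            const eT dz = coords(i, 2) - coords(j, 2);
            const eT r  = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (r < static_cast<eT>(kDegenerateDist)) {
                stop("degenerate geometry: atoms %d and %d are closer than %g Angstrom",
                     (int)(members(i) + 1), (int)(members(j) + 1), kDegenerateDist);
            }
            M(i, j) = k / r;
            M(j, i) = M(i, j);
        }
        M(i, m) = static_cast<eT>(-1);
        M(m, i) = static_cast<eT>(1);
    }
    M(m, m) = 0;
    b(m) = static_cast<eT>(Qfrag);

    arma::Col<eT> sol;
    const bool ok = arma::solve(sol, M, b, arma::solve_opts::no_approx);
    if (!ok) {
        const double rc = arma::rcond(arma::conv_to<arma::mat>::from(M));
        stop("EEM system is singular or too ill-conditioned to solve (reciprocal condition number %g)", rc);
    }
    chi_bar = sol(m);
    arma::Col<eT> q = sol.head(m);
    return q;
}

// [[Rcpp::export]]
List cpp_solve_full(const arma::mat& X,
                    const arma::vec& Apar,
                    const arma::vec& Bpar,
                    double kappa,
                    double total_charge,
                    bool single_precision)
{
    const arma::uword n = X.n_rows;
    arma::uvec members = arma::regspace<arma::uvec>(0, n - 1);
    arma::vec q(n);
    double chi;
    if (single_precision) {
        float chif;
        arma::fvec qf = solve_members<float>(X, Apar, Bpar, kappa, total_charge, members, chif);
        q = arma::conv_to<arma::vec>::from(qf);
        chi = static_cast<double>(chif);
    } else {
        q = solve_members<double>(X, Apar, Bpar, kappa, total_charge, members, chi);
    }
    return List::create(_["q"] = q, _["chi_bar"] = chi);
}

// ---------------------------------------------------------------------------
// Uniform cell grid (cell edge = radius, 27-cell neighborhood scan).
// ---------------------------------------------------------------------------
struct CellGrid {
    double edge;
    double ox, oy, oz;
    int nx, ny, nz;
    std::vector< std::vector<int> > cells;

    CellGrid(const arma::mat& X, double cell_edge) : edge(cell_edge) {
        ox = X.col(0).min(); oy = X.col(1).min(); oz = X.col(2).min();
        nx = (int)std::floor((X.col(0).max() - ox) / edge) + 1;
        ny = (int)std::floor((X.col(1).max() - oy) / edge) + 1;
        nz = (int)std::floor((X.col(2).max() - oz) / edge) + 1;
        cells.resize((size_t)nx * ny * nz);
        for (arma::uword i = 0; i < X.n_rows; ++i)
            cells[index_of(X(i, 0), X(i, 1), X(i, 2))].push_back((int)i);
    }
    size_t index_of(double x, double y, double z) const {
        int cx = std::min(nx - 1, (int)std::floor((x - ox) / edge));
        int cy = std::min(ny - 1, (int)std::floor((y - oy) / edge));
        int cz = std::min(nz - 1, (int)std::floor((z - oz) / edge));
        return ((size_t)cx * ny + cy) * nz + cz;
    }
    // all atoms within `radius` (inclusive) of atom `center`, sorted ascending
    std::vector<int> neighbors(const arma::mat& X, int center, double radius) const {
        std::vector<int> out;
        const double r2 = radius * radius;
        const double x = X(center, 0), y = X(center, 1), z = X(center, 2);
        int cx = std::min(nx - 1, (int)std::floor((x - ox) / edge));
        int cy = std::min(ny - 1, (int)std::floor((y - oy) / edge));
        int cz = std::min(nz - 1, (int)std::floor((z - oz) / edge));
        for (int dx = -1; dx <= 1; ++dx) {
            if (cx + dx < 0 || cx + dx >= nx) continue;
            for (int dy = -1; dy <= 1; ++dy) {
                if (cy + dy < 0 || cy + dy >= ny) continue;
                for (int dz = -1; dz <= 1; ++dz) {
                    if (cz + dz < 0 || cz + dz >= nz) continue;
                    const std::vector<int>& cell =
                        cells[((size_t)(cx + dx) * ny + (cy + dy)) * nz + (cz + dz)];
                    for (int j : cell) {
                        const double ddx = X(j, 0) - x, ddy = X(j, 1) - y, ddz = X(j, 2) - z;
                        if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) out.push_back(j);
                    }
                }
            }
        }
        std::sort(out.begin(), out.end());
        return out;
    }
};

// [[Rcpp::export]]
IntegerVector cpp_neighbors_within(const arma::mat& X, int center1, double radius)
{
    CellGrid grid(X, radius);
    std::vector<int> nb = grid.neighbors(X, center1 - 1, radius);
    IntegerVector out(nb.size());
    for (size_t i = 0; i < nb.size(); ++i) out[i] = nb[i] + 1;
    return out;
}

// Greedy cover-center selection: scan atoms in input order; an atom becomes a
// center unless it already lies within the assignment radius (radius / 2) of
// an existing center. Every atom is then assigned to its nearest center
// (ties -> lower center index).
// [[Rcpp::export]]
List cpp_cover_centers(const arma::mat& X, double radius)
{
    const int n = (int)X.n_rows;
    const double ra = radius / 2.0;
    CellGrid grid(X, ra);
    std::vector<bool> is_center(n, false);
    std::vector<int> centers;
    for (int i = 0; i < n; ++i) {
        bool covered = false;
        std::vector<int> nb = grid.neighbors(X, i, ra);
        for (int j : nb) if (is_center[j]) { covered = true; break; }
        if (!covered) { is_center[i] = true; centers.push_back(i); }
    }
    // nearest center per atom; every atom has a center within ra, and all
    // centers within ra of an atom fall inside its 27-cell scan
    IntegerVector assignment(n);
    std::vector<int> center_rank(n, -1);
    for (size_t k = 0; k < centers.size(); ++k) center_rank[centers[k]] = (int)k;
    for (int i = 0; i < n; ++i) {
        std::vector<int> nb = grid.neighbors(X, i, ra);
        double best = -1.0; int best_c = -1;
        for (int j : nb) {
            if (!is_center[j]) continue;
            const double dx = X(j, 0) - X(i, 0), dy = X(j, 1) - X(i, 1), dz = X(j, 2) - X(i, 2);
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (best_c < 0 || d2 < best || (d2 == best && j < best_c)) { best = d2; best_c = j; }
        }
        assignment[i] = center_rank[best_c] + 1; // 1-based index into centers
    }
    IntegerVector centers_out(centers.size());
    for (size_t k = 0; k < centers.size(); ++k) centers_out[k] = centers[k] + 1;
    return List::create(_["centers"] = centers_out, _["assignment"] = assignment);
}

// unconstrained embedded solve used by the refinement stage:
// (diag(B) + K_frag) q = chi_est - A - phi_ext
template <typename eT>
static arma::Col<eT> solve_members_embedded(const arma::mat& X,
                                            const arma::vec& Apar,
                                            const arma::vec& Bpar,
                                            double kappa,
                                            double chi_est,
                                            const arma::vec& phi_ext,
                                            const arma::uvec& members)
{
    const arma::uword m = members.n_elem;
    arma::Mat<eT> coords(m, 3);
    for (arma::uword i = 0; i < m; ++i) {
        coords(i, 0) = static_cast<eT>(X(members(i), 0));
        coords(i, 1) = static_cast<eT>(X(members(i), 1));
        coords(i, 2) = static_cast<eT>(X(members(i), 2));
    }
    arma::Mat<eT> M(m, m, arma::fill::zeros);
    arma::Col<eT> b(m);
    const eT k = static_cast<eT>(kappa);
    for (arma::uword i = 0; i < m; ++i) {
        M(i, i) = static_cast<eT>(Bpar(members(i)));
        b(i) = static_cast<eT>(chi_est - Apar(members(i)) - phi_ext(i));
        for (arma::uword j = i + 1; j < m; ++j) {
            const eT dx = coords(i, 0) - coords(j, 0);
            const eT dy = coords(i, 1) - coords(j, 1);
            const eT dz = coords(i, 2) - coords(j, 2);
            const eT r = std::sqrt(dx * dx + dy * dy + dz * dz);
            M(i, j) = k / r;
            M(j, i) = M(i, j);
        }
    }
    arma::Col<eT> sol;
    const bool ok = arma::solve(sol, M, b, arma::solve_opts::no_approx);
    if (!ok) stop("embedded fragment system is singular or too ill-conditioned");
    return sol;
}

// ---------------------------------------------------------------------------
// Fragment solves shared by the cutoff and cover schemes. `centers` are
// 1-based atom indices; `assignment[a]` is the 1-based position (into
// `centers`) of the fragment that supplies atom a's charge.
//
// Stage 1 solves each fragment's constrained EEM system with proportionally
// allocated total charge (Q * m / N), giving first-pass charges q0 and the
// mean fragment electronegativity chi_est. With `refine`, stage 2 re-solves
// each fragment without the charge constraint, embedded in the frozen far
// field of the stage-1 charges and anchored at chi_est — capturing the
// long-range charge transfer a bare local solve misses. One pass only: the
// underlying fixed-point iteration is not contractive at small radii.
// ---------------------------------------------------------------------------
template <typename eT>
static List fragment_solve_impl(const arma::mat& X,
                                const arma::vec& Apar,
                                const arma::vec& Bpar,
                                double kappa,
                                double total_charge,
                                double radius,
                                const IntegerVector& centers,
                                const IntegerVector& assignment,
                                bool refine)
{
    const int n = (int)X.n_rows;
    const int nc = centers.size();
    CellGrid grid(X, radius);

    // group atoms by their assigned fragment so each fragment is solved once
    std::vector< std::vector<int> > assigned(nc);
    for (int a = 0; a < n; ++a) {
        const int k = assignment[a] - 1;
        if (k < 0 || k >= nc) stop("assignment index out of range for atom %d", a + 1);
        assigned[k].push_back(a);
    }

    std::vector< std::vector<int> > frag_members(nc);
    arma::vec q(n, arma::fill::zeros);
    IntegerVector frag_sizes(nc);
    double peak_elems = 0.0, chi_sum = 0.0;

    for (int k = 0; k < nc; ++k) {
        const int c = centers[k] - 1;
        frag_members[k] = grid.neighbors(X, c, radius);
        const std::vector<int>& nb = frag_members[k];
        arma::uvec members(nb.size());
        for (size_t i = 0; i < nb.size(); ++i) members(i) = (arma::uword)nb[i];
        const arma::uword m = members.n_elem;
        frag_sizes[k] = (int)m;
        peak_elems = std::max(peak_elems, (double)(m + 1) * (double)(m + 1));

        const double qfrag = total_charge * ((double)m / (double)n);
        eT chi;
        arma::Col<eT> sol;
        try {
            sol = solve_members<eT>(X, Apar, Bpar, kappa, qfrag, members, chi);
        } catch (const std::exception& e) {
            stop("fragment centered on atom %d: %s", c + 1, e.what());
        }
        chi_sum += (double)chi;

        for (int a : assigned[k]) {
            // members are sorted: binary search for a's slot in the fragment
            std::vector<int>::const_iterator it =
                std::lower_bound(nb.begin(), nb.end(), a);
            if (it == nb.end() || *it != a)
                stop("atom %d is not a member of its assigned fragment (center %d)", a + 1, c + 1);
            q(a) = (double)sol(it - nb.begin());
        }
        if (k % 256 == 0) Rcpp::checkUserInterrupt();
    }

    const double chi_est = chi_sum / nc;

    if (refine) {
        // total EEM potential at every atom from the stage-1 charges
        arma::vec q0 = q;
        arma::vec Phi(n, arma::fill::zeros);
        for (int i = 0; i < n; ++i) {
            double acc = 0.0;
            for (int j = 0; j < n; ++j) {
                if (j == i) continue;
                const double dx = X(j, 0) - X(i, 0), dy = X(j, 1) - X(i, 1),
                             dz = X(j, 2) - X(i, 2);
                acc += q0(j) / std::sqrt(dx * dx + dy * dy + dz * dz);
            }
            Phi(i) = kappa * acc;
            if (i % 1024 == 0) Rcpp::checkUserInterrupt();
        }

        for (int k = 0; k < nc; ++k) {
            const std::vector<int>& nb = frag_members[k];
            const arma::uword m = (arma::uword)nb.size();
            arma::uvec members(m);
            for (arma::uword i = 0; i < m; ++i) members(i) = (arma::uword)nb[i];
            // far-field potential: total minus the in-fragment part
            arma::vec phi_ext(m);
            for (arma::uword i = 0; i < m; ++i) {
                double in = 0.0;
                const int a = nb[i];
                for (arma::uword j = 0; j < m; ++j) {
                    const int b2 = nb[j];
                    if (b2 == a) continue;
                    const double dx = X(b2, 0) - X(a, 0), dy = X(b2, 1) - X(a, 1),
                                 dz = X(b2, 2) - X(a, 2);
                    in += q0(b2) / std::sqrt(dx * dx + dy * dy + dz * dz);
                }
                phi_ext(i) = Phi(a) - kappa * in;
            }
            arma::Col<eT> sol;
            try {
                sol = solve_members_embedded<eT>(X, Apar, Bpar, kappa, chi_est,
                                                 phi_ext, members);
            } catch (const std::exception& e) {
                stop("fragment centered on atom %d: %s", centers[k], e.what());
            }
            for (int a : assigned[k]) {
                std::vector<int>::const_iterator it =
                    std::lower_bound(nb.begin(), nb.end(), a);
                q(a) = (double)sol(it - nb.begin());
            }
            if (k % 256 == 0) Rcpp::checkUserInterrupt();
        }
    }

    return List::create(_["q"] = q,
                        _["chi_bar"] = chi_est,
                        _["n_fragments"] = nc,
                        _["peak_matrix_elements"] = peak_elems,
                        _["fragment_sizes"] = frag_sizes,
                        _["charge_residual"] = arma::accu(q) - total_charge);
}

// [[Rcpp::export]]
List cpp_solve_fragments(const arma::mat& X,
                         const arma::vec& Apar,
                         const arma::vec& Bpar,
                         double kappa,
                         double total_charge,
                         double radius,
                         const IntegerVector& centers,
                         const IntegerVector& assignment,
                         bool single_precision,
                         bool refine)
{
    if (single_precision)
        return fragment_solve_impl<float>(X, Apar, Bpar, kappa, total_charge, radius,
                                          centers, assignment, refine);
    return fragment_solve_impl<double>(X, Apar, Bpar, kappa, total_charge, radius,
                                       centers, assignment, refine);
}
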