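#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tabular (recursive) additive relationship matrix.  sire/dam are 1-based
// row indices of the parents (0 = unknown); parents must precede offspring.
// [[Rcpp::export]]
NumericMatrix build_A_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i)
      stop("parents must precede offspring in the pedigree ordering");
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(i, j) = v;
      A(j, i) = v;
    }
    A(i, i) = 1.0 + ((s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}

static void build_V(arma::mat &V, const arma::field<arma::mat> &G,
                    const arma::vec &sigma2, int n) {
  int k = G.n_elem;
  V.eye(n, n);
  V *= sigma2(k);                       // residual
  for (int j = 0; j < k; ++j) V += sigma2(j) * G(j);
}

// Restricted log-likelihood (REML criterion, constant terms dropped):
//   ll = -1/2 [ log|V| + log|X'V^-1 X| + y' P y ]
static double reml_ll(const arma::vec &y, const arma::mat &X,
                      const arma::mat &V, arma::mat &P, arma::vec &Py) {
  arma::mat Vi = arma::inv_sympd(arma::symmatu(V));
  arma::mat W = Vi * X;
  arma::mat XtVX = X.t() * W;
  arma::mat C = arma::inv(arma::symmatu(XtVX));
  P = Vi - W * C * W.t();
  Py = P * y;
  double ldV, sV, ldC, sC;
  arma::log_det(ldV, sV, V);
  arma::log_det(ldC, sC, XtVX);
  return -0.5 * (ldV + ldC + arma::dot(y, Py));
}

// EM-REML for the model y = X beta + sum_j Z_j u_j + e with
// u_j ~ N(0, sigma2_j K_j), e ~ N(0, sigma2_e I).  G[j] = Z_j K_j Z_j'
// (n x n); q[j] = dim(u_j).  sigma2 holds the k component variances then
// the residual variance.  EM update for component j:
//   sigma2_j <- sigma2_j + sigma2_j^2 / q_j * ( y'P G_j P y - tr(P G_j) )
// with the residual treated as a component with G = I, q = n.  The update
// is monotone in the restricted likelihood; variances are floored.
// [[Rcpp::export]]
List em_reml_cpp(const arma::vec &y, const arma::mat &X, List G_list,
                 arma::vec sigma2, arma::vec q, double tol = 1e-8,
                 int maxit = 500, double floor_val = 1e-8) {
  int n = y.n_elem, k = G_list.size();
  arma::field<arma::mat> G(k);
  for (int j = 0; j < k; ++j) G(j) = as<arma::mat>(G_list[j]);
  arma::mat V(n, n), P;
  arma::vec Py;
  std::vector<double> trace;
  double ll = 0.0, ll_prev = 0.0;
  bool converged = false;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    build_V(V, G, sigma2, n);
    ll = reml_ll(y, X, V, P, Py);
    trace.push_back(ll);
    if (it > 1 && std::abs(ll - ll_prev) / (std::abs(ll_prev) + 1.0) < tol) {
      converged = true;
      break;
    }
    ll_prev = ll;
    arma::vec s_new = sigma2;
    for (int j = 0; j < k; ++j) {
      double yPGPy = arma::as_scalar(Py.t() * G(j) * Py);
      double trPG = arma::accu(P % G(j));
      s_new(j) = sigma2(j) +
        sigma2(j) * sigma2(j) / q(j) * (yPGPy - trPG);
    }
    s_new(k) = sigma2(k) +
      sigma2(k) * sigma2(k) / n * (arma::dot(Py, Py) - arma::trace(P));
    for (int j = 0; j <= k; ++j)
      sigma2(j) = std::max(s_new(j), floor_val);
  }
  return List::create(_["sigma2"] = sigma2,
                      _["loglik"] = ll,
                      _["trace"] = trace,
                      _["iterations"] = std::min(it, maxit),
                      _["converged"] = converged);
}

// EM-REML in the eigenbasis of A.  Inputs are rotated by the eigenvectors
// Q of A: ytil = Q'y, Xtil = Q'X, lambda = eigenvalues of A, and
// W = Q' Z L with H = L L' (empty matrix for the H0 model).  In this
// basis V = diag(sigma_u lambda + sigma_e) + sigma_h W W', so solves use
// a diagonal inverse plus a kappa x kappa Woodbury correction.  The EM
// updates are algebraically identical to em_reml_cpp's.
// [[Rcpp::export]]
List em_reml_eig_cpp(const arma::vec &ytil, const arma::mat &Xtil,
                     const arma::vec &lambda, const arma::mat &W,
                     arma::vec sigma2, arma::vec q, double tol = 1e-8,
                     int maxit = 500, double floor_val = 1e-8) {
  int n = ytil.n_elem;
  bool with_h = W.n_cols > 0;
  int kap = W.n_cols;
  double ll = 0.0, ll_prev = 0.0;
  std::vector<double> trace;
  bool converged = false;
  int it = 0;
  double sh = 0, su, se;
  arma::mat T, Minv, Wd, B;
  arma::vec D, Dinv, diagVi;
  for (it = 1; it <= maxit; ++it) {
    if (with_h) { sh = sigma2(0); su = sigma2(1); se = sigma2(2); }
    else { su = sigma2(0); se = sigma2(1); }
    D = su * lambda + se;
    Dinv = 1.0 / D;
    double logdetV = arma::accu(arma::log(D));
    if (with_h) {
      Wd = W.each_col() % Dinv;
      T = W.t() * Wd;                      // W' D^-1 W
      arma::mat M = T;
      M.diag() += 1.0 / sh;
      Minv = arma::inv_sympd(arma::symmatu(M));
      double ld, sgn;
      arma::mat IT = sh * T;
      IT.diag() += 1.0;
      arma::log_det(ld, sgn, IT);
      logdetV += ld;
    }
    // Vi v = Dinv v - Wd Minv (W' (Dinv v))
    arma::vec yD = Dinv % ytil;
    arma::vec xD = Dinv % Xtil.col(0);
    arma::vec vy, vx;
    if (with_h) {
      vy = yD - Wd * (Minv * (W.t() * yD));
      vx = xD - Wd * (Minv * (W.t() * xD));
    } else { vy = yD; vx = xD; }
    double sx = arma::dot(Xtil.col(0), vx);
    arma::vec p = vy - vx * (arma::dot(vx, ytil) / sx);
    ll = -0.5 * (logdetV + std::log(sx) + arma::dot(ytil, p));
    trace.push_back(ll);
    if (it > 1 && std::abs(ll - ll_prev) / (std::abs(ll_prev) + 1.0) < tol) {
      converged = true;
      break;
    }
    ll_prev = ll;
    // diag(Vi) and component traces
    double trViA, trVi, trViG = 0, vxG = 0;
    if (with_h) {
      B = Wd * Minv;
      diagVi = Dinv - arma::sum(B % Wd, 1);
      trViG = arma::trace(T) - arma::accu((T * Minv) % T);
      arma::vec Wvx = W.t() * vx;
      vxG = arma::dot(Wvx, Wvx);
    } else diagVi = Dinv;
    trViA = arma::dot(lambda, diagVi);
    trVi = arma::accu(diagVi);
    double vxA = arma::dot(lambda, vx % vx);
    double vxI = arma::dot(vx, vx);
    // y'P G P y terms
    double yGh = 0;
    if (with_h) {
      arma::vec Wp = W.t() * p;
      yGh = arma::dot(Wp, Wp);
    }
    double yA = arma::dot(lambda, p % p);
    double yI = arma::dot(p, p);
    arma::vec s_new = sigma2;
    int j = 0;
    if (with_h) {
      double trPG = trViG - vxG / sx;
      s_new(0) = sh + sh * sh / q(0) * (yGh - trPG);
      j = 1;
    }
    s_new(j) = su + su * su / q(j) * (yA - (trViA - vxA / sx));
    s_new(j + 1) = se + se * se / n * (yI - (trVi - vxI / sx));
    for (unsigned int k = 0; k < sigma2.n_elem; ++k)
      sigma2(k) = std::max(s_new(k), floor_val);
  }
  return List::create(_["sigma2"] = sigma2,
                      _["loglik"] = ll,
                      _["trace"] = trace,
                      _["iterations"] = std::min(it, maxit),
                      _["converged"] = converged);
}

// Restricted log-likelihood at fixed variance components (same criterion
// and constant-dropping convention as em_reml_cpp).
// [[Rcpp::export]]
double reml_loglik_cpp(const arma::vec &y, const arma::mat &X, List G_list,
                       arma::vec sigma2) {
  int n = y.n_elem, k = G_list.size();
  arma::field<arma::mat> G(k);
  for (int j = 0; j < k; ++j) G(j) = as<arma::mat>(G_list[j]);
  arma::mat V(n, n), P;
  arma::vec Py;
  build_V(V, G, sigma2, n);
  return reml_ll(y, X, V, P, Py);
}
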