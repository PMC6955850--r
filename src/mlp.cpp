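// Minimal feedforward network engine: Softplus / linear layers, an optional
// per-sample L2 normalization after a linear layer, MSE loss, and the Adamax
// optimizer. Deterministic given the integer seed (std::mt19937, no threads).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

// activation codes: 0 = linear, 1 = softplus, 2 = linear + row-wise L2 norm
int act_code(const std::string& s) {
  if (s == "linear") return 0;
  if (s == "softplus") return 1;
  if (s == "l2norm") return 2;
  stop("unknown activation: %s", s);
}

mat softplus(const mat& x) {
  // log(1 + e^x), overflow-safe: x + log1p(e^-x) for large x
  mat y(x.n_rows, x.n_cols);
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    double v = x(i);
    y(i) = v > 30.0 ? v + std::log1p(std::exp(-v)) : std::log1p(std::exp(v));
  }
  return y;
}

mat sigmoid(const mat& x) {
  mat y(x.n_rows, x.n_cols);
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    double v = x(i);
    y(i) = v >= 0 ? 1.0 / (1.0 + std::exp(-v)) : std::exp(v) / (1.0 + std::exp(v));
  }
  return y;
}

struct Net {
  std::vector<mat> W;       // W[l]: d_l x d_{l+1}
  std::vector<rowvec> b;    // b[l]: 1 x d_{l+1}
  std::vector<int> act;     // per layer
};

Net net_from_list(const List& net) {
  Net n;
  List Wl = net["W"], bl = net["b"];
  CharacterVector al = net["act"];
  for (int l = 0; l < Wl.size(); ++l) {
    n.W.push_back(as<mat>(Wl[l]));
    n.b.push_back(as<rowvec>(bl[l]));
    n.act.push_back(act_code(as<std::string>(al[l])));
  }
  return n;
}

List net_to_list(const Net& n, CharacterVector act_names) {
  List Wl(n.W.size()), bl(n.b.size());
  for (size_t l = 0; l < n.W.size(); ++l) {
    Wl[l] = n.W[l];
    bl[l] = n.b[l];
  }
  return List::create(_["W"] = Wl, _["b"] = bl, _["act"] = act_names);
}

// forward pass keeping pre-activations (Z) and activations (A); A[0] = X
void forward_pass(const Net& net, const mat& X,
                  std::vector<mat>& Z, std::vector<mat>& A) {
  size_t L = net.W.size();
  Z.assign(L, mat());
  A.assign(L + 1, mat());
  A[0] = X;
  for (size_t l = 0; l < L; ++l) {
    Z[l] = A[l] * net.W[l];
    Z[l].each_row() += net.b[l];
    switch (net.act[l]) {
      case 0: A[l + 1] = Z[l]; break;
      case 1: A[l + 1] = softplus(Z[l]); break;
      case 2: {
        mat z = Z[l];
        vec nrm = arma::sqrt(arma::sum(arma::square(z), 1) + 1e-24);
        A[l + 1] = z.each_col() / nrm;
        break;
      }
    }
  }
}

}  // namespace

// Glorot-uniform weight initialization, seeded.
// [[Rcpp::export(name = ".mlp_init")]]
List mlp_init_cpp(IntegerVector dims, CharacterVector acts, int seed) {
  int L = dims.size() - 1;
  if (acts.size() != L) stop("need one activation per layer");
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  List Wl(L), bl(L);
  for (int l = 0; l < L; ++l) {
    int din = dims[l], dout = dims[l + 1];
    double lim = std::sqrt(6.0 / (din + dout));
    mat W(din, dout);
    for (arma::uword j = 0; j < W.n_cols; ++j)   // column-major fill, fixed order
      for (arma::uword i = 0; i < W.n_rows; ++i)
        W(i, j) = lim * unif(rng);
    Wl[l] = W;
    bl[l] = rowvec(dout, arma::fill::zeros);
    act_code(as<std::string>(acts[l]));  // validate
  }
  return List::create(_["W"] = Wl, _["b"] = bl, _["act"] = acts);
}

// Forward pass through layers [0, upto); upto = -1 means all layers.
// [[Rcpp::export(name = ".mlp_forward")]]
arma::mat mlp_forward_cpp(List net, arma::mat X, int upto = -1) {
  Net n = net_from_list(net);
  size_t L = (upto < 0) ? n.W.size() : static_cast<size_t>(upto);
  if (L > n.W.size()) stop("upto exceeds layer count");
  std::vector<mat> Z, A;
  Net sub;
  sub.W.assign(n.W.begin(), n.W.begin() + L);
  sub.b.assign(n.b.begin(), n.b.begin() + L);
  sub.act.assign(n.act.begin(), n.act.begin() + L);
  forward_pass(sub, X, Z, A);
  return A[L];
}

// Adamax minibatch training on MSE. Returns updated net and the per-epoch
// mean minibatch loss. Shuffling and updates are deterministic per seed.
// [[Rcpp::export(name = ".mlp_train")]]
List mlp_train_cpp(List net, arma::mat X, arma::mat Y,
                   int epochs, int batch, double lr,
                   double beta1, double beta2, double eps, int seed) {
  Net n = net_from_list(net);
  size_t L = n.W.size();
  size_t nsamp = X.n_rows;
  if (Y.n_rows != nsamp) stop("X and Y row mismatch");
  if (batch < 1) batch = static_cast<int>(nsamp);

  std::vector<mat> mW(L), uW(L);
  std::vector<rowvec> mb(L), ub(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l].zeros(arma::size(n.W[l]));
    uW[l].zeros(arma::size(n.W[l]));
    mb[l].zeros(arma::size(n.b[l]));
    ub[l].zeros(arma::size(n.b[l]));
  }

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<arma::uword> order(nsamp);
  for (size_t i = 0; i < nsamp; ++i) order[i] = i;

  NumericVector history(epochs);
  std::vector<mat> Z, A;
  long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    if (static_cast<size_t>(batch) < nsamp) {
      std::shuffle(order.begin(), order.end(), rng);
    }
    double ep_loss = 0.0;
    int nbatch = 0;
    for (size_t start = 0; start < nsamp; start += batch) {
      size_t end = std::min(start + batch, nsamp);
      arma::uvec idx(end - start);
      for (size_t i = start; i < end; ++i) idx[i - start] = order[i];
      mat Xb = X.rows(idx), Yb = Y.rows(idx);

      forward_pass(n, Xb, Z, A);
      mat diff = A[L] - Yb;
      double loss = arma::accu(arma::square(diff)) / diff.n_elem;
      if (!std::isfinite(loss)) stop("training diverged: non-finite loss at epoch %d", ep + 1);
      ep_loss += loss;
      ++nbatch;

      // backward
      mat delta = (2.0 / diff.n_elem) * diff;  // dL/dA[L]
      ++step;
      double bc = 1.0 - std::pow(beta1, static_cast<double>(step));
      for (int l = static_cast<int>(L) - 1; l >= 0; --l) {
        mat dZ;
        switch (n.act[l]) {
          case 0: dZ = delta; break;
          case 1: dZ = delta % sigmoid(Z[l]); break;
          case 2: {
            // y = z / ||z||; dL/dz = (g - y * rowsum(y % g)) / ||z||
            mat z = Z[l];
            vec nrm = arma::sqrt(arma::sum(arma::square(z), 1) + 1e-24);
            mat y = z.each_col() / nrm;
            vec dot = arma::sum(y % delta, 1);
            dZ = (delta - y.each_col() % dot);
            dZ.each_col() /= nrm;
            break;
          }
        }
        mat gW = A[l].t() * dZ;
        rowvec gb = arma::sum(dZ, 0);
        if (l > 0) delta = dZ * n.W[l].t();

        // Adamax update, fused single pass per parameter array
        const double slr = lr / bc;
        auto adamax = [&](double* w, double* m, double* u, const double* g,
                          arma::uword cnt) {
          for (arma::uword i = 0; i < cnt; ++i) {
            m[i] = beta1 * m[i] + (1.0 - beta1) * g[i];
            const double ag = std::abs(g[i]);
            const double bu = beta2 * u[i];
            u[i] = bu > ag ? bu : ag;
            w[i] -= slr * m[i] / (u[i] + eps);
          }
        };
        adamax(n.W[l].memptr(), mW[l].memptr(), uW[l].memptr(), gW.memptr(),
               gW.n_elem);
        adamax(n.b[l].memptr(), mb[l].memptr(), ub[l].memptr(), gb.memptr(),
               gb.n_elem);
      }
    }
    history[ep] = ep_loss / nbatch;
  }
  return List::create(_["net"] = net_to_list(n, net["act"]),
                      _["history"] = history);
}

// Ridge least-squares refit of the FINAL linear layer given the learned
// hidden features: minimizes ||H * W + b - Y||^2 + lambda ||W||^2 with
// lambda = ridge * mean(diag(H'H)). Requires the final activation linear.
// [[Rcpp::export(name = ".mlp_refit_output")]]
List mlp_refit_output_cpp(List net, arma::mat X, arma::mat Y, double ridge) {
  Net n = net_from_list(net);
  size_t L = n.W.size();
  if (n.act[L - 1] != 0) stop("output-layer refit requires a linear output layer");
  std::vector<mat> Z, A;
  forward_pass(n, X, Z, A);
  mat H = A[L - 1];
  // center so the bias absorbs means
  rowvec hmean = arma::mean(H, 0), ymean = arma::mean(Y, 0);
  mat Hc = H.each_row() - hmean;
  mat Yc = Y.each_row() - ymean;
  mat G = Hc.t() * Hc;
  double lam = ridge * arma::trace(G) / G.n_rows;
  G.diag() += lam + 1e-300;
  mat Wnew = arma::solve(G, Hc.t() * Yc, arma::solve_opts::likely_sympd);
  n.W[L - 1] = Wnew;
  n.b[L - 1] = ymean - hmean * Wnew;
  return net_to_list(n, net["act"]);
}

// Training-set MSE of the current net (mean over all elements).
// [[Rcpp::export(name = ".mlp_mse")]]
double mlp_mse_cpp(List net, arma::mat X, arma::mat Y) {
  Net n = net_from_list(net);
  std::vector<mat> Z, A;
  forward_pass(n, X, Z, A);
  mat diff = A[n.W.size()] - Y;
  return arma::accu(arma::square(diff)) / diff.n_elem;
}
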