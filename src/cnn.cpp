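// Patch-classification CNN with Monte-Carlo dropout, implemented on
// Armadillo. Layout conventions:
//   * a batch of N single-channel patches arrives as a cube (side, side, N);
//   * internal activations are cubes (H, W, C*N) with slice index n*C + c;
//   * convolution is SAME-padded im2col + GEMM; pooling is 2x2 stride 2
//     with floor truncation; each convolutional cluster applies
//     batch-norm -> conv -> ReLU -> max-pool -> dropout in that order;
//   * the head is flatten -> FC(F,F) -> ReLU -> FC(F,n_out) -> softmax.
// Batch norm uses batch statistics during training (running averages
// updated with momentum 0.9) and the stored running statistics at
// prediction time; dropout can stay active at prediction time, which is
// what makes repeated forward passes a Monte-Carlo posterior sample.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uvec;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;

// ---------------------------------------------------------------------------
// patch extraction (replicate padding at the borders)

// [[Rcpp::export]]
arma::cube cpp_extract_patches(const arma::mat& img, IntegerVector cx,
                               IntegerVector cy, int side) {
  const int n = cx.size();
  const int half = side / 2;
  const int H = img.n_rows, W = img.n_cols;
  cube out(side, side, n);
  for (int i = 0; i < n; ++i) {
    for (int dx = -half; dx <= half; ++dx) {
      int x = std::min(std::max(cx[i] + dx, 0), W - 1);
      for (int dy = -half; dy <= half; ++dy) {
        int y = std::min(std::max(cy[i] + dy, 0), H - 1);
        out(dy + half, dx + half, i) = img(y, x);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// network definition

struct ClusterParams {
  vec bn_gamma, bn_beta, bn_rmean, bn_rvar;  // per input channel
  mat W;                                     // (k*k*Cin) x Cout
  vec b;                                     // Cout
};

struct Net {
  int side, n_out;
  double dropout;
  std::vector<int> kernels, depths;
  std::vector<ClusterParams> cl;
  mat fc1_W, fc2_W;
  vec fc1_b, fc2_b;
  int flat_side, flat_ch;
};

static void net_shapes(int side, const std::vector<int>& kernels,
                       std::vector<int>& sides_out) {
  int s = side;
  sides_out.clear();
  for (size_t i = 0; i < kernels.size(); ++i) {
    s = s / 2;  // SAME conv keeps size; pool halves with floor
    if (s < 1) stop("patch collapses at cluster %d", (int)(i + 1));
    sides_out.push_back(s);
  }
}

static Net net_from_list(const List& params, const List& arch, int side) {
  Net net;
  net.side = side;
  net.kernels = as<std::vector<int>>(arch["kernel_sides"]);
  net.depths = as<std::vector<int>>(arch["channel_depths"]);
  net.n_out = as<int>(arch["n_outputs"]);
  net.dropout = as<double>(arch["dropout_rate"]);
  std::vector<int> sides;
  net_shapes(side, net.kernels, sides);
  List clusters = params["clusters"];
  for (size_t i = 0; i < net.kernels.size(); ++i) {
    List c = clusters[i];
    ClusterParams p;
    p.bn_gamma = as<vec>(c["bn_gamma"]);
    p.bn_beta = as<vec>(c["bn_beta"]);
    p.bn_rmean = as<vec>(c["bn_rmean"]);
    p.bn_rvar = as<vec>(c["bn_rvar"]);
    p.W = as<mat>(c["W"]);
    p.b = as<vec>(c["b"]);
    net.cl.push_back(p);
  }
  net.fc1_W = as<mat>(params["fc1_W"]);
  net.fc1_b = as<vec>(params["fc1_b"]);
  net.fc2_W = as<mat>(params["fc2_W"]);
  net.fc2_b = as<vec>(params["fc2_b"]);
  net.flat_side = sides.back();
  net.flat_ch = net.depths.back();
  return net;
}

static List net_to_list(const Net& net) {
  List clusters(net.cl.size());
  for (size_t i = 0; i < net.cl.size(); ++i) {
    clusters[i] = List::create(
        _["bn_gamma"] = net.cl[i].bn_gamma, _["bn_beta"] = net.cl[i].bn_beta,
        _["bn_rmean"] = net.cl[i].bn_rmean, _["bn_rvar"] = net.cl[i].bn_rvar,
        _["W"] = net.cl[i].W, _["b"] = net.cl[i].b);
  }
  return List::create(_["clusters"] = clusters, _["fc1_W"] = net.fc1_W,
                      _["fc1_b"] = net.fc1_b, _["fc2_W"] = net.fc2_W,
                      _["fc2_b"] = net.fc2_b);
}

// Glorot (fan-balanced) uniform initializer
static mat glorot(int rows, int cols, double fan_in, double fan_out,
                  std::mt19937& rng) {
  double lim = std::sqrt(6.0 / (fan_in + fan_out));
  std::uniform_real_distribution<double> u(-lim, lim);
  mat W(rows, cols);
  for (arma::uword j = 0; j < W.n_cols; ++j)
    for (arma::uword i = 0; i < W.n_rows; ++i) W(i, j) = u(rng);
  return W;
}

// [[Rcpp::export]]
List cpp_cnn_init(int side, const List& arch, int seed) {
  std::mt19937 rng(seed);
  std::vector<int> kernels = as<std::vector<int>>(arch["kernel_sides"]);
  std::vector<int> depths = as<std::vector<int>>(arch["channel_depths"]);
  int n_out = as<int>(arch["n_outputs"]);
  std::vector<int> sides;
  net_shapes(side, kernels, sides);
  Net net;
  net.kernels = kernels;
  net.depths = depths;
  int cin = 1;
  for (size_t i = 0; i < kernels.size(); ++i) {
    ClusterParams p;
    p.bn_gamma = vec(cin, arma::fill::ones);
    p.bn_beta = vec(cin, arma::fill::zeros);
    p.bn_rmean = vec(cin, arma::fill::zeros);
    p.bn_rvar = vec(cin, arma::fill::ones);
    int k = kernels[i], cout = depths[i];
    p.W = glorot(k * k * cin, cout, k * k * cin, k * k * cout, rng);
    p.b = vec(cout, arma::fill::zeros);
    net.cl.push_back(p);
    cin = cout;
  }
  int F = sides.back() * sides.back() * depths.back();
  net.fc1_W = glorot(F, F, F, F, rng);
  net.fc1_b = vec(F, arma::fill::zeros);
  net.fc2_W = glorot(F, n_out, F, n_out, rng);
  net.fc2_b = vec(n_out, arma::fill::zeros);
  return net_to_list(net);
}

// ---------------------------------------------------------------------------
// layer primitives

// im2col for SAME zero padding: rows ordered (n, then column-major spatial),
// columns ordered (c, ky over rows, kx over cols) -> c*k*k + kx*k + ky
static mat im2col_same(const cube& X, int N, int C, int k) {
  const int H = X.n_rows, W = X.n_cols;
  const int pt = (k - 1) / 2;  // top/left pad (even k pads one more at the end)
  mat M((arma::uword)N * H * W, (arma::uword)k * k * C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const mat& A = X.slice((arma::uword)n * C + c);
      for (int kx = 0; kx < k; ++kx) {
        for (int ky = 0; ky < k; ++ky) {
          arma::uword col = (arma::uword)c * k * k + kx * k + ky;
          int ylo = std::max(0, pt - ky), yhi = std::min(H, H + pt - ky);
          int xlo = std::max(0, pt - kx), xhi = std::min(W, W + pt - kx);
          for (int x = xlo; x < xhi; ++x) {
            double* dst = M.colptr(col) + (arma::uword)n * H * W +
                          (arma::uword)x * H + ylo;
            const double* src = A.colptr(x - pt + kx) + (ylo - pt + ky);
            std::copy(src, src + (yhi - ylo), dst);
          }
        }
      }
    }
  }
  return M;
}

// scatter-add transpose of im2col_same
static cube col2im_same(const mat& M, int N, int C, int k, int H, int W) {
  const int pt = (k - 1) / 2;
  cube X(H, W, (arma::uword)N * C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      mat& A = X.slice((arma::uword)n * C + c);
      for (int kx = 0; kx < k; ++kx) {
        for (int ky = 0; ky < k; ++ky) {
          arma::uword col = (arma::uword)c * k * k + kx * k + ky;
          int ylo = std::max(0, pt - ky), yhi = std::min(H, H + pt - ky);
          int xlo = std::max(0, pt - kx), xhi = std::min(W, W + pt - kx);
          for (int x = xlo; x < xhi; ++x) {
            const double* src = M.colptr(col) + (arma::uword)n * H * W +
                                (arma::uword)x * H + ylo;
            double* dst = A.colptr(x - pt + kx) + (ylo - pt + ky);
            for (int y = 0; y < yhi - ylo; ++y) dst[y] += src[y];
          }
        }
      }
    }
  }
  return X;
}

static cube conv_out_to_cube(const mat& Y, int N, int D, int H, int W) {
  cube out(H, W, (arma::uword)N * D);
  for (int n = 0; n < N; ++n)
    for (int d = 0; d < D; ++d) {
      mat block(Y.colptr(d) + (arma::uword)n * H * W, H, W);
      out.slice((arma::uword)n * D + d) = block;
    }
  return out;
}

static mat cube_to_conv_grad(const cube& dY, int N, int D) {
  const int H = dY.n_rows, W = dY.n_cols;
  mat G((arma::uword)N * H * W, D);
  for (int n = 0; n < N; ++n)
    for (int d = 0; d < D; ++d) {
      const mat& s = dY.slice((arma::uword)n * D + d);
      std::copy(s.memptr(), s.memptr() + (arma::uword)H * W,
                G.colptr(d) + (arma::uword)n * H * W);
    }
  return G;
}

struct PoolCache {
  arma::umat argmax;  // (Hout*Wout*N) rows? stored flat per slice
};

static cube maxpool2(const cube& X, int N, int C,
                     std::vector<arma::uvec>& argmax) {
  const int H = X.n_rows, W = X.n_cols;
  const int Ho = H / 2, Wo = W / 2;
  cube Y(Ho, Wo, X.n_slices);
  argmax.assign(X.n_slices, arma::uvec());
  for (arma::uword s = 0; s < X.n_slices; ++s) {
    const mat& A = X.slice(s);
    mat& B = Y.slice(s);
    arma::uvec am((arma::uword)Ho * Wo);
    for (int x = 0; x < Wo; ++x) {
      for (int y = 0; y < Ho; ++y) {
        int by = 2 * y, bx = 2 * x;
        double best = A(by, bx);
        arma::uword bi = (arma::uword)bx * H + by;
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy) {
            double v = A(by + dy, bx + dx);
            if (v > best) {
              best = v;
              bi = (arma::uword)(bx + dx) * H + (by + dy);
            }
          }
        B(y, x) = best;
        am((arma::uword)x * Ho + y) = bi;
      }
    }
    argmax[s] = am;
  }
  return Y;
}

static cube maxpool2_back(const cube& dY, const std::vector<arma::uvec>& argmax,
                          int H, int W) {
  cube dX(H, W, dY.n_slices, arma::fill::zeros);
  for (arma::uword s = 0; s < dY.n_slices; ++s) {
    const mat& G = dY.slice(s);
    mat& D = dX.slice(s);
    const arma::uvec& am = argmax[s];
    const double* g = G.memptr();
    for (arma::uword i = 0; i < am.n_elem; ++i) D(am(i)) += g[i];
  }
  return dX;
}

// flatten cube (h, w, C*N) -> mat (N, h*w*C), features ordered channel-major
static mat flatten_batch(const cube& X, int N, int C) {
  const arma::uword P = X.n_rows * X.n_cols;
  mat out(N, P * C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const mat& s = X.slice((arma::uword)n * C + c);
      for (arma::uword i = 0; i < P; ++i) out(n, (arma::uword)c * P + i) = s(i);
    }
  return out;
}

static cube unflatten_batch(const mat& G, int N, int C, int h, int w) {
  const arma::uword P = (arma::uword)h * w;
  cube out(h, w, (arma::uword)N * C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      mat& s = out.slice((arma::uword)n * C + c);
      for (arma::uword i = 0; i < P; ++i) s(i) = G(n, (arma::uword)c * P + i);
    }
  return out;
}

// dropout mask with inverted scaling; mask entries are 0 or 1/(1-rate)
static cube dropout_mask(arma::uword H, arma::uword W, arma::uword S,
                         double rate, std::mt19937& rng) {
  cube M(H, W, S);
  std::bernoulli_distribution keep(1.0 - rate);
  const double scale = 1.0 / (1.0 - rate);
  for (double* p = M.memptr(); p != M.memptr() + M.n_elem; ++p)
    *p = keep(rng) ? scale : 0.0;
  return M;
}

// ---------------------------------------------------------------------------
// forward pass

struct ForwardCache {
  // per cluster
  std::vector<cube> x_in;        // input to BN
  std::vector<cube> xhat;        // normalized input
  std::vector<vec> bn_mean, bn_istd;
  std::vector<mat> im2col;       // conv input columns
  std::vector<cube> conv_out;    // pre-ReLU
  std::vector<cube> relu_out;
  std::vector<std::vector<arma::uvec>> pool_arg;
  std::vector<cube> pool_out;
  std::vector<cube> drop_mask;
  mat flat, fc1_pre, fc1_out, probs;
};

// batch-norm forward on cube (H, W, C*N) over channels
static cube bn_forward(const cube& X, ClusterParams& p, int N, int C,
                       bool training, ForwardCache* cache) {
  cube Y(X.n_rows, X.n_cols, X.n_slices);
  vec mean(C), istd(C);
  const double M = (double)N * X.n_rows * X.n_cols;
  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const mat& A = X.slice((arma::uword)n * C + c);
        s += arma::accu(A);
        s2 += arma::accu(arma::square(A));
      }
      mu = s / M;
      var = s2 / M - mu * mu;
      if (var < 0) var = 0;
      p.bn_rmean(c) = BN_MOMENTUM * p.bn_rmean(c) + (1 - BN_MOMENTUM) * mu;
      p.bn_rvar(c) = BN_MOMENTUM * p.bn_rvar(c) + (1 - BN_MOMENTUM) * var;
    } else {
      mu = p.bn_rmean(c);
      var = p.bn_rvar(c);
    }
    mean(c) = mu;
    istd(c) = 1.0 / std::sqrt(var + BN_EPS);
    for (int n = 0; n < N; ++n) {
      Y.slice((arma::uword)n * C + c) =
          (X.slice((arma::uword)n * C + c) - mu) * istd(c);
    }
  }
  cube out(Y.n_rows, Y.n_cols, Y.n_slices);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      out.slice((arma::uword)n * C + c) =
          Y.slice((arma::uword)n * C + c) * p.bn_gamma(c) + p.bn_beta(c);
  if (cache) {
    cache->xhat.push_back(Y);
    cache->bn_mean.push_back(mean);
    cache->bn_istd.push_back(istd);
  }
  return out;
}

static mat softmax_rows(mat Z) {
  Z.each_col() -= arma::max(Z, 1);
  Z = arma::exp(Z);
  Z.each_col() /= arma::sum(Z, 1);
  return Z;
}

// forward through the whole net; dropout_active draws fresh masks from rng;
// training toggles batch-norm batch statistics and cache recording
static mat net_forward(Net& net, const cube& X0, int N, bool training,
                       bool dropout_active, std::mt19937& rng,
                       ForwardCache* cache) {
  cube X = X0;  // (side, side, N), C = 1
  int C = 1;
  for (size_t i = 0; i < net.cl.size(); ++i) {
    if (cache) cache->x_in.push_back(X);
    cube A = bn_forward(X, net.cl[i], N, C, training, cache);
    int k = net.kernels[i], D = net.depths[i];
    mat M = im2col_same(A, N, C, k);
    mat Yc = M * net.cl[i].W;
    Yc.each_row() += net.cl[i].b.t();
    cube Y = conv_out_to_cube(Yc, N, D, A.n_rows, A.n_cols);
    if (cache) {
      cache->im2col.push_back(M);
      cache->conv_out.push_back(Y);
    }
    Y.transform([](double v) { return v > 0 ? v : 0.0; });
    if (cache) cache->relu_out.push_back(Y);
    std::vector<arma::uvec> am;
    cube Pled = maxpool2(Y, N, D, am);
    if (cache) {
      cache->pool_arg.push_back(am);
      cache->pool_out.push_back(Pled);
    }
    if (dropout_active && net.dropout > 0) {
      cube Mk = dropout_mask(Pled.n_rows, Pled.n_cols, Pled.n_slices,
                             net.dropout, rng);
      Pled %= Mk;
      if (cache) cache->drop_mask.push_back(Mk);
    } else if (cache) {
      cache->drop_mask.push_back(cube());
    }
    X = Pled;
    C = D;
  }
  mat F = flatten_batch(X, N, C);
  mat H1 = F * net.fc1_W;
  H1.each_row() += net.fc1_b.t();
  mat H1r = H1;
  H1r.transform([](double v) { return v > 0 ? v : 0.0; });
  mat Z = H1r * net.fc2_W;
  Z.each_row() += net.fc2_b.t();
  mat P = softmax_rows(Z);
  if (cache) {
    cache->flat = F;
    cache->fc1_pre = H1;
    cache->fc1_out = H1r;
    cache->probs = P;
  }
  return P;
}

// ---------------------------------------------------------------------------
// training (softmax cross entropy + L2 weight decay, Adam)

struct AdamState {
  std::vector<mat> m, v;
  int t = 0;
};

static void adam_update(mat& W, mat& g, mat& m, mat& v, double lr, double b1,
                        double b2, int t) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  mat mhat = m / (1 - std::pow(b1, t));
  mat vhat = v / (1 - std::pow(b2, t));
  W -= lr * mhat / (arma::sqrt(vhat) + 1e-8);
}

// [[Rcpp::export]]
List cpp_cnn_train(const List& params, const List& arch, const arma::cube& X,
                   const IntegerVector& y, int n_steps, int batch_size,
                   double lr, double weight_decay, double beta1, double beta2,
                   int seed) {
  const int side = X.n_rows;
  Net net = net_from_list(params, arch, side);
  const int Nall = X.n_slices;
  std::mt19937 rng(seed);
  std::uniform_int_distribution<int> pick(0, Nall - 1);
  const int n_cl = net.cl.size();

  // Adam state: per cluster (gamma, beta, W, b) then fc1_W, fc1_b, fc2_W, fc2_b
  std::vector<mat> m_st, v_st;
  auto add_slot = [&](arma::uword r, arma::uword c) {
    m_st.push_back(mat(r, c, arma::fill::zeros));
    v_st.push_back(mat(r, c, arma::fill::zeros));
  };
  for (int i = 0; i < n_cl; ++i) {
    add_slot(net.cl[i].bn_gamma.n_elem, 1);
    add_slot(net.cl[i].bn_beta.n_elem, 1);
    add_slot(net.cl[i].W.n_rows, net.cl[i].W.n_cols);
    add_slot(net.cl[i].b.n_elem, 1);
  }
  add_slot(net.fc1_W.n_rows, net.fc1_W.n_cols);
  add_slot(net.fc1_b.n_elem, 1);
  add_slot(net.fc2_W.n_rows, net.fc2_W.n_cols);
  add_slot(net.fc2_b.n_elem, 1);

  NumericVector loss_trace(n_steps);
  const int B = std::min(batch_size, Nall);

  for (int step = 0; step < n_steps; ++step) {
    // assemble batch
    cube Xb(side, side, B);
    arma::ivec yb(B);
    for (int i = 0; i < B; ++i) {
      int j = pick(rng);
      Xb.slice(i) = X.slice(j);
      yb(i) = y[j];
    }

    ForwardCache cache;
    net_forward(net, Xb, B, true, true, rng, &cache);

    // loss: mean CE + 0.5 * wd * sum ||W||^2 over conv and fc weights
    double ce = 0;
    for (int i = 0; i < B; ++i) {
      double p = cache.probs(i, yb(i) == 1 ? 1 : 0);
      ce -= std::log(std::max(p, 1e-12));
    }
    ce /= B;
    double l2 = arma::accu(arma::square(net.fc1_W)) +
                arma::accu(arma::square(net.fc2_W));
    for (int i = 0; i < n_cl; ++i) l2 += arma::accu(arma::square(net.cl[i].W));
    loss_trace[step] = ce + 0.5 * weight_decay * l2;

    // backward: softmax cross-entropy
    mat dZ = cache.probs;
    for (int i = 0; i < B; ++i) dZ(i, yb(i) == 1 ? 1 : 0) -= 1.0;
    dZ /= B;

    mat g_fc2_W = cache.fc1_out.t() * dZ + weight_decay * net.fc2_W;
    mat g_fc2_b = arma::sum(dZ, 0).t();
    mat dH1 = dZ * net.fc2_W.t();
    dH1 %= arma::conv_to<mat>::from(cache.fc1_pre > 0);
    mat g_fc1_W = cache.flat.t() * dH1 + weight_decay * net.fc1_W;
    mat g_fc1_b = arma::sum(dH1, 0).t();
    mat dF = dH1 * net.fc1_W.t();

    cube dX = unflatten_batch(dF, B, net.flat_ch, net.flat_side, net.flat_side);

    std::vector<mat> g_gamma(n_cl), g_beta(n_cl), g_W(n_cl), g_b(n_cl);
    int C = 1;
    std::vector<int> cins(n_cl);
    for (int i = 0; i < n_cl; ++i) {
      cins[i] = C;
      C = net.depths[i];
    }
    for (int i = n_cl - 1; i >= 0; --i) {
      const int D = net.depths[i], Cin = cins[i], k = net.kernels[i];
      // dropout
      if (net.dropout > 0) dX %= cache.drop_mask[i];
      // pool
      const cube& relu = cache.relu_out[i];
      dX = maxpool2_back(dX, cache.pool_arg[i], relu.n_rows, relu.n_cols);
      // relu
      dX %= arma::conv_to<cube>::from(cache.conv_out[i] > 0);
      // conv
      mat dY = cube_to_conv_grad(dX, B, D);
      g_W[i] = cache.im2col[i].t() * dY + weight_decay * net.cl[i].W;
      g_b[i] = arma::sum(dY, 0).t();
      mat dM = dY * net.cl[i].W.t();
      cube dA =
          col2im_same(dM, B, Cin, k, cache.xhat[i].n_rows, cache.xhat[i].n_cols);
      // batch norm
      const cube& xhat = cache.xhat[i];
      const vec& istd = cache.bn_istd[i];
      const double Mn = (double)B * xhat.n_rows * xhat.n_cols;
      g_gamma[i] = mat(Cin, 1);
      g_beta[i] = mat(Cin, 1);
      cube dXn(xhat.n_rows, xhat.n_cols, xhat.n_slices);
      for (int c = 0; c < Cin; ++c) {
        double sum_dy = 0, sum_dy_xhat = 0;
        for (int n = 0; n < B; ++n) {
          const mat& dy = dA.slice((arma::uword)n * Cin + c);
          const mat& xh = xhat.slice((arma::uword)n * Cin + c);
          sum_dy += arma::accu(dy);
          sum_dy_xhat += arma::accu(dy % xh);
        }
        g_gamma[i](c, 0) = sum_dy_xhat;
        g_beta[i](c, 0) = sum_dy;
        const double gam = net.cl[i].bn_gamma(c);
        const double mdy = sum_dy / Mn, mdyx = sum_dy_xhat / Mn;
        for (int n = 0; n < B; ++n) {
          const mat& dy = dA.slice((arma::uword)n * Cin + c);
          const mat& xh = xhat.slice((arma::uword)n * Cin + c);
          dXn.slice((arma::uword)n * Cin + c) =
              gam * istd(c) * (dy - mdy - xh * mdyx);
        }
      }
      dX = dXn;
    }

    // Adam updates in the same slot order as allocation
    int t = step + 1, slot = 0;
    for (int i = 0; i < n_cl; ++i) {
      mat gg = g_gamma[i];
      mat gv(net.cl[i].bn_gamma);
      adam_update(gv, gg, m_st[slot], v_st[slot], lr, beta1, beta2, t);
      net.cl[i].bn_gamma = gv.col(0);
      ++slot;
      mat gb = g_beta[i];
      mat bv(net.cl[i].bn_beta);
      adam_update(bv, gb, m_st[slot], v_st[slot], lr, beta1, beta2, t);
      net.cl[i].bn_beta = bv.col(0);
      ++slot;
      adam_update(net.cl[i].W, g_W[i], m_st[slot], v_st[slot], lr, beta1,
                  beta2, t);
      ++slot;
      mat cb(net.cl[i].b);
      adam_update(cb, g_b[i], m_st[slot], v_st[slot], lr, beta1, beta2, t);
      net.cl[i].b = cb.col(0);
      ++slot;
    }
    adam_update(net.fc1_W, g_fc1_W, m_st[slot], v_st[slot], lr, beta1, beta2, t);
    ++slot;
    {
      mat b1v(net.fc1_b);
      adam_update(b1v, g_fc1_b, m_st[slot], v_st[slot], lr, beta1, beta2, t);
      net.fc1_b = b1v.col(0);
      ++slot;
    }
    adam_update(net.fc2_W, g_fc2_W, m_st[slot], v_st[slot], lr, beta1, beta2, t);
    ++slot;
    {
      mat b2v(net.fc2_b);
      adam_update(b2v, g_fc2_b, m_st[slot], v_st[slot], lr, beta1, beta2, t);
      net.fc2_b = b2v.col(0);
    }
    if (step % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["params"] = net_to_list(net),
                      _["loss_trace"] = loss_trace);
}

// ---------------------------------------------------------------------------
// prediction

// Returns an N x T matrix of true-class softmax probabilities; when
// dropout_active is false the passes are deterministic (column-identical).
// [[Rcpp::export]]
arma::mat cpp_cnn_predict(const List& params, const List& arch,
                          const arma::cube& X, bool dropout_active, int T,
                          int seed) {
  const int side = X.n_rows;
  Net net = net_from_list(params, arch, side);
  const int N = X.n_slices;
  std::mt19937 rng(seed);
  mat out(N, T);
  for (int t = 0; t < T; ++t) {
    mat P = net_forward(net, X, N, false, dropout_active, rng, nullptr);
    out.col(t) = P.col(1);
    if (!dropout_active) {
      for (int tt = 1; tt < T; ++tt) out.col(tt) = out.col(0);
      break;
    }
  }
  return out;
}

// Full softmax matrix of a deterministic pass (both class columns).
// [[Rcpp::export]]
arma::mat cpp_cnn_predict_probs(const List& params, const List& arch,
                                const arma::cube& X) {
  const int side = X.n_rows;
  Net net = net_from_list(params, arch, side);
  std::mt19937 rng(0);
  return net_forward(net, X, X.n_slices, false, false, rng, nullptr);
}
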