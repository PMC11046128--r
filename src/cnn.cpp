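// Compact CNN for single-channel square images:
//   conv3x3(c1) -> ReLU -> maxpool2 -> conv3x3(c2) -> ReLU -> maxpool2
//   -> global average pool -> dense(1) -> sigmoid, binary cross-entropy,
// trained with Adam. Feature maps are stored as (channels x pixels) matrices
// with column-major spatial indexing p = r + c * side. All randomness
// (weight init, epoch permutations) is injected from R for reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// im2col for 3x3 same-padding convolution over C channel maps of side S
void im2col3(const mat& maps, int S, mat& out) {
  const int C = maps.n_rows;
  const int P = S * S;
  out.zeros(9 * C, P);
  for (int c = 0; c < S; ++c) {
    for (int r = 0; r < S; ++r) {
      const int p = r + c * S;
      for (int dc = -1; dc <= 1; ++dc) {
        const int cc = c + dc;
        if (cc < 0 || cc >= S) continue;
        for (int dr = -1; dr <= 1; ++dr) {
          const int rr = r + dr;
          if (rr < 0 || rr >= S) continue;
          const int q = rr + cc * S;
          const int krow = (dr + 1) + (dc + 1) * 3;
          for (int k = 0; k < C; ++k) {
            out(k * 9 + krow, p) = maps(k, q);
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col3
void col2im3(const mat& cols, int S, int C, mat& maps) {
  maps.zeros(C, S * S);
  for (int c = 0; c < S; ++c) {
    for (int r = 0; r < S; ++r) {
      const int p = r + c * S;
      for (int dc = -1; dc <= 1; ++dc) {
        const int cc = c + dc;
        if (cc < 0 || cc >= S) continue;
        for (int dr = -1; dr <= 1; ++dr) {
          const int rr = r + dr;
          if (rr < 0 || rr >= S) continue;
          const int q = rr + cc * S;
          const int krow = (dr + 1) + (dc + 1) * 3;
          for (int k = 0; k < C; ++k) {
            maps(k, q) += cols(k * 9 + krow, p);
          }
        }
      }
    }
  }
}

void maxpool2(const mat& maps, int S, mat& out, umat& argmax) {
  const int H = S / 2;
  const int C = maps.n_rows;
  out.set_size(C, H * H);
  argmax.set_size(C, H * H);
  for (int c2 = 0; c2 < H; ++c2) {
    for (int r2 = 0; r2 < H; ++r2) {
      const int po = r2 + c2 * H;
      const int base_r = 2 * r2, base_c = 2 * c2;
      const int idx[4] = {base_r + base_c * S, base_r + 1 + base_c * S,
                          base_r + (base_c + 1) * S,
                          base_r + 1 + (base_c + 1) * S};
      for (int k = 0; k < C; ++k) {
        double best = maps(k, idx[0]);
        int bi = idx[0];
        for (int j = 1; j < 4; ++j) {
          if (maps(k, idx[j]) > best) { best = maps(k, idx[j]); bi = idx[j]; }
        }
        out(k, po) = best;
        argmax(k, po) = bi;
      }
    }
  }
}

struct Params {
  mat W1, W2;
  vec b1, b2, wd;
  double bd;
};

struct Cache {
  mat col1, Z1, P1, col2, Z2, P2;
  umat am1, am2;
  vec g;
  double z;
};

double forward(const Params& th, const rowvec& xrow, int S, Cache& ca) {
  const int S2 = S / 2, S4 = S / 4;
  mat img(xrow.t());
  img.reshape(S * S, 1);
  mat maps0 = img.t();                       // 1 x P
  im2col3(maps0, S, ca.col1);
  ca.Z1 = th.W1 * ca.col1;
  ca.Z1.each_col() += th.b1;
  mat A1 = clamp(ca.Z1, 0.0, datum::inf);
  maxpool2(A1, S, ca.P1, ca.am1);
  im2col3(ca.P1, S2, ca.col2);
  ca.Z2 = th.W2 * ca.col2;
  ca.Z2.each_col() += th.b2;
  mat A2 = clamp(ca.Z2, 0.0, datum::inf);
  maxpool2(A2, S2, ca.P2, ca.am2);
  ca.g = mean(ca.P2, 1);
  ca.z = dot(th.wd, ca.g) + th.bd;
  return 1.0 / (1.0 + std::exp(-ca.z));
}

void backward(const Params& th, const Cache& ca, double dz, int S,
              Params& gr) {
  const int S2 = S / 2, S4 = S / 4;
  // dense
  gr.wd += dz * ca.g;
  gr.bd += dz;
  // GAP
  vec dg = dz * th.wd;
  mat dP2(ca.P2.n_rows, ca.P2.n_cols);
  dP2.each_col() = dg / double(S4 * S4);
  // pool2 -> A2
  mat dA2(ca.Z2.n_rows, ca.Z2.n_cols, fill::zeros);
  for (uword k = 0; k < dP2.n_rows; ++k) {
    for (uword p = 0; p < dP2.n_cols; ++p) {
      dA2(k, ca.am2(k, p)) += dP2(k, p);
    }
  }
  mat dZ2 = dA2 % conv_to<mat>::from(ca.Z2 > 0);
  gr.W2 += dZ2 * ca.col2.t();
  gr.b2 += sum(dZ2, 1);
  mat dcol2 = th.W2.t() * dZ2;
  mat dP1;
  col2im3(dcol2, S2, ca.P1.n_rows, dP1);
  mat dA1(ca.Z1.n_rows, ca.Z1.n_cols, fill::zeros);
  for (uword k = 0; k < dP1.n_rows; ++k) {
    for (uword p = 0; p < dP1.n_cols; ++p) {
      dA1(k, ca.am1(k, p)) += dP1(k, p);
    }
  }
  mat dZ1 = dA1 % conv_to<mat>::from(ca.Z1 > 0);
  gr.W1 += dZ1 * ca.col1.t();
  gr.b1 += sum(dZ1, 1);
}

double bce(double p, double y) {
  const double eps = 1e-12;
  return -(y * std::log(p + eps) + (1.0 - y) * std::log(1.0 - p + eps));
}

struct Adam {
  Params m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Params& th) {
    m.W1.zeros(size(th.W1)); m.W2.zeros(size(th.W2));
    m.b1.zeros(size(th.b1)); m.b2.zeros(size(th.b2));
    m.wd.zeros(size(th.wd)); m.bd = 0;
    v = m;
  }
  void step(Params& th, const Params& g, double lr) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    auto upd = [&](mat& p, mat& mm, mat& vv, const mat& gg) {
      mm = b1 * mm + (1 - b1) * gg;
      vv = b2 * vv + (1 - b2) * (gg % gg);
      p -= lr * (mm / c1) / (sqrt(vv / c2) + eps);
    };
    auto updv = [&](vec& p, vec& mm, vec& vv, const vec& gg) {
      mm = b1 * mm + (1 - b1) * gg;
      vv = b2 * vv + (1 - b2) * (gg % gg);
      p -= lr * (mm / c1) / (sqrt(vv / c2) + eps);
    };
    upd(th.W1, m.W1, v.W1, g.W1);
    upd(th.W2, m.W2, v.W2, g.W2);
    updv(th.b1, m.b1, v.b1, g.b1);
    updv(th.b2, m.b2, v.b2, g.b2);
    updv(th.wd, m.wd, v.wd, g.wd);
    m.bd = b1 * m.bd + (1 - b1) * g.bd;
    v.bd = b2 * v.bd + (1 - b2) * g.bd * g.bd;
    th.bd -= lr * (m.bd / c1) / (std::sqrt(v.bd / c2) + eps);
  }
};

Params params_from_list(const Rcpp::List& w) {
  Params th;
  th.W1 = Rcpp::as<mat>(w["W1"]);
  th.b1 = Rcpp::as<vec>(w["b1"]);
  th.W2 = Rcpp::as<mat>(w["W2"]);
  th.b2 = Rcpp::as<vec>(w["b2"]);
  th.wd = Rcpp::as<vec>(w["wd"]);
  th.bd = Rcpp::as<double>(w["bd"]);
  return th;
}

Rcpp::List params_to_list(const Params& th) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = th.W1, Rcpp::Named("b1") = th.b1,
      Rcpp::Named("W2") = th.W2, Rcpp::Named("b2") = th.b2,
      Rcpp::Named("wd") = th.wd, Rcpp::Named("bd") = th.bd);
}

double dataset_loss(const Params& th, const mat& X, const vec& y, int S,
                    Cache& ca) {
  double total = 0;
  for (uword i = 0; i < X.n_rows; ++i) {
    total += bce(forward(th, X.row(i), S, ca), y(i));
  }
  return total / X.n_rows;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(const arma::mat& X, const arma::vec& y,
                         const arma::mat& Xval, const arma::vec& yval,
                         int side, int epochs, int batch, double lr,
                         const Rcpp::List& init,
                         const arma::umat& perms) {
  if (side % 4 != 0) Rcpp::stop("image side must be divisible by 4");
  Params th = params_from_list(init);
  Adam adam;
  adam.init(th);
  Cache ca;
  Params best = th;
  vec val_loss(epochs), train_loss(epochs);
  double best_val = datum::inf;
  int best_epoch = 0;
  const uword n = X.n_rows;
  for (int e = 0; e < epochs; ++e) {
    double ep_loss = 0;
    uword done = 0;
    while (done < n) {
      const uword b = std::min<uword>(batch, n - done);
      Params gr;
      gr.W1.zeros(size(th.W1)); gr.W2.zeros(size(th.W2));
      gr.b1.zeros(size(th.b1)); gr.b2.zeros(size(th.b2));
      gr.wd.zeros(size(th.wd)); gr.bd = 0;
      double bloss = 0;
      for (uword j = 0; j < b; ++j) {
        const uword i = perms(e, done + j) - 1;  // R indices are 1-based
        const double p = forward(th, X.row(i), side, ca);
        bloss += bce(p, y(i));
        backward(th, ca, (p - y(i)) / double(b), side, gr);
      }
      bloss /= b;
      if (!std::isfinite(bloss)) {
        Rcpp::stop("non-finite training loss at epoch %d (diverged; lower "
                   "the learning rate)", e + 1);
      }
      ep_loss += bloss * b;
      adam.step(th, gr, lr);
      done += b;
    }
    train_loss(e) = ep_loss / n;
    val_loss(e) = dataset_loss(th, Xval, yval, side, ca);
    if (val_loss(e) < best_val) {
      best_val = val_loss(e);
      best = th;
      best_epoch = e + 1;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = params_to_list(best),
      Rcpp::Named("final_weights") = params_to_list(th),
      Rcpp::Named("selected_epoch") = best_epoch,
      Rcpp::Named("val_loss") = val_loss,
      Rcpp::Named("train_loss") = train_loss);
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
arma::vec cnn_predict_cpp(const Rcpp::List& weights, const arma::mat& X,
                          int side) {
  Params th = params_from_list(weights);
  Cache ca;
  vec out(X.n_rows);
  for (uword i = 0; i < X.n_rows; ++i) {
    out(i) = forward(th, X.row(i), side, ca);
  }
  return out;
}
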