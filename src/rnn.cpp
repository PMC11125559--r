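// Continuous-time RNN core: Euler forward simulation, BPTT gradients,
// Adam training loop, and fixed-point search by speed minimization.
//
// Dynamics (time in units of tau, gamma = dt/tau):
//   x[t] = x[t-1] + gamma * (-x[t-1] + J r[t-1] + B u[t] + b + eta[t])
//   r = tanh(x),  z[t] = W r[t] + c
// Noise eta is drawn per unit per step (sd = noise_sd) and enters the
// right-hand side of the ODE, i.e. it is multiplied by gamma in the
// update — the literal Euler discretization of the model equation.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

namespace {

struct TrialBatch {
  arma::uvec item1, item2;   // 0-based item indices
  arma::uvec p1, p2;         // 1-based pulse steps
  int T;
};

// forward pass storing rates at every step; R0 = tanh(x0) replicated.
// Xs (optional, n x M x (T+1)) stores x including x[0] at slice 0.
void forward(const arma::mat& J, const arma::mat& B, const arma::mat& W,
             const arma::vec& b, const arma::vec& c, const arma::vec& x0,
             const arma::mat& panel_t,   // N_in x n_items
             const TrialBatch& tb, double gamma, double noise_sd,
             std::mt19937_64* rng,
             arma::cube& Rs,             // N x M x (T+1)
             arma::cube& Z,              // Nout x M x T
             arma::cube* Xs) {
  const int N = J.n_rows, M = tb.item1.n_elem, T = tb.T;
  arma::mat X(N, M);
  X.each_col() = x0;
  arma::mat Rt = arma::tanh(X);
  Rs.slice(0) = Rt;
  if (Xs) Xs->slice(0) = X;
  std::normal_distribution<double> nd(0.0, 1.0);
  for (int t = 1; t <= T; ++t) {
    arma::mat drive = J * Rt;
    drive.each_col() += b;
    for (int m = 0; m < M; ++m) {
      if ((int)tb.p1[m] == t) drive.col(m) += B * panel_t.col(tb.item1[m]);
      if ((int)tb.p2[m] == t) drive.col(m) += B * panel_t.col(tb.item2[m]);
    }
    if (noise_sd > 0 && rng) {
      for (arma::uword i = 0; i < drive.n_elem; ++i)
        drive[i] += noise_sd * nd(*rng);
    }
    X += gamma * (-X + drive);
    Rt = arma::tanh(X);
    Rs.slice(t) = Rt;
    if (Xs) Xs->slice(t) = X;
    arma::mat zt = W * Rt;
    zt.each_col() += c;
    Z.slice(t - 1) = zt;
  }
}

// piecewise-constant targets: rest unit (row 2) = z_active for t <= p2,
// correct choice unit = z_active for t > p2.
arma::cube targets(const TrialBatch& tb, const arma::uvec& correct1,
                   double z_active, int Nout) {
  const int M = tb.item1.n_elem, T = tb.T;
  arma::cube Zh(Nout, M, T, arma::fill::zeros);
  for (int m = 0; m < M; ++m) {
    int cu = correct1[m] ? 0 : 1;
    for (int t = 1; t <= T; ++t) {
      if (t <= (int)tb.p2[m]) Zh(2, m, t - 1) = z_active;
      else Zh(cu, m, t - 1) = z_active;
    }
  }
  return Zh;
}

// response rule: first of ztilde_1, ztilde_2 to reach `thresh` during the
// choice period (t > p2); ties broken by the larger ztilde. Returns choice
// (1/2, 0 = no response) and crossing step.
void decide_trial(const arma::cube& Z, int m, int p2, int T,
                  double z_active, double thresh,
                  int& choice, int& step) {
  choice = 0; step = -1;
  for (int t = p2 + 1; t <= T; ++t) {
    double z1 = 0.5 * std::tanh(Z(0, m, t - 1) - z_active / 2.0) + 0.5;
    double z2 = 0.5 * std::tanh(Z(1, m, t - 1) - z_active / 2.0) + 0.5;
    bool c1 = z1 >= thresh, c2 = z2 >= thresh;
    if (c1 || c2) {
      if (c1 && c2) choice = (z1 >= z2) ? 1 : 2;
      else choice = c1 ? 1 : 2;
      step = t;
      return;
    }
  }
}

struct Grads {
  arma::mat J, B, W;
  arma::vec b, c, x0;
};

// BPTT for the full objective E = E_task + alpha R_L2 + beta R_FR.
// Returns loss components via refs.
Grads backward(const arma::mat& J, const arma::mat& B, const arma::mat& W,
               const arma::mat& panel_t, const TrialBatch& tb,
               const arma::cube& Rs, const arma::cube& Z,
               const arma::cube& Zh, double gamma, double alpha, double beta,
               double& e_task, double& r_l2, double& r_fr) {
  const int N = J.n_rows, M = tb.item1.n_elem, T = tb.T;
  const int Nout = Z.n_rows;
  const double wz = 1.0 / ((double)M * T * Nout);
  const double wr = 1.0 / ((double)M * T * N);
  Grads g;
  g.J.zeros(N, N); g.B.zeros(N, B.n_cols); g.W.zeros(Nout, N);
  g.b.zeros(N); g.c.zeros(Nout); g.x0.zeros(N);
  e_task = 0.0; r_fr = 0.0;
  arma::mat delta(N, M, arma::fill::zeros);  // dE/dx[t+1] carried backward
  for (int t = T; t >= 1; --t) {
    const arma::mat& Rt = Rs.slice(t);
    arma::mat dz = 2.0 * wz * (Z.slice(t - 1) - Zh.slice(t - 1));
    e_task += 0.5 * arma::accu(dz % (Z.slice(t - 1) - Zh.slice(t - 1)));
    r_fr += wr * gamma * arma::accu(Rt % Rt);
    g.W += dz * Rt.t();
    g.c += arma::sum(dz, 1);
    arma::mat dr = W.t() * dz + (2.0 * beta * wr * gamma) * Rt;
    dr += J.t() * (gamma * delta);
    arma::mat dx = (1.0 - Rt % Rt) % dr + (1.0 - gamma) * delta;
    // contributions of step t's update to J, B, b (uses r[t-1], u[t])
    g.J += (gamma * dx) * Rs.slice(t - 1).t();
    g.b += gamma * arma::sum(dx, 1);
    for (int m = 0; m < M; ++m) {
      if ((int)tb.p1[m] == t)
        g.B += (gamma * dx.col(m)) * panel_t.col(tb.item1[m]).t();
      if ((int)tb.p2[m] == t)
        g.B += (gamma * dx.col(m)) * panel_t.col(tb.item2[m]).t();
    }
    delta = dx;
  }
  // through r[0] = tanh(x0)
  const arma::mat& R0 = Rs.slice(0);
  arma::mat dr0 = J.t() * (gamma * delta);
  arma::mat dx0 = (1.0 - R0 % R0) % dr0 + (1.0 - gamma) * delta;
  g.x0 = arma::sum(dx0, 1);
  // per-element means: a raw sum over the 10^4 entries of B would swamp
  // E_task at alpha = 1 and make the highest regime untrainable
  r_l2 = arma::accu(B % B) / B.n_elem + arma::accu(W % W) / W.n_elem;
  g.B += (2.0 * alpha / B.n_elem) * B;
  g.W += (2.0 * alpha / W.n_elem) * W;
  return g;
}

TrialBatch as_batch(const arma::uvec& item1, const arma::uvec& item2,
                    const arma::uvec& p1, const arma::uvec& p2, int T) {
  TrialBatch tb; tb.item1 = item1; tb.item2 = item2;
  tb.p1 = p1; tb.p2 = p2; tb.T = T;
  return tb;
}

struct Adam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  std::vector<arma::mat> m, v;
  explicit Adam(double lr_) : lr(lr_) {}
  void init(const std::vector<arma::mat*>& params) {
    for (auto* p : params) {
      m.emplace_back(arma::size(*p), arma::fill::zeros);
      v.emplace_back(arma::size(*p), arma::fill::zeros);
    }
  }
  void step(std::vector<arma::mat*>& params, std::vector<arma::mat>& grads) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * grads[i];
      v[i] = b2 * v[i] + (1 - b2) * (grads[i] % grads[i]);
      *params[i] -= lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + eps);
    }
  }
};

} // namespace

// [[Rcpp::export]]
List rnn_forward_cpp(const arma::mat& J, const arma::mat& B,
                     const arma::mat& W, const arma::vec& b,
                     const arma::vec& c, const arma::vec& x0,
                     const arma::mat& panel_t,
                     const arma::uvec& item1, const arma::uvec& item2,
                     const arma::uvec& p1, const arma::uvec& p2, int T,
                     double gamma, double noise_sd, bool return_state,
                     unsigned long seed) {
  TrialBatch tb = as_batch(item1, item2, p1, p2, T);
  const int N = J.n_rows, M = item1.n_elem;
  arma::cube Rs(N, M, T + 1), Z(W.n_rows, M, T);
  std::mt19937_64 rng(seed);
  if (return_state) {
    arma::cube Xs(N, M, T + 1);
    forward(J, B, W, b, c, x0, panel_t, tb, gamma, noise_sd,
            noise_sd > 0 ? &rng : nullptr, Rs, Z, &Xs);
    return List::create(_["Z"] = Z, _["X"] = Xs);
  }
  forward(J, B, W, b, c, x0, panel_t, tb, gamma, noise_sd,
          noise_sd > 0 ? &rng : nullptr, Rs, Z, nullptr);
  return List::create(_["Z"] = Z);
}

// Loss and gradients for one (noise-free unless noise_sd>0) batch.
// [[Rcpp::export]]
List rnn_loss_grad_cpp(const arma::mat& J, const arma::mat& B,
                       const arma::mat& W, const arma::vec& b,
                       const arma::vec& c, const arma::vec& x0,
                       const arma::mat& panel_t,
                       const arma::uvec& item1, const arma::uvec& item2,
                       const arma::uvec& p1, const arma::uvec& p2, int T,
                       const arma::uvec& correct1,
                       double gamma, double alpha, double beta,
                       double z_active) {
  TrialBatch tb = as_batch(item1, item2, p1, p2, T);
  const int N = J.n_rows, M = item1.n_elem;
  arma::cube Rs(N, M, T + 1), Z(W.n_rows, M, T);
  forward(J, B, W, b, c, x0, panel_t, tb, gamma, 0.0, nullptr, Rs, Z, nullptr);
  arma::cube Zh = targets(tb, correct1, z_active, W.n_rows);
  double e_task, r_l2, r_fr;
  Grads g = backward(J, B, W, panel_t, tb, Rs, Z, Zh, gamma, alpha, beta,
                     e_task, r_l2, r_fr);
  return List::create(
    _["E_task"] = e_task, _["R_L2"] = r_l2, _["R_FR"] = r_fr,
    _["E"] = e_task + alpha * r_l2 + beta * r_fr,
    _["gJ"] = g.J, _["gB"] = g.B, _["gW"] = g.W,
    _["gb"] = g.b, _["gc"] = g.c, _["gx0"] = g.x0);
}

// Noise-free evaluation: per-trial choice (0/1/2) and crossing step.
// [[Rcpp::export]]
List rnn_decide_cpp(const arma::mat& J, const arma::mat& B,
                    const arma::mat& W, const arma::vec& b,
                    const arma::vec& c, const arma::vec& x0,
                    const arma::mat& panel_t,
                    const arma::uvec& item1, const arma::uvec& item2,
                    const arma::uvec& p1, const arma::uvec& p2, int T,
                    double gamma, double noise_sd, double z_active,
                    double thresh, unsigned long seed) {
  TrialBatch tb = as_batch(item1, item2, p1, p2, T);
  const int N = J.n_rows, M = item1.n_elem;
  arma::cube Rs(N, M, T + 1), Z(W.n_rows, M, T);
  std::mt19937_64 rng(seed);
  forward(J, B, W, b, c, x0, panel_t, tb, gamma, noise_sd,
          noise_sd > 0 ? &rng : nullptr, Rs, Z, nullptr);
  IntegerVector choice(M), step(M);
  for (int m = 0; m < M; ++m) {
    int ch, st;
    decide_trial(Z, m, tb.p2[m], T, z_active, thresh, ch, st);
    choice[m] = ch; step[m] = st;
  }
  return List::create(_["choice"] = choice, _["step"] = step);
}

// Full training loop: Adam + BPTT with trainability mask and stopping rules.
// eval sets: list of lists(item1, item2, p1, p2, T, correct1); stop when
// every eval trial is answered correctly noise-free, or E_task < etask_stop,
// or max_epochs.
// [[Rcpp::export]]
List rnn_train_cpp(arma::mat J, arma::mat B, arma::mat W,
                   arma::vec b, arma::vec c, arma::vec x0,
                   const arma::mat& panel_t,
                   const arma::uvec& tr_item1, const arma::uvec& tr_item2,
                   const arma::uvec& tr_correct1,
                   int p1_step, int p2_min, int p2_max, int T,
                   List eval_sets,
                   LogicalVector mask,  // J, B, W, biases, x0
                   double gamma, double alpha, double beta,
                   double noise_sd, double z_active, double thresh,
                   int batch_size, int max_epochs, double lr,
                   double etask_stop, int eval_every, unsigned long seed) {
  std::mt19937_64 rng(seed);
  std::uniform_int_distribution<int> pick(0, tr_item1.n_elem - 1);
  std::uniform_int_distribution<int> pdelay(p2_min, p2_max);

  // vectors live as single-column mats so one Adam handles every block
  arma::mat bmat = b, cmat = c, x0mat = x0;
  std::vector<arma::mat*> params = {&J, &B, &W, &bmat, &cmat, &x0mat};
  Adam opt(lr);
  opt.init(params);

  const int n_eval = eval_sets.size();
  std::vector<TrialBatch> evb(n_eval);
  std::vector<arma::uvec> evc(n_eval);
  for (int e = 0; e < n_eval; ++e) {
    List es = eval_sets[e];
    evb[e] = as_batch(as<arma::uvec>(es["item1"]), as<arma::uvec>(es["item2"]),
                      as<arma::uvec>(es["p1"]), as<arma::uvec>(es["p2"]),
                      as<int>(es["T"]));
    evc[e] = as<arma::uvec>(es["correct1"]);
  }

  auto all_correct = [&]() -> bool {
    for (int e = 0; e < n_eval; ++e) {
      const TrialBatch& tb = evb[e];
      const int M = tb.item1.n_elem;
      arma::cube Rs(J.n_rows, M, tb.T + 1), Z(W.n_rows, M, tb.T);
      forward(J, B, W, bmat.col(0), cmat.col(0), x0mat.col(0), panel_t, tb,
              gamma, 0.0, nullptr, Rs, Z, nullptr);
      for (int m = 0; m < M; ++m) {
        int ch, st;
        decide_trial(Z, m, tb.p2[m], tb.T, z_active, thresh, ch, st);
        if (ch == 0 || (unsigned)ch != (evc[e][m] ? 1u : 2u)) return false;
      }
    }
    return true;
  };

  std::vector<double> tr_etask, tr_total;
  tr_etask.reserve(max_epochs); tr_total.reserve(max_epochs);
  std::string stop_reason = "epoch-cap";
  int epoch = 0;
  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    // sample batch
    arma::uvec it1(batch_size), it2(batch_size), bp1(batch_size),
               bp2(batch_size), cor1(batch_size);
    for (int m = 0; m < batch_size; ++m) {
      int k = pick(rng);
      it1[m] = tr_item1[k]; it2[m] = tr_item2[k]; cor1[m] = tr_correct1[k];
      bp1[m] = p1_step;
      bp2[m] = (p2_min == p2_max) ? p2_min : pdelay(rng);
    }
    TrialBatch tb = as_batch(it1, it2, bp1, bp2, T);
    const int N = J.n_rows, M = batch_size;
    arma::cube Rs(N, M, T + 1), Z(W.n_rows, M, T);
    forward(J, B, W, bmat.col(0), cmat.col(0), x0mat.col(0), panel_t, tb,
            gamma, noise_sd, noise_sd > 0 ? &rng : nullptr, Rs, Z, nullptr);
    arma::cube Zh = targets(tb, cor1, z_active, W.n_rows);
    double e_task, r_l2, r_fr;
    Grads g = backward(J, B, W, panel_t, tb, Rs, Z, Zh, gamma, alpha, beta,
                       e_task, r_l2, r_fr);
    double total = e_task + alpha * r_l2 + beta * r_fr;
    if (!std::isfinite(total))
      stop("training error: non-finite loss at epoch %d", epoch);
    tr_etask.push_back(e_task);
    tr_total.push_back(total);

    std::vector<arma::mat> grads = {g.J, g.B, g.W, arma::mat(g.b),
                                    arma::mat(g.c), arma::mat(g.x0)};
    if (!mask[0]) grads[0].zeros();
    if (!mask[1]) grads[1].zeros();
    if (!mask[2]) grads[2].zeros();
    if (!mask[3]) { grads[3].zeros(); grads[4].zeros(); }
    if (!mask[4]) grads[5].zeros();
    opt.step(params, grads);

    if (e_task < etask_stop) { stop_reason = "task-loss"; break; }
    if (epoch % eval_every == 0 && all_correct()) {
      stop_reason = "all-correct"; break;
    }
  }
  if (epoch > max_epochs) epoch = max_epochs;
  return List::create(
    _["J"] = J, _["B"] = B, _["W"] = W,
    _["b"] = arma::vec(bmat.col(0)), _["c"] = arma::vec(cmat.col(0)),
    _["x0"] = arma::vec(x0mat.col(0)),
    _["epochs"] = epoch, _["stop_reason"] = stop_reason,
    _["E_task_trace"] = tr_etask, _["E_trace"] = tr_total);
}

// Fixed-point search: Adam minimization of speed q(x) = mean(F(x)^2),
// F = (-x + J tanh(x) + b) / tau, vectorized over candidate columns.
// Optional Newton polish afterwards improves precision of converged points.
// [[Rcpp::export]]
List fp_find_cpp(const arma::mat& J, const arma::vec& b, arma::mat X,
                 double tau, double lr, int max_iter, int patience,
                 bool newton_polish) {
  const int N = J.n_rows, K = X.n_cols;
  arma::mat M1(arma::size(X), arma::fill::zeros),
            V1(arma::size(X), arma::fill::zeros);
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  auto speed = [&](const arma::mat& Xc) {
    arma::mat R = arma::tanh(Xc);
    arma::mat F = (-Xc + J * R);
    F.each_col() += b;
    F /= tau;
    return arma::rowvec(arma::mean(F % F, 0));
  };
  double best = arma::datum::inf;
  int since = 0;
  for (int it = 1; it <= max_iter; ++it) {
    arma::mat R = arma::tanh(X);
    arma::mat F = (-X + J * R);
    F.each_col() += b;
    F /= tau;
    double q = arma::mean(arma::mean(F % F, 0));
    if (q < best - 1e-16) { best = q; since = 0; } else if (++since >= patience) break;
    arma::mat G = (2.0 / (N * tau)) * (-F + (1.0 - R % R) % (J.t() * F));
    double c1 = 1.0 - std::pow(b1, (double)it);
    double c2 = 1.0 - std::pow(b2, (double)it);
    M1 = b1 * M1 + (1 - b1) * G;
    V1 = b2 * V1 + (1 - b2) * (G % G);
    X -= lr * (M1 / c1) / (arma::sqrt(V1 / c2) + eps);
  }
  if (newton_polish) {
    for (int k = 0; k < K; ++k) {
      arma::vec x = X.col(k);
      for (int it = 0; it < 50; ++it) {
        arma::vec r = arma::tanh(x);
        arma::vec F = (-x + J * r + b) / tau;
        if (arma::norm(F, "inf") < 1e-13) break;
        arma::mat Jf = (J * arma::diagmat(1.0 - r % r) -
                        arma::eye(N, N)) / tau;
        arma::vec dx;
        bool ok = arma::solve(dx, Jf, -F, arma::solve_opts::no_approx);
        if (!ok || !dx.is_finite()) break;
        if (arma::norm(dx) > 1.0) dx *= 1.0 / arma::norm(dx);
        x += dx;
      }
      // keep the polished point only if it did not move away/diverge
      arma::vec r = arma::tanh(x);
      arma::vec F = (-x + J * r + b) / tau;
      double qk = arma::mean(arma::square(F));
      arma::vec r0 = arma::tanh(X.col(k));
      arma::vec F0 = (-X.col(k) + J * r0 + b) / tau;
      if (qk < arma::mean(arma::square(F0))) X.col(k) = x;
    }
  }
  return List::create(_["X"] = X, _["speed"] = arma::vec(speed(X).t()));
}
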