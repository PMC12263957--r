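// Core numerics for the PV-RNN: multi-timescale recurrent dynamics with
// Gaussian latent variables, normalized free energy, reverse-mode gradients
// (BPTT), full-batch Adam training, and the sliding-window inner optimization
// used during online inference. All stochastic draws go through R's RNG so
// that set.seed() at the R level controls every source of randomness.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace {

const double SIG_CLAMP = 10.0;  // bound on the argument of exp() for sigma

struct Net {
  int L;
  arma::ivec nd, nz;
  vec tau;
  // all tensors stored as mat (biases are n x 1) so they can be handled
  // uniformly by the optimizer
  std::vector<mat> Wdd, Wzd, Wtd, Wbu, bh, Wmu, Wsg, bmup, bsgp, bmuq, bsgq;
  mat Wout, bout;
};

Net netFromList(const List& params, const List& spec) {
  Net n;
  n.nd = as<arma::ivec>(spec["n_d"]);
  n.nz = as<arma::ivec>(spec["n_z"]);
  n.tau = as<vec>(spec["tau"]);
  n.L = n.nd.n_elem;
  List Wdd = params["W_dd"], Wzd = params["W_zd"], Wtd = params["W_td"],
       Wbu = params["W_bu"], bh = params["b_h"], Wmu = params["W_mu"],
       Wsg = params["W_sg"], bmup = params["b_mu_p"], bsgp = params["b_sg_p"],
       bmuq = params["b_mu_q"], bsgq = params["b_sg_q"];
  for (int l = 0; l < n.L; ++l) {
    n.Wdd.push_back(as<mat>(Wdd[l]));
    n.Wzd.push_back(as<mat>(Wzd[l]));
    n.Wtd.push_back(as<mat>(Wtd[l]));
    n.Wbu.push_back(as<mat>(Wbu[l]));
    n.bh.push_back(as<mat>(bh[l]));
    n.Wmu.push_back(as<mat>(Wmu[l]));
    n.Wsg.push_back(as<mat>(Wsg[l]));
    n.bmup.push_back(as<mat>(bmup[l]));
    n.bsgp.push_back(as<mat>(bsgp[l]));
    n.bmuq.push_back(as<mat>(bmuq[l]));
    n.bsgq.push_back(as<mat>(bsgq[l]));
  }
  n.Wout = as<mat>(params["W_out"]);
  n.bout = as<mat>(params["b_out"]);
  return n;
}

List netToList(const Net& n) {
  List Wdd(n.L), Wzd(n.L), Wtd(n.L), Wbu(n.L), bh(n.L), Wmu(n.L), Wsg(n.L),
      bmup(n.L), bsgp(n.L), bmuq(n.L), bsgq(n.L);
  for (int l = 0; l < n.L; ++l) {
    Wdd[l] = n.Wdd[l]; Wzd[l] = n.Wzd[l]; Wtd[l] = n.Wtd[l]; Wbu[l] = n.Wbu[l];
    bh[l] = n.bh[l]; Wmu[l] = n.Wmu[l]; Wsg[l] = n.Wsg[l];
    bmup[l] = n.bmup[l]; bsgp[l] = n.bsgp[l]; bmuq[l] = n.bmuq[l]; bsgq[l] = n.bsgq[l];
  }
  return List::create(
      _["W_dd"] = Wdd, _["W_zd"] = Wzd, _["W_td"] = Wtd, _["W_bu"] = Wbu,
      _["b_h"] = bh, _["W_mu"] = Wmu, _["W_sg"] = Wsg,
      _["b_mu_p"] = bmup, _["b_sg_p"] = bsgp,
      _["b_mu_q"] = bmuq, _["b_sg_q"] = bsgq,
      _["W_out"] = n.Wout, _["b_out"] = n.bout);
}

std::vector<mat*> tensors(Net& n) {
  std::vector<mat*> out;
  for (int l = 0; l < n.L; ++l) {
    out.push_back(&n.Wdd[l]); out.push_back(&n.Wzd[l]);
    out.push_back(&n.Wtd[l]); out.push_back(&n.Wbu[l]);
    out.push_back(&n.bh[l]);  out.push_back(&n.Wmu[l]);
    out.push_back(&n.Wsg[l]); out.push_back(&n.bmup[l]);
    out.push_back(&n.bsgp[l]); out.push_back(&n.bmuq[l]);
    out.push_back(&n.bsgq[l]);
  }
  out.push_back(&n.Wout); out.push_back(&n.bout);
  return out;
}

Net zerosLike(const Net& n) {
  Net z = n;
  for (mat* t : tensors(z)) t->zeros();
  return z;
}

// ---- forward / free energy ------------------------------------------------

struct Cache {
  int Tw = -1, RX = -1;
  // per layer, columns indexed by window step
  std::vector<mat> h, d, mup, sgp, muq, sgq, z, asp, asq;  // as*: raw sigma preacts
  mat xbar;  // RX x Tw

  // (re)allocate only when the geometry changes, so repeated passes over the
  // same window reuse their buffers
  void ensure(const Net& net, int Tw_) {
    if (Tw == Tw_ && RX == (int)net.Wout.n_rows &&
        (int)h.size() == net.L) return;
    const int L = net.L;
    Tw = Tw_;
    RX = net.Wout.n_rows;
    h.assign(L, mat()); d.assign(L, mat());
    mup.assign(L, mat()); sgp.assign(L, mat());
    muq.assign(L, mat()); sgq.assign(L, mat());
    z.assign(L, mat()); asp.assign(L, mat()); asq.assign(L, mat());
    for (int l = 0; l < L; ++l) {
      h[l].set_size(net.nd[l], Tw); d[l].set_size(net.nd[l], Tw);
      mup[l].set_size(net.nz[l], Tw); sgp[l].set_size(net.nz[l], Tw);
      muq[l].set_size(net.nz[l], Tw); sgq[l].set_size(net.nz[l], Tw);
      z[l].set_size(net.nz[l], Tw);
      asp[l].set_size(net.nz[l], Tw); asq[l].set_size(net.nz[l], Tw);
    }
    xbar.set_size(RX, Tw);
  }
};

// A[l]: (2 nz_l) x Tw (rows 1..nz = mu part, nz+1..2nz = sigma part)
// eps[l]: nz_l x Tw
void forwardPass(const Net& net, int Tw,
                 const std::vector<mat>& A, const std::vector<mat>& eps,
                 const std::vector<vec>& h0, const std::vector<vec>& d0,
                 bool unitPriorFirst, bool posterior, Cache& C) {
  const int L = net.L;
  C.ensure(net, Tw);

  std::vector<vec> dprev(L), hprev(L);
  for (int l = 0; l < L; ++l) { dprev[l] = d0[l]; hprev[l] = h0[l]; }

  for (int t = 0; t < Tw; ++t) {
    for (int l = 0; l < L; ++l) {
      const int nz = net.nz[l];
      if (nz > 0) {
        vec apm = net.Wmu[l] * dprev[l] + net.bmup[l];
        vec asp = arma::clamp(net.Wsg[l] * dprev[l] + net.bsgp[l],
                              -SIG_CLAMP, SIG_CLAMP);
        vec mup = arma::tanh(apm);
        vec sgp = arma::exp(asp);
        if (t == 0 && unitPriorFirst) { mup.zeros(); sgp.ones(); asp.zeros(); }
        C.mup[l].col(t) = mup; C.sgp[l].col(t) = sgp; C.asp[l].col(t) = asp;
        if (posterior) {
          vec Amu = A[l].rows(0, nz - 1).col(t);
          vec Asg = A[l].rows(nz, 2 * nz - 1).col(t);
          vec aqm = net.Wmu[l] * dprev[l] + Amu + net.bmuq[l];
          vec asq = arma::clamp(net.Wsg[l] * dprev[l] + Asg + net.bsgq[l],
                                -SIG_CLAMP, SIG_CLAMP);
          C.muq[l].col(t) = arma::tanh(aqm);
          C.sgq[l].col(t) = arma::exp(asq);
          C.asq[l].col(t) = asq;
          C.z[l].col(t) = C.muq[l].col(t) + C.sgq[l].col(t) % eps[l].col(t);
        } else {
          C.muq[l].col(t) = mup; C.sgq[l].col(t) = sgp; C.asq[l].col(t) = asp;
          C.z[l].col(t) = mup + sgp % eps[l].col(t);
        }
      }
      vec u = net.Wdd[l] * dprev[l] + net.bh[l];
      if (nz > 0) u += net.Wzd[l] * C.z[l].col(t);
      if (l < L - 1) u += net.Wtd[l] * dprev[l + 1];
      if (l > 0) u += net.Wbu[l] * dprev[l - 1];
      const double a = 1.0 / net.tau[l];
      C.h[l].col(t) = (1.0 - a) * hprev[l] + a * u;
      C.d[l].col(t) = arma::tanh(C.h[l].col(t));
    }
    C.xbar.col(t) = arma::tanh(net.Wout * C.d[0].col(t) + net.bout);
    for (int l = 0; l < L; ++l) {
      hprev[l] = C.h[l].col(t); dprev[l] = C.d[l].col(t);
    }
  }
}

// per-layer summed KL at each step; klsum(l, t) = sum_r delta(l, r, t)
mat klMatrix(const Net& net, const Cache& C) {
  mat kl(net.L, C.Tw, arma::fill::zeros);
  for (int l = 0; l < net.L; ++l) {
    if (net.nz[l] == 0) continue;
    const mat& mp = C.mup[l]; const mat& sp = C.sgp[l];
    const mat& mq = C.muq[l]; const mat& sq = C.sgq[l];
    mat delta = arma::log(sp / sq) +
                (arma::square(mq - mp) + arma::square(sq)) /
                    (2.0 * arma::square(sp)) - 0.5;
    kl.row(l) = arma::sum(delta, 0);
  }
  return kl;
}

// Free energy of Eq.-9 form: complexity_l = (w_l / nz_l) * sum_t sum_r delta,
// accuracy = (1/RX) * sum_t ||X_t - Xbar_t||^2, total = sum_l complexity + accuracy.
struct FE { vec complexity; double accuracy; double total; };

FE feCompute(const Net& net, const Cache& C, const mat& X, const vec& w) {
  FE fe;
  fe.complexity.set_size(net.L);
  mat kl = klMatrix(net, C);
  for (int l = 0; l < net.L; ++l)
    fe.complexity[l] = net.nz[l] > 0
        ? (w[l] / net.nz[l]) * arma::accu(kl.row(l)) : 0.0;
  fe.accuracy = arma::accu(arma::square(X - C.xbar)) / C.RX;
  fe.total = arma::accu(fe.complexity) + fe.accuracy;
  return fe;
}

// ---- backward (posterior path) --------------------------------------------

struct Grads {
  Net g;                  // parameter gradients (same shapes)
  std::vector<mat> gA;    // per layer (2 nz) x Tw
  bool ready = false;
  int Tw = -1;

  void ensure(const Net& net, int Tw_) {
    if (ready && Tw == Tw_) {
      for (mat* t : tensors(g)) t->zeros();
      for (mat& a : gA) a.zeros();
      return;
    }
    g = zerosLike(net);
    gA.assign(net.L, mat());
    for (int l = 0; l < net.L; ++l) gA[l].zeros(2 * net.nz[l], Tw_);
    Tw = Tw_;
    ready = true;
  }
};

void backwardPass(const Net& net, const Cache& C, const mat& X, const vec& w,
                  const std::vector<mat>& eps, const std::vector<vec>& d0,
                  bool unitPriorFirst, Grads& G) {
  const int L = net.L, Tw = C.Tw, RX = C.RX;
  G.ensure(net, Tw);

  std::vector<vec> ghNext(L), carried(L);
  for (int l = 0; l < L; ++l) {
    ghNext[l].zeros(net.nd[l]);
    carried[l].zeros(net.nd[l]);
  }

  for (int t = Tw - 1; t >= 0; --t) {
    std::vector<vec> carryNew(L);
    for (int l = 0; l < L; ++l) carryNew[l].zeros(net.nd[l]);

    // output readout contributes to bottom-layer d at t
    vec gout = (2.0 / RX) * (C.xbar.col(t) - X.col(t)) %
               (1.0 - arma::square(C.xbar.col(t)));
    G.g.Wout += gout * C.d[0].col(t).t();
    G.g.bout += gout;

    std::vector<vec> gh(L);
    for (int l = 0; l < L; ++l) {
      vec gd = carried[l];
      if (l == 0) gd += net.Wout.t() * gout;
      gh[l] = gd % (1.0 - arma::square(C.d[l].col(t))) +
              (1.0 - 1.0 / net.tau[l]) * ghNext[l];
    }

    for (int l = 0; l < L; ++l) {
      const int nz = net.nz[l];
      const double a = 1.0 / net.tau[l];
      vec dprev = (t == 0) ? d0[l] : vec(C.d[l].col(t - 1));

      if (nz > 0) {
        const double cl = w[l] / nz;
        vec mp = C.mup[l].col(t), sp = C.sgp[l].col(t);
        vec mq = C.muq[l].col(t), sq = C.sgq[l].col(t);
        vec gz = a * (net.Wzd[l].t() * gh[l]);

        vec dmu = (mq - mp) / arma::square(sp);
        vec gmuq = cl * dmu + gz;
        vec gsgq = cl * (-1.0 / sq + sq / arma::square(sp)) + gz % eps[l].col(t);
        vec gaq_mu = gmuq % (1.0 - arma::square(mq));
        vec gaq_sg = gsgq % sq;
        // clamp: zero gradient where the raw activation was saturated
        gaq_sg.elem(arma::find(arma::abs(C.asq[l].col(t)) >= SIG_CLAMP)).zeros();

        vec gap_mu(nz, arma::fill::zeros), gap_sg(nz, arma::fill::zeros);
        if (!(t == 0 && unitPriorFirst)) {
          vec gmup = -cl * dmu;
          vec gsgp = cl * (1.0 / sp -
                           (arma::square(mq - mp) + arma::square(sq)) /
                               arma::pow(sp, 3));
          gap_mu = gmup % (1.0 - arma::square(mp));
          gap_sg = gsgp % sp;
          gap_sg.elem(arma::find(arma::abs(C.asp[l].col(t)) >= SIG_CLAMP)).zeros();
        }

        G.gA[l].rows(0, nz - 1).col(t) = gaq_mu;
        G.gA[l].rows(nz, 2 * nz - 1).col(t) = gaq_sg;
        G.g.Wmu[l] += (gaq_mu + gap_mu) * dprev.t();
        G.g.Wsg[l] += (gaq_sg + gap_sg) * dprev.t();
        G.g.bmuq[l] += gaq_mu; G.g.bsgq[l] += gaq_sg;
        G.g.bmup[l] += gap_mu; G.g.bsgp[l] += gap_sg;
        if (t > 0)
          carryNew[l] += net.Wmu[l].t() * (gaq_mu + gap_mu) +
                         net.Wsg[l].t() * (gaq_sg + gap_sg);

        G.g.Wzd[l] += a * gh[l] * C.z[l].col(t).t();
      }

      G.g.Wdd[l] += a * gh[l] * dprev.t();
      G.g.bh[l] += a * gh[l];
      if (l < L - 1) G.g.Wtd[l] += a * gh[l] * (t == 0 ? d0[l + 1] : vec(C.d[l + 1].col(t - 1))).t();
      if (l > 0) G.g.Wbu[l] += a * gh[l] * (t == 0 ? d0[l - 1] : vec(C.d[l - 1].col(t - 1))).t();

      if (t > 0) {
        carryNew[l] += a * (net.Wdd[l].t() * gh[l]);
        if (l < L - 1) carryNew[l + 1] += a * (net.Wtd[l].t() * gh[l]);
        if (l > 0) carryNew[l - 1] += a * (net.Wbu[l].t() * gh[l]);
      }
    }
    carried = carryNew;
    ghNext = gh;
  }
}

// ---- helpers ---------------------------------------------------------------

std::vector<mat> listToMats(SEXP x, int L) {
  std::vector<mat> out;
  if (Rf_isNull(x)) return out;
  List l(x);
  for (int i = 0; i < L; ++i) out.push_back(as<mat>(l[i]));
  return out;
}

void initState(SEXP init, const Net& net, std::vector<vec>& h0,
               std::vector<vec>& d0) {
  h0.assign(net.L, vec()); d0.assign(net.L, vec());
  if (Rf_isNull(init)) {
    for (int l = 0; l < net.L; ++l) {
      h0[l].zeros(net.nd[l]); d0[l].zeros(net.nd[l]);
    }
  } else {
    List s(init);
    List h = s["h"], d = s["d"];
    for (int l = 0; l < net.L; ++l) {
      h0[l] = as<vec>(h[l]); d0[l] = as<vec>(d[l]);
    }
  }
}

std::vector<mat> drawEps(const Net& net, int Tw) {
  std::vector<mat> eps(net.L);
  for (int l = 0; l < net.L; ++l) {
    eps[l].set_size(net.nz[l], Tw);
    for (arma::uword j = 0; j < eps[l].n_cols; ++j)
      for (arma::uword i = 0; i < eps[l].n_rows; ++i)
        eps[l](i, j) = R::norm_rand();
  }
  return eps;
}

std::vector<mat> zeroEps(const Net& net, int Tw) {
  std::vector<mat> eps(net.L);
  for (int l = 0; l < net.L; ++l) eps[l].zeros(net.nz[l], Tw);
  return eps;
}

List cacheFrames(const Cache& C) {
  int L = C.h.size();
  List out(L);
  for (int l = 0; l < L; ++l)
    out[l] = List::create(_["h"] = C.h[l], _["d"] = C.d[l],
                          _["mu_p"] = C.mup[l], _["sigma_p"] = C.sgp[l],
                          _["mu_q"] = C.muq[l], _["sigma_q"] = C.sgq[l],
                          _["z"] = C.z[l]);
  return out;
}

List gradsToList(const Grads& G) {
  List gA(G.gA.size());
  for (size_t l = 0; l < G.gA.size(); ++l) gA[l] = G.gA[l];
  return List::create(_["params"] = netToList(G.g), _["A"] = gA);
}

void adamStep(std::vector<mat*>& p, std::vector<mat*>& g,
              std::vector<mat*>& m, std::vector<mat*>& v, double lr,
              double b1, double b2, double epsad, int t) {
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  for (size_t i = 0; i < p.size(); ++i) {
    if (p[i]->n_elem == 0) continue;
    *m[i] = b1 * (*m[i]) + (1.0 - b1) * (*g[i]);
    *v[i] = b2 * (*v[i]) + (1.0 - b2) * arma::square(*g[i]);
    *p[i] -= lr * ((*m[i]) / c1) / (arma::sqrt((*v[i]) / c2) + epsad);
  }
}

}  // namespace

// Evaluate the network over a window: forward pass, free energy, and
// (optionally) gradients with respect to all parameters and the adaptive
// variables A. `eps` may be NULL (fresh standard-normal draws via R's RNG).
// [[Rcpp::export]]
List cpp_window_pass(List params, List spec, SEXP X, SEXP A, SEXP eps,
                     std::string z_source, SEXP init, bool unit_prior_first,
                     arma::vec w, bool want_grads, int steps = 0) {
  Net net = netFromList(params, spec);
  bool posterior = (z_source == "posterior");
  std::vector<mat> Amats = listToMats(A, net.L);
  if (posterior && Amats.empty())
    stop("posterior evaluation requires adaptive variables A");

  mat Xm;
  bool haveX = !Rf_isNull(X);
  if (haveX) Xm = as<mat>(X).t();  // RX x Tw internally

  int Tw;
  if (posterior) Tw = Amats[0].n_cols;
  else if (haveX) Tw = Xm.n_cols;
  else if (steps > 0) Tw = steps;
  else stop("window length undetermined: supply X, A or steps");
  if (haveX && (int)Xm.n_cols != Tw) stop("target length does not match window");

  std::vector<mat> epsm = Rf_isNull(eps) ? drawEps(net, Tw)
                                         : listToMats(eps, net.L);
  std::vector<vec> h0, d0;
  initState(init, net, h0, d0);

  Cache C;
  forwardPass(net, Tw, Amats, epsm, h0, d0, unit_prior_first, posterior, C);

  List out = List::create(_["xbar"] = mat(C.xbar.t()),
                          _["frames"] = cacheFrames(C),
                          _["kl"] = klMatrix(net, C));
  if (haveX) {
    FE fe = feCompute(net, C, Xm, w);
    out["fe"] = List::create(_["total"] = fe.total,
                             _["complexity"] = fe.complexity,
                             _["accuracy"] = fe.accuracy);
    out["err"] = vec(arma::sum(arma::square(Xm - C.xbar), 0).t() / C.RX);
  }
  if (want_grads) {
    if (!posterior || !haveX)
      stop("gradients require posterior evaluation against a target");
    Grads G;
    backwardPass(net, C, Xm, w, epsm, d0, unit_prior_first, G);
    out["grads"] = gradsToList(G);
  }
  return out;
}

// Full-batch Adam training: jointly optimizes network parameters and the
// per-sequence adaptive variables A by minimizing the mean free energy over
// the corpus. Fresh reparameterization noise is drawn each epoch.
// [[Rcpp::export]]
List cpp_train(List corpus, List params, List spec, arma::vec w, int epochs,
               double lr, double beta1, double beta2, double adam_eps,
               int log_every, SEXP A_init) {
  Net net = netFromList(params, spec);
  const int nseq = corpus.size();
  std::vector<mat> X(nseq);
  for (int s = 0; s < nseq; ++s) X[s] = as<mat>(corpus[s]).t();
  const int Tw = X[0].n_cols;

  // per-sequence adaptive variables (zero-initialized unless provided)
  std::vector<std::vector<mat>> A(nseq), Am(nseq), Av(nseq);
  for (int s = 0; s < nseq; ++s) {
    if (Rf_isNull(A_init)) {
      for (int l = 0; l < net.L; ++l) A[s].push_back(mat(2 * net.nz[l], Tw, arma::fill::zeros));
    } else {
      List Ai(A_init);
      A[s] = listToMats(Ai[s], net.L);
    }
    Am[s] = A[s]; Av[s] = A[s];
    for (int l = 0; l < net.L; ++l) { Am[s][l].zeros(); Av[s][l].zeros(); }
  }

  Net gm = zerosLike(net), gv = zerosLike(net);
  std::vector<vec> h0, d0;
  initState(R_NilValue, net, h0, d0);

  std::vector<double> logEpoch, logAcc, logTotal;
  std::vector<vec> logCplx;

  // reusable buffers (allocated once)
  Cache C;
  Grads G;
  Net gsum = zerosLike(net);
  std::vector<std::vector<mat>> gA(nseq);
  for (int s = 0; s < nseq; ++s)
    for (int l = 0; l < net.L; ++l)
      gA[s].push_back(mat(2 * net.nz[l], Tw, arma::fill::zeros));
  std::vector<mat> epsm = zeroEps(net, Tw);

  for (int ep = 1; ep <= epochs; ++ep) {
    for (mat* t : tensors(gsum)) t->zeros();
    double acc = 0.0, total = 0.0;
    vec cplx(net.L, arma::fill::zeros);

    for (int s = 0; s < nseq; ++s) {
      for (int l = 0; l < net.L; ++l)
        for (arma::uword i = 0; i < epsm[l].n_elem; ++i)
          epsm[l][i] = R::norm_rand();
      forwardPass(net, Tw, A[s], epsm, h0, d0, true, true, C);
      FE fe = feCompute(net, C, X[s], w);
      acc += fe.accuracy / nseq; total += fe.total / nseq;
      cplx += fe.complexity / nseq;
      backwardPass(net, C, X[s], w, epsm, d0, true, G);
      std::vector<mat*> gs = tensors(gsum), gg = tensors(G.g);
      for (size_t i = 0; i < gs.size(); ++i) *gs[i] += (*gg[i]) / nseq;
      for (int l = 0; l < net.L; ++l) gA[s][l] = G.gA[l] / nseq;
    }

    if (!std::isfinite(total))
      stop("free energy became non-finite at epoch %d", ep);

    if (ep == 1 || ep % log_every == 0 || ep == epochs) {
      logEpoch.push_back(ep); logAcc.push_back(acc);
      logTotal.push_back(total); logCplx.push_back(cplx);
    }

    std::vector<mat*> tp = tensors(net), tg = tensors(gsum),
                      tm = tensors(gm), tv = tensors(gv);
    adamStep(tp, tg, tm, tv, lr, beta1, beta2, adam_eps, ep);
    for (int s = 0; s < nseq; ++s) {
      std::vector<mat*> ap, ag, am, av;
      for (int l = 0; l < net.L; ++l) {
        ap.push_back(&A[s][l]); ag.push_back(&gA[s][l]);
        am.push_back(&Am[s][l]); av.push_back(&Av[s][l]);
      }
      adamStep(ap, ag, am, av, lr, beta1, beta2, adam_eps, ep);
    }
    if (ep % 200 == 0) Rcpp::checkUserInterrupt();
  }

  int nlog = logEpoch.size();
  mat hist(nlog, 3 + net.L);
  for (int i = 0; i < nlog; ++i) {
    hist(i, 0) = logEpoch[i];
    for (int l = 0; l < net.L; ++l) hist(i, 1 + l) = logCplx[i][l];
    hist(i, 1 + net.L) = logAcc[i];
    hist(i, 2 + net.L) = logTotal[i];
  }
  List Aout(nseq);
  for (int s = 0; s < nseq; ++s) {
    List As(net.L);
    for (int l = 0; l < net.L; ++l) As[l] = A[s][l];
    Aout[s] = As;
  }
  return List::create(_["params"] = netToList(net), _["A"] = Aout,
                      _["history"] = hist);
}

// Inner optimization of the sliding inference window: plain gradient
// descent on the adaptive variables A only (parameters frozen), with a
// global gradient-norm clip for stability, fresh noise per inner epoch.
// Plain (un-normalized) descent is essential here: the meta-prior w shifts
// the equilibrium between the complexity and accuracy pulls on A, which a
// per-parameter normalizing optimizer would cancel out. The record pass
// afterwards uses a fresh sampled z (not the posterior mean), so the
// recorded trajectory inherits regime-appropriate stochasticity — in the
// high-w regime sampled prior noise is what lets the internal trajectory
// jump between learned patterns.
// [[Rcpp::export]]
List cpp_infer_window(List params, List spec, arma::mat X, List A, SEXP init,
                      bool unit_prior_first, arma::vec w, int inner_epochs,
                      double inner_lr, double clip_norm) {
  Net net = netFromList(params, spec);
  mat Xm = X.t();
  const int Tw = Xm.n_cols;
  std::vector<mat> Amats = listToMats(A, net.L);
  std::vector<vec> h0, d0;
  initState(init, net, h0, d0);

  Cache C;
  Grads G;
  std::vector<mat> epsm = zeroEps(net, Tw);
  for (int ep = 1; ep <= inner_epochs; ++ep) {
    for (int l = 0; l < net.L; ++l)
      for (arma::uword i = 0; i < epsm[l].n_elem; ++i)
        epsm[l][i] = R::norm_rand();
    forwardPass(net, Tw, Amats, epsm, h0, d0, unit_prior_first, true, C);
    FE fe = feCompute(net, C, Xm, w);
    if (!std::isfinite(fe.total))
      stop("inner free energy became non-finite at inner epoch %d", ep);
    if (inner_lr > 0) {
      backwardPass(net, C, Xm, w, epsm, d0, unit_prior_first, G);
      double nrm2 = 0.0;
      for (int l = 0; l < net.L; ++l) nrm2 += arma::accu(arma::square(G.gA[l]));
      double scale = 1.0;
      if (clip_norm > 0 && nrm2 > clip_norm * clip_norm)
        scale = clip_norm / std::sqrt(nrm2);
      for (int l = 0; l < net.L; ++l)
        Amats[l] -= (inner_lr * scale) * G.gA[l];
    }
  }

  // record pass with a fresh sampled z
  std::vector<mat> eps0 = drawEps(net, Tw);
  forwardPass(net, Tw, Amats, eps0, h0, d0, unit_prior_first, true, C);
  FE fe = feCompute(net, C, Xm, w);
  mat kl = klMatrix(net, C);
  for (int l = 0; l < net.L; ++l)
    if (net.nz[l] > 0) kl.row(l) /= net.nz[l];  // mean KL per z unit

  List Aout(net.L);
  for (int l = 0; l < net.L; ++l) Aout[l] = Amats[l];
  return List::create(
      _["A"] = Aout, _["xbar"] = mat(C.xbar.t()),
      _["err"] = vec(arma::sum(arma::square(Xm - C.xbar), 0).t() / C.RX),
      _["kl"] = kl,
      _["fe"] = List::create(_["total"] = fe.total,
                             _["complexity"] = fe.complexity,
                             _["accuracy"] = fe.accuracy));
}

// Advance the window anchor by one step using the evicted step's optimized
// posterior, with a sampled z (matching the sampling convention of the
// window evaluation).
// [[Rcpp::export]]
List cpp_step_state(List params, List spec, List A1, SEXP init,
                    bool unit_prior_first) {
  Net net = netFromList(params, spec);
  std::vector<mat> Amats = listToMats(A1, net.L);
  std::vector<vec> h0, d0;
  initState(init, net, h0, d0);
  std::vector<mat> eps0 = drawEps(net, 1);
  Cache C;
  forwardPass(net, 1, Amats, eps0, h0, d0, unit_prior_first, true, C);
  List h(net.L), d(net.L);
  for (int l = 0; l < net.L; ++l) {
    h[l] = vec(C.h[l].col(0)); d[l] = vec(C.d[l].col(0));
  }
  return List::create(_["h"] = h, _["d"] = d);
}
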