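// Metropolis-within-Gibbs sampler for Q-restricted latent class models:
// DINA / DINO / DINR / DINMix (guess, slip, mixing proportions), ACDM
// (identity-link additive effects), and saturated GDINA (free reduced-pattern
// probabilities, conjugate Beta updates).
//
// One sweep:
//   1. sample each person's attribute class from its full conditional over
//      all 2^K classes given item parameters and class proportions pi;
//   2. sample pi from its conjugate Dirichlet full conditional;
//   3. update item parameters by random-walk Metropolis on transformed
//      scales (logit for g and s under g < 1 - s; additive log-ratio for the
//      mixing simplex), with conjugate Beta draws for GDINA pattern
//      probabilities and bound-rejection for ACDM effects.
// Proposal scales adapt toward a target acceptance rate during burn-in and
// are frozen afterwards. Per-draw deviance (conditional on sampled classes),
// CPO accumulators, and per-person class counts are collected online.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

const int DINA = 0, DINO = 1, DINR = 2, DINMIX = 3, ACDM = 4, GDINA = 5;

struct ItemDesign {
  arma::uvec req;        // 0-based indices of required attributes
  int Kstar;
  int R;                 // 2^Kstar reduced patterns
  arma::uvec map;        // class (0..C-1) -> reduced pattern (0..R-1)
  arma::vec conj, disj, ratio;  // latent-response basis per reduced pattern
  arma::mat bits;        // R x Kstar mastery indicators per reduced pattern
  std::vector<std::vector<int>> subs, sups;  // immediate sub/super patterns
  std::vector<int> order;                    // patterns by mastery count
};

// does p respect the monotone partial order over reduced patterns?
bool monotone_ok(const ItemDesign& d, const arma::vec& p) {
  for (int r = 0; r < d.R; ++r)
    for (int s : d.sups[r])
      if (p[r] > p[s]) return false;
  return true;
}

double clipp(double p, double eps) {
  if (p < eps) return eps;
  if (p > 1.0 - eps) return 1.0 - eps;
  return p;
}

// Binomial log-likelihood of one item over reduced patterns.
double item_ll(const arma::vec& p, const arma::vec& rr, const arma::vec& nn,
               double eps) {
  double ll = 0.0;
  for (arma::uword r = 0; r < p.n_elem; ++r) {
    if (nn[r] == 0.0) continue;
    double pc = clipp(p[r], eps);
    ll += rr[r] * std::log(pc) + (nn[r] - rr[r]) * std::log1p(-pc);
  }
  return ll;
}

arma::vec detnoisy_probs(const ItemDesign& d, double g, double s,
                         const arma::vec& tau) {
  arma::vec psi = tau[0] * d.conj + tau[1] * d.disj + tau[2] * d.ratio;
  return g + (1.0 - s - g) * psi;
}

arma::vec acdm_probs(const ItemDesign& d, const arma::vec& delta) {
  arma::vec p(d.R);
  for (int r = 0; r < d.R; ++r) {
    double v = delta[0];
    for (int k = 0; k < d.Kstar; ++k) v += d.bits(r, k) * delta[k + 1];
    p[r] = v;
  }
  return p;
}

arma::vec rdirichlet(int n) {
  arma::vec w(n);
  for (int j = 0; j < n; ++j) w[j] = R::rgamma(1.0, 1.0);
  return w / arma::accu(w);
}

} // namespace

// [[Rcpp::export]]
List run_dcm_chain(const arma::imat& Y, const arma::imat& Q, int model,
                   int n_iter, int burnin, int thin, int alpha_thin,
                   Nullable<NumericMatrix> fixed_probs,
                   double eps, double target_acc, int adapt_every,
                   int gs_reps, int tau_reps) {
  const int N = Y.n_rows, I = Y.n_cols, K = Q.n_cols;
  const int C = 1 << K;
  if ((int)Q.n_rows != I) stop("Y and Q dimensions are inconsistent");
  if (burnin >= n_iter) stop("burn-in must be smaller than the iteration count");

  // --- design precomputation -------------------------------------------
  std::vector<ItemDesign> des(I);
  for (int i = 0; i < I; ++i) {
    ItemDesign d;
    std::vector<arma::uword> req;
    for (int k = 0; k < K; ++k) if (Q(i, k) == 1) req.push_back(k);
    d.req = arma::uvec(req);
    d.Kstar = req.size();
    d.R = 1 << d.Kstar;
    d.map.set_size(C);
    for (int c = 0; c < C; ++c) {
      int r = 0;
      for (int j = 0; j < d.Kstar; ++j)
        if ((c >> d.req[j]) & 1) r |= (1 << j);
      d.map[c] = r;
    }
    d.conj.set_size(d.R); d.disj.set_size(d.R); d.ratio.set_size(d.R);
    d.bits.set_size(d.R, d.Kstar);
    for (int r = 0; r < d.R; ++r) {
      int m = 0;
      for (int j = 0; j < d.Kstar; ++j) {
        int b = (r >> j) & 1;
        d.bits(r, j) = b;
        m += b;
      }
      d.conj[r] = (m == d.Kstar) ? 1.0 : 0.0;
      d.disj[r] = (m > 0) ? 1.0 : 0.0;
      d.ratio[r] = (double)m / d.Kstar;
    }
    d.subs.resize(d.R); d.sups.resize(d.R);
    for (int r = 0; r < d.R; ++r)
      for (int j = 0; j < d.Kstar; ++j) {
        if ((r >> j) & 1) d.subs[r].push_back(r & ~(1 << j));
        else d.sups[r].push_back(r | (1 << j));
      }
    std::vector<int> ord(d.R);
    for (int r = 0; r < d.R; ++r) ord[r] = r;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      int ca = __builtin_popcount(a), cb = __builtin_popcount(b);
      return ca != cb ? ca < cb : a < b;
    });
    d.order = ord;
    des[i] = d;
  }

  arma::mat Yd = arma::conv_to<arma::mat>::from(Y);
  arma::mat Yt = Yd.t(); // I x N
  // person partitions by response, one pair of index sets per item
  std::vector<arma::uvec> yes_idx(I), no_idx(I);
  for (int i = 0; i < I; ++i) {
    std::vector<arma::uword> a, b;
    for (int n = 0; n < N; ++n) (Y(n, i) == 1 ? a : b).push_back(n);
    yes_idx[i] = arma::uvec(a);
    no_idx[i] = arma::uvec(b);
  }

  const bool fixed = fixed_probs.isNotNull();
  arma::mat Pfix;
  if (fixed) Pfix = as<arma::mat>(fixed_probs.get()); // C x I

  // --- state initialisation (random starting points) --------------------
  arma::vec g(I), s(I);
  arma::mat tau(I, 3, arma::fill::zeros);
  std::vector<arma::vec> delta(I), gpr(I);
  for (int i = 0; i < I; ++i) {
    g[i] = R::runif(0.05, 0.25);
    s[i] = R::runif(0.05, 0.25);
    if (model == DINA) tau.row(i) = arma::rowvec{1, 0, 0};
    else if (model == DINO) tau.row(i) = arma::rowvec{0, 1, 0};
    else if (model == DINR) tau.row(i) = arma::rowvec{0, 0, 1};
    else if (model == DINMIX) {
      if (des[i].Kstar == 1) tau.row(i) = arma::rowvec{1, 0, 0};
      else tau.row(i) = rdirichlet(3).t();
    }
    if (model == ACDM) {
      arma::vec d0(des[i].Kstar + 1);
      d0[0] = R::runif(0.05, 0.15);
      arma::vec w = rdirichlet(des[i].Kstar);
      double total = R::runif(0.5, 0.85) - d0[0];
      for (int k = 0; k < des[i].Kstar; ++k) d0[k + 1] = total * w[k];
      delta[i] = d0;
    }
    if (model == GDINA) {
      // monotone start: probability grows with the number of mastered
      // required attributes
      arma::vec p0(des[i].R);
      for (int r = 0; r < des[i].R; ++r) {
        double frac = (double)__builtin_popcount(r) / des[i].Kstar;
        p0[r] = 0.15 + 0.6 * frac + R::runif(0.0, 0.1);
      }
      gpr[i] = p0;
    }
  }
  arma::vec pi = rdirichlet(C);
  arma::uvec cls(N);
  for (int n = 0; n < N; ++n) cls[n] = (arma::uword)(R::unif_rand() * C);

  // per-item proposal scales and acceptance counters
  // blocks: 0 = g, 1 = s, 2 = tau / additive effects, 3 = collapsed refresh
  arma::mat prop_sd(I, 4, arma::fill::value(0.3));
  prop_sd.col(3).fill(0.2);
  arma::mat acc(I, 4, arma::fill::zeros), att(I, 4, arma::fill::zeros);

  // --- storage ----------------------------------------------------------
  int n_keep = (n_iter - burnin) / thin;
  int npar = 0;
  if (model <= DINMIX) npar = 5 * I;
  else if (model == ACDM) { for (int i = 0; i < I; ++i) npar += des[i].Kstar + 1; }
  else { for (int i = 0; i < I; ++i) npar += des[i].R; }
  arma::mat par_draws(fixed ? 0 : n_keep, fixed ? 0 : npar);
  arma::mat pi_draws(n_keep, C);
  arma::vec dev_draws(n_keep);
  arma::mat cpo_sum(N, I, arma::fill::zeros);
  arma::mat cls_counts(N, C, arma::fill::zeros);
  int n_alpha = (n_keep + alpha_thin - 1) / alpha_thin;
  arma::umat alpha_draws(n_alpha, N);

  arma::mat Pfull(C, I);       // current clipped class probabilities
  arma::vec rr, nn;
  arma::mat Rcnt(I, C);
  arma::vec ncls(C);
  int keep_idx = 0, alpha_idx = 0;

  auto current_red_probs = [&](int i) -> arma::vec {
    if (model <= DINMIX) return detnoisy_probs(des[i], g[i], s[i], tau.row(i).t());
    if (model == ACDM) return acdm_probs(des[i], delta[i]);
    return gpr[i];
  };

  for (int it = 1; it <= n_iter; ++it) {
    // 1. class full conditional --------------------------------------
    arma::mat logP(C, I), log1mP(C, I);
    for (int i = 0; i < I; ++i) {
      arma::vec red = fixed ? arma::vec() : current_red_probs(i);
      for (int c = 0; c < C; ++c) {
        double p = fixed ? Pfix(c, i) : red[des[i].map[c]];
        p = clipp(p, eps);
        Pfull(c, i) = p;
        logP(c, i) = std::log(p);
        log1mP(c, i) = std::log1p(-p);
      }
    }
    arma::mat D = (logP - log1mP).t();            // I x C
    arma::rowvec c0 = arma::sum(log1mP, 1).t();   // per-class sum over items
    arma::rowvec lpi = arma::log(pi).t();
    arma::mat Mp = Yd * D;                        // N x C person-class loglik
    Mp.each_row() += (c0 + lpi);                  // ... plus log prior over classes
    const bool adapting = (it <= burnin);

    // 1b. collapsed item refresh: Metropolis update of each item's whole
    // parameter block targeting the posterior with attribute classes
    // marginalised over (given pi). Valid because classes are redrawn from
    // their exact full conditional immediately afterwards; breaks the slow
    // coupling between item parameters and sampled classes.
    // scaled likelihood table, persons in columns: Et(c, n) =
    // exp(Mp(n, c) - mx(n)). Collapsed proposals are evaluated as dot
    // products against Et's contiguous person columns, so only the length-C
    // shift vector is ever exponentiated; the class sampler reuses Et as
    // unnormalised categorical weights.
    arma::mat Mpt = Mp.t();                     // C x N
    arma::rowvec mx = arma::max(Mpt, 0);
    arma::mat Et = arma::exp(Mpt.each_row() - mx);
    if (!fixed) {
      double cur_total =
        arma::accu(mx + arma::log(arma::sum(Et, 0)));
      // try one candidate parameter block for item i; commit on acceptance
      auto try_item = [&](int i, const arma::vec& red_new, double jac,
                          bool count) -> bool {
        const ItemDesign& d = des[i];
        arma::vec ed1(C), ed0(C);
        for (int c = 0; c < C; ++c) {
          double pn = clipp(red_new[d.map[c]], eps);
          ed1[c] = std::exp(std::log(pn) - logP(c, i));
          ed0[c] = std::exp(std::log1p(-pn) - log1mP(c, i));
        }
        double new_total = 0.0;
        for (arma::uword j = 0; j < yes_idx[i].n_elem; ++j) {
          arma::uword n = yes_idx[i][j];
          new_total += mx[n] + std::log(arma::dot(Et.unsafe_col(n), ed1));
        }
        for (arma::uword j = 0; j < no_idx[i].n_elem; ++j) {
          arma::uword n = no_idx[i][j];
          new_total += mx[n] + std::log(arma::dot(Et.unsafe_col(n), ed0));
        }
        if (std::log(R::unif_rand()) >= new_total - cur_total + jac) return false;
        if (count) acc(i, 3) += 1.0;
        for (arma::uword j = 0; j < yes_idx[i].n_elem; ++j)
          Et.unsafe_col(yes_idx[i][j]) %= ed1;
        for (arma::uword j = 0; j < no_idx[i].n_elem; ++j)
          Et.unsafe_col(no_idx[i][j]) %= ed0;
        cur_total = new_total;
        for (int c = 0; c < C; ++c) {
          double pn = clipp(red_new[d.map[c]], eps);
          logP(c, i) = std::log(pn);
          log1mP(c, i) = std::log1p(-pn);
          Pfull(c, i) = pn;
        }
        // guard against scale drift from repeated accepted updates
        arma::rowvec m2 = arma::max(Et, 0);
        if (m2.max() > 1e250 || m2.min() < 1e-250) {
          Et.each_row() /= m2;
          mx += arma::log(m2);
        }
        return true;
      };

      // collapsed refresh of pi: independence proposal from the Dirichlet
      // conditional given the previous sweep's classes, accepted against the
      // class-marginalised likelihood. Breaks the three-way coupling between
      // item parameters, classes, and class proportions.
      auto refresh_pi = [&]() {
        arma::vec a(C);
        for (int c = 0; c < C; ++c) a[c] = 1.0;
        for (int n = 0; n < N; ++n) a[cls[n]] += 1.0;
        arma::vec pin(C);
        for (int c = 0; c < C; ++c) pin[c] = R::rgamma(a[c], 1.0);
        pin /= arma::accu(pin);
        arma::vec ed(C);
        double lr = 0.0;
        for (int c = 0; c < C; ++c) {
          ed[c] = pin[c] / pi[c];
          lr += (a[c] - 1.0) * (std::log(pi[c]) - std::log(pin[c]));
        }
        double new_total = 0.0;
        for (int n = 0; n < N; ++n)
          new_total += mx[n] + std::log(arma::dot(Et.unsafe_col(n), ed));
        lr += new_total - cur_total;
        if (std::log(R::unif_rand()) < lr) {
          pi = pin;
          Et.each_col() %= ed;
          cur_total = new_total;
          arma::rowvec m2 = arma::max(Et, 0);
          if (m2.max() > 1e250 || m2.min() < 1e-250) {
            Et.each_row() /= m2;
            mx += arma::log(m2);
          }
        }
      };
      refresh_pi();

      for (int i = 0; i < I; ++i) {
        const ItemDesign& d = des[i];
        if (model <= DINMIX) {
          // move A (repeated): (g, s) random walk on the logit scale,
          // classes marginalised out
          for (int rep = 0; rep < gs_reps; ++rep) {
            att(i, 3) += 1.0;
            double lg = std::log(g[i] / (1 - g[i])) + R::norm_rand() * prop_sd(i, 3);
            double ls = std::log(s[i] / (1 - s[i])) + R::norm_rand() * prop_sd(i, 3);
            double gn = 1.0 / (1.0 + std::exp(-lg));
            double sn = 1.0 / (1.0 + std::exp(-ls));
            if (gn < 1 - sn) {
              double jac = std::log(gn * (1 - gn)) - std::log(g[i] * (1 - g[i])) +
                           std::log(sn * (1 - sn)) - std::log(s[i] * (1 - s[i]));
              if (try_item(i, detnoisy_probs(d, gn, sn, tau.row(i).t()), jac, true)) {
                g[i] = gn; s[i] = sn;
              }
            }
          }
          // move B (x2 each): mixing-proportion refresh from the flat
          // Dirichlet prior, alternated with a local additive-log-ratio
          // random walk on the simplex
          if (model == DINMIX && d.Kstar > 1) {
            for (int rep = 0; rep < tau_reps; ++rep) {
              arma::vec tn = rdirichlet(3);
              if (try_item(i, detnoisy_probs(d, g[i], s[i], tn), 0.0, false)) {
                tau.row(i) = tn.t();
              }
              arma::vec t = tau.row(i).t();
              double v1 = std::log(t[0] / t[2]) + R::norm_rand() * 0.6;
              double v2 = std::log(t[1] / t[2]) + R::norm_rand() * 0.6;
              double e1 = std::exp(v1), e2 = std::exp(v2);
              double den = e1 + e2 + 1.0;
              arma::vec tw = {e1 / den, e2 / den, 1.0 / den};
              double jac_t = arma::accu(arma::log(tw)) - arma::accu(arma::log(t));
              if (try_item(i, detnoisy_probs(d, g[i], s[i], tw), jac_t, false)) {
                tau.row(i) = tw.t();
              }
            }
          }
        } else if (model == ACDM) {
          att(i, 3) += 1.0;
          arma::vec dc = delta[i];
          for (arma::uword j = 0; j < dc.n_elem; ++j)
            dc[j] += R::norm_rand() * prop_sd(i, 3) * 0.5;
          bool ok_main = true;
          for (arma::uword j = 1; j < dc.n_elem; ++j)
            if (dc[j] < 0.0) ok_main = false;   // monotone main effects
          arma::vec red_new = acdm_probs(d, dc);
          if (ok_main && red_new.min() >= 0.0 && red_new.max() <= 1.0 &&
              try_item(i, red_new, 0.0, true)) {
            delta[i] = dc;
          }
        } else { // GDINA
          att(i, 3) += 1.0;
          arma::vec pc = gpr[i];
          for (arma::uword r = 0; r < pc.n_elem; ++r)
            pc[r] += R::norm_rand() * prop_sd(i, 3) * 0.5;
          if (pc.min() >= 0.0 && pc.max() <= 1.0 && monotone_ok(d, pc) &&
              try_item(i, pc, 0.0, true)) {
            gpr[i] = pc;
          }
        }
        if (adapting && it % adapt_every == 0 && att(i, 3) > 0) {
          double rate = acc(i, 3) / att(i, 3);
          prop_sd(i, 3) *= std::exp(1.5 * (rate - 0.3));
          prop_sd(i, 3) = std::min(std::max(prop_sd(i, 3), 1e-3), 5.0);
          acc(i, 3) = 0.0; att(i, 3) = 0.0;
        }
      }
      refresh_pi();
    }

    for (int n = 0; n < N; ++n) {
      const double* w = Et.colptr(n);
      double tot = 0.0;
      for (int c = 0; c < C; ++c) tot += w[c];
      double u = R::unif_rand() * tot, cum = 0.0;
      int pick = C - 1;
      for (int c = 0; c < C; ++c) { cum += w[c]; if (u <= cum) { pick = c; break; } }
      cls[n] = pick;
    }

    // 2. class proportions --------------------------------------------
    ncls.zeros();
    for (int n = 0; n < N; ++n) ncls[cls[n]] += 1.0;
    for (int c = 0; c < C; ++c) pi[c] = R::rgamma(1.0 + ncls[c], 1.0);
    pi /= arma::accu(pi);

    // 3. sufficient statistics ----------------------------------------
    Rcnt.zeros();
    for (int n = 0; n < N; ++n) Rcnt.col(cls[n]) += Yt.col(n);

    double dev = 0.0;
    for (int i = 0; i < I; ++i) {
      const ItemDesign& d = des[i];
      rr.zeros(d.R); nn.zeros(d.R);
      for (int c = 0; c < C; ++c) {
        rr[d.map[c]] += Rcnt(i, c);
        nn[d.map[c]] += ncls[c];
      }

      if (!fixed && model == GDINA) {
        // monotone saturated model: each pattern probability is drawn from
        // its conjugate Beta truncated to [max over immediate sub-patterns,
        // min over immediate super-patterns]. Monotonicity both regularises
        // the saturated fit and pins attribute polarity (the unconstrained
        // model is invariant to attribute flips).
        for (int k = 0; k < d.R; ++k) {
          int r = d.order[k];
          double lo = 0.0, hi = 1.0;
          for (int ssub : d.subs[r]) lo = std::max(lo, gpr[i][ssub]);
          for (int ssup : d.sups[r]) hi = std::min(hi, gpr[i][ssup]);
          double a = 1.0 + rr[r], b = 1.0 + nn[r] - rr[r];
          double plo = R::pbeta(lo, a, b, 1, 0), phi = R::pbeta(hi, a, b, 1, 0);
          if (phi - plo > 1e-12) {
            double u = plo + R::unif_rand() * (phi - plo);
            gpr[i][r] = R::qbeta(std::min(u, 1.0 - 1e-14), a, b, 1, 0);
          } else {
            gpr[i][r] = 0.5 * (lo + hi);  // numerically empty slice
          }
          gpr[i][r] = std::min(std::max(gpr[i][r], lo), hi);
        }
      } else if (!fixed && model == ACDM) {
        double ll = item_ll(acdm_probs(d, delta[i]), rr, nn, eps);
        for (int j = 0; j <= d.Kstar; ++j) {
          att(i, 2) += 1.0;
          arma::vec cand = delta[i];
          cand[j] += R::norm_rand() * prop_sd(i, 2);
          if (j > 0 && cand[j] < 0.0) continue;  // monotone main effects
          arma::vec pc = acdm_probs(d, cand);
          if (pc.min() < 0.0 || pc.max() > 1.0) continue;
          double llc = item_ll(pc, rr, nn, eps);
          if (std::log(R::unif_rand()) < llc - ll) {
            delta[i] = cand; ll = llc; acc(i, 2) += 1.0;
          }
        }
      } else if (!fixed) {
        arma::vec t = tau.row(i).t();
        double ll = item_ll(detnoisy_probs(d, g[i], s[i], t), rr, nn, eps);
        for (int rep = 0; rep < 4; ++rep) {
        // guessing
        att(i, 0) += 1.0;
        {
          double lg = std::log(g[i] / (1.0 - g[i])) + R::norm_rand() * prop_sd(i, 0);
          double gc = 1.0 / (1.0 + std::exp(-lg));
          if (gc < 1.0 - s[i]) {
            double llc = item_ll(detnoisy_probs(d, gc, s[i], t), rr, nn, eps);
            double la = llc - ll + std::log(gc * (1.0 - gc)) -
                        std::log(g[i] * (1.0 - g[i]));
            if (std::log(R::unif_rand()) < la) { g[i] = gc; ll = llc; acc(i, 0) += 1.0; }
          }
        }
        // slip
        att(i, 1) += 1.0;
        {
          double ls = std::log(s[i] / (1.0 - s[i])) + R::norm_rand() * prop_sd(i, 1);
          double sc = 1.0 / (1.0 + std::exp(-ls));
          if (g[i] < 1.0 - sc) {
            double llc = item_ll(detnoisy_probs(d, g[i], sc, t), rr, nn, eps);
            double la = llc - ll + std::log(sc * (1.0 - sc)) -
                        std::log(s[i] * (1.0 - s[i]));
            if (std::log(R::unif_rand()) < la) { s[i] = sc; ll = llc; acc(i, 1) += 1.0; }
          }
        }
        // mixing proportions (free only for multidimensional DINMix items)
        if (model == DINMIX && d.Kstar > 1) {
          att(i, 2) += 1.0;
          double v1 = std::log(t[0] / t[2]) + R::norm_rand() * prop_sd(i, 2);
          double v2 = std::log(t[1] / t[2]) + R::norm_rand() * prop_sd(i, 2);
          double e1 = std::exp(v1), e2 = std::exp(v2);
          double den = e1 + e2 + 1.0;
          arma::vec tc = {e1 / den, e2 / den, 1.0 / den};
          double llc = item_ll(detnoisy_probs(d, g[i], s[i], tc), rr, nn, eps);
          double la = llc - ll +
                      arma::accu(arma::log(tc)) - arma::accu(arma::log(t));
          if (std::log(R::unif_rand()) < la) {
            tau.row(i) = tc.t(); t = tc; ll = llc; acc(i, 2) += 1.0;
          }
          // independence refresh from the flat Dirichlet prior: proposal and
          // prior densities cancel, so the acceptance ratio is the likelihood
          // ratio. Lets the simplex jump between modes when the likelihood is
          // only weakly informative about the rule mix.
          arma::vec ti = rdirichlet(3);
          double lli = item_ll(detnoisy_probs(d, g[i], s[i], ti), rr, nn, eps);
          if (std::log(R::unif_rand()) < lli - ll) {
            tau.row(i) = ti.t(); t = ti; ll = lli;
          }
        }
        } // update repetitions
      }

      // deviance contribution at the (possibly updated) parameters
      arma::vec pcur = fixed ? arma::vec() : current_red_probs(i);
      arma::vec pdev(d.R);
      if (fixed) {
        pdev.zeros();
        for (int c = 0; c < C; ++c) pdev[d.map[c]] = Pfix(c, i);
      } else pdev = pcur;
      dev += item_ll(pdev, rr, nn, eps);

      if (adapting && !fixed && it % adapt_every == 0) {
        for (int b = 0; b < 3; ++b) {
          if (att(i, b) > 0) {
            double rate = acc(i, b) / att(i, b);
            // scalar blocks (g, s) target the 1-D random-walk optimum ~0.44;
            // the vector block (tau / additive effects) targets target_acc
            double tgt = (b < 2) ? 0.44 : target_acc;
            prop_sd(i, b) *= std::exp(1.5 * (rate - tgt));
            prop_sd(i, b) = std::min(std::max(prop_sd(i, b), 1e-3), 5.0);
            acc(i, b) = 0.0; att(i, b) = 0.0;
          }
        }
      }
    }
    dev *= -2.0;

    // 4. retention -----------------------------------------------------
    if (it > burnin && (it - burnin) % thin == 0) {
      if (!fixed) {
        int col = 0;
        if (model <= DINMIX) {
          for (int i = 0; i < I; ++i) par_draws(keep_idx, col++) = g[i];
          for (int i = 0; i < I; ++i) par_draws(keep_idx, col++) = s[i];
          for (int i = 0; i < I; ++i)
            for (int m = 0; m < 3; ++m) par_draws(keep_idx, col++) = tau(i, m);
        } else if (model == ACDM) {
          for (int i = 0; i < I; ++i)
            for (arma::uword j = 0; j < delta[i].n_elem; ++j)
              par_draws(keep_idx, col++) = delta[i][j];
        } else {
          for (int i = 0; i < I; ++i)
            for (arma::uword r = 0; r < gpr[i].n_elem; ++r)
              par_draws(keep_idx, col++) = gpr[i][r];
        }
      }
      pi_draws.row(keep_idx) = pi.t();
      dev_draws[keep_idx] = dev;
      // CPO accumulators and class counts use the same (updated) parameters
      // as the stored draw: recompute clipped class probabilities.
      for (int i = 0; i < I; ++i) {
        arma::vec red = fixed ? arma::vec() : current_red_probs(i);
        for (int n = 0; n < N; ++n) {
          double p = fixed ? Pfix(cls[n], i) : red[des[i].map[cls[n]]];
          p = clipp(p, eps);
          cpo_sum(n, i) += (Y(n, i) == 1) ? 1.0 / p : 1.0 / (1.0 - p);
        }
      }
      for (int n = 0; n < N; ++n) cls_counts(n, cls[n]) += 1.0;
      if (keep_idx % alpha_thin == 0) {
        alpha_draws.row(alpha_idx) = cls.t() + 1; // 1-based class indices
        ++alpha_idx;
      }
      ++keep_idx;
    }
  }

  arma::mat acc_rate(I, 4);
  for (int i = 0; i < I; ++i)
    for (int b = 0; b < 4; ++b)
      acc_rate(i, b) = att(i, b) > 0 ? acc(i, b) / att(i, b) : NA_REAL;

  return List::create(
    _["par"] = par_draws,
    _["pi"] = pi_draws,
    _["deviance"] = dev_draws,
    _["cpo_sum"] = cpo_sum,
    _["cls_counts"] = cls_counts,
    _["alpha"] = alpha_draws,
    _["n_kept"] = n_keep,
    _["accept_rate"] = acc_rate);
}
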