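#include <Rcpp.h>
using namespace Rcpp;

// Session negative log-likelihood of the seven-parameter hybrid model.
// Parameters arrive on the natural scale in the fixed order
// (beta1, beta2, alpha1, alpha2, lam, omega, pi). Missing trials contribute
// zero likelihood and freeze the learner state. Kept in C++ because the
// optimizer evaluates this thousands of times per session; an independent
// plain-R loop (session_negll_ref) serves as the oracle in the tests.
// [[Rcpp::export(name = ".negll_cpp")]]
double negll_cpp(NumericVector par, IntegerVector choice1,
                 IntegerVector state2, IntegerVector choice2,
                 IntegerVector reward, LogicalVector missing,
                 double q_init, double p_common) {
  const double b1 = par[0], b2 = par[1], a1 = par[2], a2 = par[3],
               lam = par[4], om = par[5], pi = par[6];
  const int n = choice1.size();
  double qmf1[2] = {q_init, q_init};
  double q2[2][2] = {{q_init, q_init}, {q_init, q_init}};
  int prev = -1;
  double ll = 0.0;

  for (int t = 0; t < n; ++t) {
    if (missing[t]) continue;
    const int c1 = choice1[t], s2 = state2[t], c2 = choice2[t], r = reward[t];

    // model-based planning over the known transition structure
    const double m0 = std::max(q2[0][0], q2[0][1]);
    const double m1 = std::max(q2[1][0], q2[1][1]);
    const double qmb0 = p_common * m0 + (1.0 - p_common) * m1;
    const double qmb1 = p_common * m1 + (1.0 - p_common) * m0;

    double x0 = b1 * (om * qmb0 + (1.0 - om) * qmf1[0]);
    double x1 = b1 * (om * qmb1 + (1.0 - om) * qmf1[1]);
    if (prev == 0) x0 += pi; else if (prev == 1) x1 += pi;
    const double mx = std::max(x0, x1);
    const double lse1 = mx + std::log(std::exp(x0 - mx) + std::exp(x1 - mx));
    ll += (c1 == 0 ? x0 : x1) - lse1;

    const double y0 = b2 * q2[s2][0], y1 = b2 * q2[s2][1];
    const double my = std::max(y0, y1);
    const double lse2 = my + std::log(std::exp(y0 - my) + std::exp(y1 - my));
    ll += (c2 == 0 ? y0 : y1) - lse2;

    // SARSA update: stage-1 backup from the chosen second-stage action,
    // then the second-stage RPE, eligibility-weighted back to stage 1
    const double d1 = q2[s2][c2] - qmf1[c1];
    qmf1[c1] += a1 * d1;
    const double d2 = (double)r - q2[s2][c2];
    q2[s2][c2] += a2 * d2;
    qmf1[c1] += a1 * lam * d2;
    prev = c1;
  }
  return -ll;
}
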