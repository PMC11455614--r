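#include <Rcpp.h>
using namespace Rcpp;

// Forward pass of the Q-learning choice model over concatenated sessions.
//
// choice:   0 = left, 1 = right (timeouts must be removed by the caller;
//           they contribute neither likelihood nor value updates)
// rewarded: 0/1 water outcome R
// session:  integer run id; Q-values reset to (0, 0) whenever it changes
// in_loss:  trials contributing to the (mean) negative log-likelihood
//
// Value recursion (chosen spout i, unchosen j):
//   Q_i <- Q_i + alpha * (R - Q_i)
//   Q_j <- (1 - zeta) * Q_j
// Choice policy, right spout as reference:
//   P(right) = 1 / (1 + exp(-(beta * (Q_R - Q_L) + b)))
//
// Returns the mean NLL over in_loss trials, its analytic gradient with
// respect to (alpha, zeta, beta, b) on the natural scale, and the
// per-trial P(right) under the model.
// [[Rcpp::export]]
List qlearn_forward(IntegerVector choice, IntegerVector rewarded,
                    IntegerVector session, LogicalVector in_loss,
                    double alpha, double zeta, double beta, double b) {
  int n = choice.size();
  NumericVector p_right(n);
  double nll = 0.0, g_a = 0.0, g_z = 0.0, g_beta = 0.0, g_b = 0.0;
  int n_loss = 0;

  double qL = 0.0, qR = 0.0;
  // derivatives of the Q-values w.r.t. alpha and zeta
  double dLa = 0.0, dRa = 0.0, dLz = 0.0, dRz = 0.0;
  int cur = n > 0 ? session[0] : 0;

  for (int t = 0; t < n; ++t) {
    if (session[t] != cur) {
      cur = session[t];
      qL = qR = dLa = dRa = dLz = dRz = 0.0;
    }
    double dq = qR - qL;
    double logit = beta * dq + b;
    double p = 1.0 / (1.0 + std::exp(-logit));
    p_right[t] = p;

    int y = choice[t];  // 1 if right
    if (in_loss[t]) {
      nll += y == 1 ? -std::log(p) : -std::log1p(-p);
      double dl = p - (double)y;  // d(-log lik)/d(logit)
      g_beta += dl * dq;
      g_b    += dl;
      g_a    += dl * beta * (dRa - dLa);
      g_z    += dl * beta * (dRz - dLz);
      ++n_loss;
    }

    double R = (double)rewarded[t];
    if (y == 1) {  // right chosen
      dRa = (1.0 - alpha) * dRa + (R - qR);
      dRz = (1.0 - alpha) * dRz;
      qR  = qR + alpha * (R - qR);
      dLz = (1.0 - zeta) * dLz - qL;
      dLa = (1.0 - zeta) * dLa;
      qL  = (1.0 - zeta) * qL;
    } else {       // left chosen
      dLa = (1.0 - alpha) * dLa + (R - qL);
      dLz = (1.0 - alpha) * dLz;
      qL  = qL + alpha * (R - qL);
      dRz = (1.0 - zeta) * dRz - qR;
      dRa = (1.0 - zeta) * dRa;
      qR  = (1.0 - zeta) * qR;
    }
  }

  if (n_loss > 0) {
    nll /= n_loss; g_a /= n_loss; g_z /= n_loss;
    g_beta /= n_loss; g_b /= n_loss;
  }
  return List::create(
    _["nll"] = nll,
    _["grad"] = NumericVector::create(g_a, g_z, g_beta, g_b),
    _["p_right"] = p_right,
    _["n_loss"] = n_loss);
}
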