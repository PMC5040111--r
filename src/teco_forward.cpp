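#include <Rcpp.h>
using namespace Rcpp;

// Daily explicit (forward-Euler) update of a six-pool terrestrial carbon
// model. Pools: foliage, fine root, litter, fast SOM, slow SOM, passive SOM.
// Carbon input is allocated to foliage/root; donor-controlled first-order
// transfers run foliage->litter, root->litter, litter->(fast + CO2),
// fast->(slow + CO2), slow->(passive + CO2), passive->CO2. Litter and SOM
// fluxes are multiplied by the temperature scalar q10^((T - Tref)/10); plant
// pool turnover is not. resp_frac of each scaled donor flux is respired
// (terminal passive flux fully respired), so mass balance
// d(total)/dt = input - Rh holds exactly per step.
// [[Rcpp::export(name = ".teco_forward_cpp")]]
List teco_forward_cpp(NumericVector pools0, NumericVector ks, double q10,
                      double tref, NumericVector temp, NumericVector c_input,
                      double alloc_foliage, double alloc_root,
                      double resp_frac) {
  const int n = temp.size();
  if (c_input.size() != n) stop("temperature and input series differ in length");
  if (pools0.size() != 6 || ks.size() != 6) stop("expected 6 pools / 6 rates");

  double fol = pools0[0], root = pools0[1], lit = pools0[2];
  double fast = pools0[3], slow = pools0[4], pass = pools0[5];

  NumericMatrix pools(n, 6);
  NumericVector rh(n), agb(n);

  for (int t = 0; t < n; ++t) {
    const double xi = std::pow(q10, (temp[t] - tref) / 10.0);
    const double u = c_input[t];

    const double f_fol  = ks[0] * fol;
    const double f_root = ks[1] * root;
    const double f_lit  = ks[2] * xi * lit;
    const double f_fast = ks[3] * xi * fast;
    const double f_slow = ks[4] * xi * slow;
    const double f_pass = ks[5] * xi * pass;

    fol  += alloc_foliage * u - f_fol;
    root += alloc_root * u - f_root;
    lit  += f_fol + f_root - f_lit;
    fast += (1.0 - resp_frac) * f_lit - f_fast;
    slow += (1.0 - resp_frac) * f_fast - f_slow;
    pass += (1.0 - resp_frac) * f_slow - f_pass;

    if (fol < 0 || root < 0 || lit < 0 || fast < 0 || slow < 0 || pass < 0)
      stop("negative pool at day %d: step too large or invalid rates", t + 1);

    rh[t] = resp_frac * (f_lit + f_fast + f_slow) + f_pass;
    agb[t] = fol;
    pools(t, 0) = fol;  pools(t, 1) = root; pools(t, 2) = lit;
    pools(t, 3) = fast; pools(t, 4) = slow; pools(t, 5) = pass;
  }

  return List::create(_["pools"] = pools, _["rh"] = rh, _["agb"] = agb);
}
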