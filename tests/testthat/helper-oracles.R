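# Independent oracles for the equilibrium solvers. These deliberately avoid
# the closed-form quadratic and the bisection used by the package: the
# pairwise oracle iterates the mass-action fixed point c <- (D-c)(P-c)/K,
# the competitive oracle iterates the hub conservation fixed point
# h <- H / (1 + sum(P_i / (K_i + h))).

pairwise_complex_oracle <- function(D, P, K, tol = 1e-15, max_iter = 1e6) {
  c_old <- 0
  for (i in seq_len(max_iter)) {
    c_new <- (D - c_old) * (P - c_old) / K
    # damped average keeps the iteration inside [0, min(D, P)]
    c_new <- (c_new + c_old) / 2
    if (abs(c_new - c_old) <= tol * max(c_new, .Machine$double.xmin)) {
      return(c_new)
    }
    c_old <- c_new
  }
  stop("pairwise oracle did not converge")
}

competitive_free_hub_oracle <- function(H, P, K, tol = 1e-15,
                                        max_iter = 1e6) {
  if (H == 0 || length(P) == 0L) return(H)
  h <- H
  for (i in seq_len(max_iter)) {
    h_new <- H / (1 + sum(P / (K + h)))
    if (abs(h_new - h) <= tol * max(h_new, .Machine$double.xmin)) {
      return(h_new)
    }
    h <- h_new
  }
  stop("competitive oracle did not converge")
}

# random one-hub systems spanning nM..uM totals and sub-uM..0.1 mM KDs
random_system <- function(n_partners) {
  H <- 10^stats::runif(1, -9, -4)
  P <- 10^stats::runif(n_partners, -9, -4)
  K <- 10^stats::runif(n_partners, -7, -4)
  equilibrium_system("hub", H, paste0("p", seq_len(n_partners)), P,
                     kds = K)
}

rel_diff <- function(a, b) {
  abs(a - b) / pmax(abs(a), abs(b), .Machine$double.xmin)
}
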