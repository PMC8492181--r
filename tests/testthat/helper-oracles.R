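# Independent closed-form oracles used to cross-check the package's
# numerical machinery. These deliberately re-derive quantities from the
# published algebra rather than calling the implementation under test.

# stationary production rate of the mechanistic model
oracle_gamma <- function(p) {
  p$a * p$b * p$c /
    (p$a_rev * (p$b_rev + p$c) + p$a * (p$b_rev + p$b + p$c))
}

# randomness parameters, written out directly from the closed forms
oracle_R_tele <- function(rho, sigma_u, sigma_b) {
  1 + 2 * rho * sigma_u / (sigma_b + sigma_u)^2
}
oracle_R_mech <- function(p) {
  1 + 2 * p$b * p$c * (p$a_rev * (p$b_rev + p$c - p$a) - p$a^2) /
    (p$a_rev * (p$b_rev + p$c) + p$a * (p$b + p$b_rev + p$c))^2
}

# telegraph waiting-time Laplace transform (two-state first passage,
# solved by hand)
oracle_lt_tele <- function(rho, sigma_u, sigma_b, s) {
  rho * (s + sigma_b) /
    ((s + rho + sigma_u) * (s + sigma_b) - sigma_u * sigma_b)
}

# regularized Kummer series for the Peccoud-Ycart telegraph mature-mRNA
# pmf; uses 1F1(a; b; -z) = exp(-z) 1F1(b - a; b; z) for stability
kummer_1f1 <- function(a, b, z, tol = 1e-15, kmax = 10000) {
  term <- 1; acc <- 1
  for (k in seq_len(kmax)) {
    term <- term * (a + k - 1) / (b + k - 1) * z / k
    acc <- acc + term
    if (abs(term) < tol * abs(acc)) break
  }
  acc
}
oracle_telegraph_pmf <- function(rho, sigma_u, sigma_b, d, n_max) {
  al <- sigma_b / d; be <- sigma_u / d; lam <- rho / d
  n <- 0:n_max
  logpoch <- function(x, k) lgamma(x + k) - lgamma(x)
  pref <- exp(n * log(lam) - lgamma(n + 1) +
                logpoch(al, n) - logpoch(al + be, n) - lam)
  pref * vapply(n, function(k) kummer_1f1(be, al + be + k, lam), 0)
}

# log-uniform mechanistic parameter draws for property tests
draw_mech <- function(n, seed, range = c(1e-3, 5), d = NULL, tau = NULL) {
  set.seed(seed)
  m <- matrix(exp(runif(5 * n, log(range[1]), log(range[2]))), ncol = 5)
  lapply(seq_len(n), function(i)
    mechanistic_params(m[i, 1], m[i, 2], m[i, 3], m[i, 4], m[i, 5],
                       d = d, tau = if (is.null(tau)) 0 else tau))
}

table2 <- function(i) builtin_fixtures(paste0("table2_set", i))
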