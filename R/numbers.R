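# Steady-state molecule-number statistics. Active Pol II numbers are
# computed through the window-count identity: with deterministic removal
# a time tau after production, the number of active Pol II equals the
# number of production-marked firings in the trailing window of length
# tau, so its exact distribution follows from a count-augmented master
# equation integrated over one window starting from the stationary
# gene-state distribution. Mature mRNA distributions come from truncated
# chemical-master-equation solves: a deterministic time shift of a
# stationary arrival process leaves its statistics invariant, so the
# delayed production of M is statistically equivalent, at stationarity,
# to production directly on the marked transition.

#' Mean number of active Pol II in the mechanistic model
#'
#' `<n> = gamma * tau`, the stationary production flux times the
#' elongation delay (infinite-server occupancy).
#'
#' @param p a `mechanistic_params` object.
#' @return Mean number of active Pol II molecules.
#' @export
mean_active <- function(p) {
  stopifnot(inherits(p, "mechanistic_params"))
  stationary_flux(p) * p$tau
}

#' Mean number of mature mRNA in the mechanistic model
#'
#' `<m> = gamma / d` by flux balance of production against first-order
#' decay.
#'
#' @param p a `mechanistic_params` object with a positive decay rate `d`.
#' @return Mean number of mature mRNA molecules.
#' @export
mean_mature <- function(p) {
  stopifnot(inherits(p, "mechanistic_params"))
  if (is.null(p$d) || p$d <= 0)
    stop("mature-mRNA statistics require a positive decay rate 'd'",
         call. = FALSE)
  stationary_flux(p) / p$d
}

#' Fano factor of active Pol II in the delay telegraph model
#'
#' Closed form
#' `FF = 1 + 2 rho sigma_u (exp(-(sigma_b+sigma_u) tau) - 1) /
#' (tau (sigma_b+sigma_u)^3) + 2 rho sigma_u / (sigma_b+sigma_u)^2`,
#' with the analytic limit `FF -> 1` as `tau -> 0` and
#' `FF -> R` (the randomness parameter) as `tau -> Inf`.
#'
#' @param p a `delay_telegraph_params` object (or list with `rho`,
#'   `sigma_u`, `sigma_b`).
#' @param tau removal delay (s); defaults to `p$tau`.
#' @return Dimensionless Fano factor.
#' @export
fano_active_delay_telegraph <- function(p, tau = p$tau) {
  if (is.null(tau)) stop("a delay 'tau' is required", call. = FALSE)
  s <- p$sigma_b + p$sigma_u
  if (tau == 0) return(1)
  1 + 2 * p$rho * p$sigma_u * expm1(-s * tau) / (tau * s^3) +
    2 * p$rho * p$sigma_u / s^2
}

#' Fano factor of mature mRNA in the telegraph model
#'
#' Closed form
#' `FF = 1 + rho sigma_u / ((sigma_b+sigma_u)(sigma_b+d+sigma_u))`,
#' always >= 1.
#'
#' @param p a `telegraph_params` object.
#' @param d decay rate (s^-1); defaults to `p$d`.
#' @return Dimensionless Fano factor.
#' @export
fano_mature_telegraph <- function(p, d = p$d) {
  if (is.null(d)) stop("a decay rate 'd' is required", call. = FALSE)
  s <- p$sigma_b + p$sigma_u
  1 + p$rho * p$sigma_u / (s * (s + d))
}

#' Fano factor of mature mRNA in the mechanistic model
#'
#' Closed form
#' `FF = 1 + b c (a'(b'+c) - a(a'+d) - a^2) / ((a'(b'+c) + a(b'+b+c)) *
#' (a'(b'+c+d) + a(b'+b+c+d) + d(b'+b+c+d)))`. `FF >= 1` exactly when
#' `b' + c >= (a/a')(a + a' + d)`, the mature-number reducibility
#' condition.
#'
#' @param p a `mechanistic_params` object with positive `d`.
#' @return Dimensionless Fano factor (may be below 1).
#' @export
fano_mature_mechanistic <- function(p) {
  stopifnot(inherits(p, "mechanistic_params"))
  if (is.null(p$d) || p$d <= 0)
    stop("mature-mRNA statistics require a positive decay rate 'd'",
         call. = FALSE)
  with(p, 1 + b * c * (a_rev * (b_rev + c) - a * (a_rev + d) - a^2) /
         ((a_rev * (b_rev + c) + a * (b_rev + b + c)) *
          (a_rev * (b_rev + c + d) + a * (b_rev + b + c + d) +
           d * (b_rev + b + c + d))))
}

# ---- window-count engine -------------------------------------------------

default_nmax <- function(mean, R) {
  max(10L, ceiling(mean + 12 * sqrt(max(mean, 1e-12) * max(1, R))))
}

#' Distribution of production counts in a trailing window
#'
#' Integrates the joint master equation over (gene state, cumulative
#' production count) for a duration `window`, starting from the
#' stationary gene-state distribution with count zero. By the
#' window-count identity this marginal is the exact steady-state
#' distribution of active Pol II numbers for any model with deterministic
#' removal delay `window`. Probability that leaks past the count
#' truncation `n_max` is reported as the `deficit`.
#'
#' @param x a `gene_chain` or `gene_params` object.
#' @param window window length (s); defaults to the model's `tau`.
#' @param n_max count truncation; chosen adaptively when `NULL` as
#'   `mean + 12 sqrt(mean * max(1, R))`.
#' @param rtol,atol relative/absolute integrator tolerances (stiff-capable
#'   `lsoda`).
#' @param deficit_tol maximal tolerated truncation deficit.
#' @return A `count_distribution` object.
#' @examples
#' p <- mechanistic_params(0.112, 0.032, 0.16, 0.016, 0.24,
#'                         d = 0.016, tau = 100)
#' wd <- window_count_distribution(p)
#' number_moments(wd)   # mean 7.85, variance 6.19
#' @export
window_count_distribution <- function(x, window = NULL, n_max = NULL,
                                      rtol = 1e-10, atol = 1e-12,
                                      deficit_tol = 1e-9) {
  ch <- as_chain(x)
  if (is.null(window)) {
    if (inherits(x, "gene_params") && !is.null(x$tau)) window <- x$tau
    else stop("a 'window' length is required", call. = FALSE)
  }
  stopifnot(window >= 0)
  flux <- stationary_flux(ch)
  if (window == 0 || flux == 0) {
    return(new_count_distribution(c(1, rep(0, 9L)), deficit = 0,
                                  provenance = "window-ode"))
  }
  if (is.null(n_max)) {
    R <- waiting_moments(waiting_lt(ch), 2)$R
    n_max <- default_nmax(flux * window, R)
  }
  ns <- length(ch$states)
  K <- as.integer(n_max)
  # state: P[count block 0..K, gene state]; dP_n = P_n D0 + P_{n-1} D1
  rhs <- function(t, y, parms) {
    P <- matrix(y, nrow = K + 1L, ncol = ns)
    dP <- P %*% ch$D0
    dP[-1L, ] <- dP[-1L, ] + P[-(K + 1L), ] %*% ch$D1
    list(as.vector(dP))
  }
  y0 <- rep(0, (K + 1L) * ns)
  y0[1L + (seq_len(ns) - 1L) * (K + 1L)] <- ch$stationary
  sol <- deSolve::ode(y0, times = c(0, window), func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  P <- matrix(sol[2L, -1L], nrow = K + 1L, ncol = ns)
  pr <- pmax(rowSums(P), 0)
  deficit <- max(1 - sum(pr), 0)
  if (deficit >= deficit_tol)
    stop(sprintf(paste0("truncation deficit %.3g >= %.3g; ",
                        "increase 'n_max' (used %d)"),
                 deficit, deficit_tol, K), call. = FALSE)
  new_count_distribution(pr, deficit = deficit, provenance = "window-ode")
}

#' Raw moments of window counts via the moment master equation
#'
#' Exact first three raw moments of the number of production-marked
#' firings in a trailing window, from the closed linear ODE system for
#' `E[N^k 1_{state}]` (dimension `3 * n_states`, no count truncation).
#'
#' @inheritParams window_count_distribution
#' @param order highest raw-moment order (1 to 3).
#' @return Numeric vector of raw moments `E[N], E[N^2], E[N^3]`.
#' @export
window_count_moments <- function(x, window = NULL, order = 3,
                                 rtol = 1e-12, atol = 1e-14) {
  ch <- as_chain(x)
  if (is.null(window)) {
    if (inherits(x, "gene_params") && !is.null(x$tau)) window <- x$tau
    else stop("a 'window' length is required", call. = FALSE)
  }
  stopifnot(window >= 0, order >= 1, order <= 3)
  ns <- length(ch$states)
  if (window == 0) return(rep(0, order))
  piD1 <- as.numeric(ch$stationary %*% ch$D1)
  rhs <- function(t, y, parms) {
    m1 <- y[seq_len(ns)]
    m2 <- y[ns + seq_len(ns)]
    m3 <- y[2L * ns + seq_len(ns)]
    m1D1 <- as.numeric(m1 %*% ch$D1)
    m2D1 <- as.numeric(m2 %*% ch$D1)
    d1 <- as.numeric(m1 %*% ch$Q) + piD1
    d2 <- as.numeric(m2 %*% ch$Q) + 2 * m1D1 + piD1
    d3 <- as.numeric(m3 %*% ch$Q) + 3 * m2D1 + 3 * m1D1 + piD1
    list(c(d1, d2, d3))
  }
  sol <- deSolve::ode(rep(0, 3L * ns), times = c(0, window), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  y <- sol[2L, -1L]
  mom <- c(sum(y[seq_len(ns)]), sum(y[ns + seq_len(ns)]),
           sum(y[2L * ns + seq_len(ns)]))
  mom[seq_len(order)]
}

#' Fano factor of active Pol II in the mechanistic model
#'
#' Computed numerically exactly from the window-count moment equations.
#' Satisfies `FF -> 1` as `tau -> 0` and `FF -> R` (randomness parameter)
#' as `tau -> Inf`; for parameter sets with `R >= 1` the Fano factor dips
#' below 1 at intermediate `tau`. The Fano factor at zero mean is defined
#' as 1 by convention so limit statements remain total.
#'
#' @param p a `mechanistic_params` object (any marked chain works).
#' @param tau window length (s); defaults to `p$tau`.
#' @return Dimensionless Fano factor.
#' @export
fano_active_mechanistic <- function(p, tau = NULL) {
  ch <- as_chain(p)
  if (is.null(tau)) {
    if (inherits(p, "gene_params") && !is.null(p$tau)) tau <- p$tau
    else stop("a delay 'tau' is required", call. = FALSE)
  }
  if (tau == 0) return(1)
  mom <- window_count_moments(ch, tau, order = 2)
  if (mom[1] <= 0) return(1)
  (mom[2] - mom[1]^2) / mom[1]
}

# ---- truncated-CME steady states ----------------------------------------

#' Steady-state mature-mRNA distribution by truncated CME solve
#'
#' Builds the sparse generator over (gene state, mRNA count), with
#' production on the marked transitions and first-order decay at rate
#' `d * m`, truncates the count at `n_max` (production is blocked in the
#' top block) and solves the stationary linear system. Exact for the
#' telegraph and refractory models, and for the mechanistic model too,
#' because the deterministic elongation shift of a stationary production
#' process does not change the stationary mature-mRNA statistics.
#'
#' @param p a `gene_params` object with positive decay rate `d`.
#' @param n_max count truncation (adaptive when `NULL`).
#' @param deficit_tol maximal tolerated probability in the top count
#'   block (truncation-adequacy proxy).
#' @return A `count_distribution` object.
#' @examples
#' tp <- telegraph_params(0.09, 0.012, 0.029, d = 0.0016)
#' md <- mature_distribution(tp)
#' number_moments(md)
#' @export
mature_distribution <- function(p, n_max = NULL, deficit_tol = 1e-9) {
  stopifnot(inherits(p, "gene_params"))
  if (is.null(p$d) || p$d <= 0)
    stop("mature-mRNA statistics require a positive decay rate 'd'",
         call. = FALSE)
  ch <- as_chain(p)
  if (is.null(n_max)) {
    mu <- stationary_flux(ch) / p$d
    ff <- if (inherits(p, "mechanistic_params")) fano_mature_mechanistic(p)
          else if (inherits(p, "telegraph_params")) fano_mature_telegraph(p)
          else waiting_moments(waiting_lt(ch), 2)$R
    n_max <- default_nmax(mu, max(1, ff))
  }
  cme_stationary(ch, d = p$d, n_max = as.integer(n_max),
                 deficit_tol = deficit_tol)
}

cme_stationary <- function(ch, d, n_max, deficit_tol = 1e-9) {
  ns <- length(ch$states)
  K <- n_max
  nst <- ns * (K + 1L)
  idx <- function(state, m) (m) * ns + state  # 1-based state, m in 0..K
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(from, to, rate) {
    ii <<- c(ii, from); jj <<- c(jj, to); vv <<- c(vv, rate)
  }
  for (m in 0:K) {
    for (s in seq_len(ns)) {
      from <- idx(s, m)
      for (j in seq_len(ns)) {
        r0 <- ch$D0[s, j]
        if (j != s && r0 > 0) add(from, idx(j, m), r0)
        r1 <- ch$D1[s, j]
        if (r1 > 0 && m < K) add(from, idx(j, m + 1L), r1)
        # production blocked at m = K (conservative truncation)
      }
      if (m > 0 && d > 0) add(from, idx(s, m - 1L), m * d)
    }
  }
  Qt <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nst, nst))
  Qt <- Qt - Matrix::Diagonal(x = Matrix::rowSums(Qt))
  A <- Matrix::t(Qt)
  A[nst, ] <- 1
  b <- c(rep(0, nst - 1L), 1)
  pivec <- as.numeric(Matrix::solve(A, b))
  P <- matrix(pivec, nrow = ns, ncol = K + 1L)
  pr <- pmax(colSums(P), 0)
  pr <- pr / sum(pr)
  deficit <- pr[K + 1L]   # mass pressed against the truncation boundary
  if (deficit >= deficit_tol)
    stop(sprintf("probability %.3g at the count truncation >= %.3g; increase 'n_max' (used %d)",
                 deficit, deficit_tol, K), call. = FALSE)
  new_count_distribution(pr, deficit = deficit, provenance = "cme-solve")
}

#' Steady-state active Pol II distribution
#'
#' Dispatches to the window-count engine with window `tau`; valid for the
#' mechanistic and delay-telegraph models (and any chain with
#' deterministic removal).
#'
#' @param p a `gene_params` object with positive `tau`.
#' @param ... passed to [window_count_distribution()].
#' @return A `count_distribution` object.
#' @export
active_distribution <- function(p, ...) {
  stopifnot(inherits(p, "gene_params"))
  if (is.null(p$tau) || p$tau <= 0)
    stop("active Pol II statistics require a positive delay 'tau'",
         call. = FALSE)
  window_count_distribution(p, window = p$tau, ...)
}

# ---- count-distribution container ---------------------------------------

new_count_distribution <- function(p, deficit, provenance) {
  structure(list(p = as.numeric(p), support = seq_along(p) - 1L,
                 deficit = deficit, provenance = provenance),
            class = "count_distribution")
}

#' Construct a count distribution from probabilities
#'
#' @param p probabilities over counts `0:(length(p) - 1)`.
#' @param provenance free-text origin tag (e.g. `"simulation"`).
#' @return A `count_distribution` object; the shortfall of `sum(p)` from
#'   one is stored as the `deficit`.
#' @export
count_distribution <- function(p, provenance = "analytic") {
  if (any(p < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (sum(p) > 1 + 1e-8) stop("probabilities sum to more than 1",
                              call. = FALSE)
  new_count_distribution(p, deficit = max(0, 1 - sum(p)),
                         provenance = provenance)
}

#' Empirical count distribution from samples
#'
#' @param n non-negative integer molecule-number samples.
#' @return A `count_distribution` with `provenance = "simulation"`.
#' @export
empirical_distribution <- function(n) {
  stopifnot(all(n >= 0))
  tab <- tabulate(n + 1L, nbins = max(n) + 1L)
  new_count_distribution(tab / length(n), deficit = 0,
                         provenance = "simulation")
}

#' Moments of a count distribution
#'
#' @param dist a `count_distribution`.
#' @param order highest raw-moment order.
#' @return `count_moments`: raw moments; `number_moments`: a list with
#'   `mean`, `variance` and `fano` (defined as 1 at zero mean).
#' @export
count_moments <- function(dist, order = 3) {
  stopifnot(inherits(dist, "count_distribution"))
  vapply(seq_len(order),
         function(k) sum(dist$p * dist$support^k), 0)
}

#' @rdname count_moments
#' @export
number_moments <- function(dist) {
  m <- count_moments(dist, 2)
  v <- m[2] - m[1]^2
  list(mean = m[1], variance = v,
       fano = if (m[1] > 0) v / m[1] else 1)
}

#' Hellinger distance between two count distributions
#'
#' `h = sqrt(sum((sqrt(p) - sqrt(q))^2) / 2)` on the zero-padded union
#' support, after renormalizing each distribution; comparison requires
#' both truncation deficits below `deficit_tol`.
#'
#' @param p,q `count_distribution` objects.
#' @param deficit_tol maximal deficit for a valid comparison.
#' @return Dimensionless distance in `[0, 1]`.
#' @examples
#' hellinger(count_distribution(c(1, 0)), count_distribution(c(0.5, 0.5)))
#' @export
hellinger <- function(p, q, deficit_tol = 1e-6) {
  stopifnot(inherits(p, "count_distribution"),
            inherits(q, "count_distribution"))
  if (p$deficit >= deficit_tol || q$deficit >= deficit_tol)
    stop("truncation deficit too large for a valid Hellinger comparison",
         call. = FALSE)
  n <- max(length(p$p), length(q$p))
  pp <- c(p$p, rep(0, n - length(p$p))); pp <- pp / sum(pp)
  qq <- c(q$p, rep(0, n - length(q$p))); qq <- qq / sum(qq)
  min(1, sqrt(sum((sqrt(pp) - sqrt(qq))^2) / 2))
}

#' @export
print.count_distribution <- function(x, ...) {
  nm <- number_moments(x)
  cat(sprintf("<count distribution (%s): support 0..%d>\n",
              x$provenance, max(x$support)))
  cat(sprintf("mean %.6g, variance %.6g, Fano %.6g, deficit %.3g\n",
              nm$mean, nm$variance, nm$fano, x$deficit))
  invisible(x)
}

#' @export
plot.count_distribution <- function(x, ...) {
  graphics::plot(x$support, x$p, type = "h", xlab = "molecule number",
                 ylab = "probability", ...)
  invisible(x)
}
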