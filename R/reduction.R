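# Model reduction: mapping the mechanistic model onto two-state
# (telegraph / delay telegraph) and refractory models, by closed-form
# waiting-time moment matching, numerical number-moment matching, or
# maximum likelihood on molecule-number samples.

#' Feasibility parameter Delta of the reduction map
#'
#' `Delta = b' + c - a - a^2 / a'` (s^-1). `Delta >= 0` is equivalent to
#' the waiting-time reducibility condition
#' `b' + c >= (a/a')(a + a')` and to a mechanistic randomness parameter
#' `R >= 1`.
#'
#' @param p a `mechanistic_params` object.
#' @return Delta (s^-1).
#' @export
reduction_delta <- function(p) {
  with(p, b_rev + c - a - a^2 / a_rev)
}

#' Reducibility conditions of the mechanistic model
#'
#' @param p a `mechanistic_params` object.
#' @return A list with `waiting` (`b'+c >= (a/a')(a+a')`, i.e.
#'   `Delta >= 0`: two-state models can match the first three waiting-time
#'   moments) and `mature_number`
#'   (`b'+c >= (a/a')(a+a'+d)`: the mature-mRNA Fano factor is >= 1, so
#'   number-moment matching of the telegraph model is possible; `NA` when
#'   `d` is not set). The first condition failing implies the second
#'   fails.
#' @export
is_reducible <- function(p) {
  stopifnot(inherits(p, "mechanistic_params"))
  w <- with(p, b_rev + c >= a / a_rev * (a + a_rev))
  m <- if (is.null(p$d)) NA else
    with(p, b_rev + c >= a / a_rev * (a + a_rev + d))
  list(waiting = w, mature_number = m)
}

#' Closed-form two-state effective parameters
#'
#' The unique telegraph-model parameters whose first three waiting-time
#' moments equal those of the mechanistic model:
#' `rho = b c a' (Delta a' + a^2) / D`,
#' `sigma_u = Delta^3 a'^4 / ((Delta a' + a^2) D)`,
#' `sigma_b = a Delta a' / (Delta a' + a^2)`, with
#' `D = a'(a'(Delta a' + a^2 + 3 a Delta + Delta(b + Delta)) +
#' a^2(2a + b + 2 Delta)) + a^4`. Requires `Delta >= 0`; at
#' `Delta = 0` the map returns `sigma_u = 0` (constitutive limit). The
#' telegraph variant inherits `d`, the delay-telegraph variant inherits
#' `tau`.
#'
#' @param p a `mechanistic_params` object with `Delta >= 0`.
#' @param variant `"telegraph"` (mature mRNA) or `"delay_telegraph"`
#'   (active Pol II).
#' @return A `two_state_params` object of the requested variant.
#' @examples
#' p <- mechanistic_params(0.032, 0.032, 0.16, 0.016, 0.32,
#'                         d = 0.0016, tau = 273.62)
#' effective_two_state(p)   # sigma_u ~ 0.012, sigma_b ~ 0.029
#' @export
effective_two_state <- function(p, variant = c("telegraph",
                                               "delay_telegraph")) {
  stopifnot(inherits(p, "mechanistic_params"))
  variant <- match.arg(variant)
  Delta <- reduction_delta(p)
  if (Delta < 0)
    stop(sprintf(paste0("Delta = %.4g < 0: no two-state model matches the ",
                        "first three waiting-time moments (an effective ",
                        "parameter would be negative)"), Delta),
         call. = FALSE)
  m <- two_state_map(p$a, p$a_rev, p$b, p$b_rev, p$c)
  if (variant == "telegraph") {
    if (is.null(p$d))
      stop("the telegraph variant inherits 'd', which is not set",
           call. = FALSE)
    telegraph_params(m$rho, m$sigma_u, m$sigma_b, d = p$d)
  } else {
    if (is.null(p$tau) || p$tau <= 0)
      stop("the delay-telegraph variant inherits 'tau', which is not set",
           call. = FALSE)
    delay_telegraph_params(m$rho, m$sigma_u, m$sigma_b, tau = p$tau)
  }
}

# vectorized closed-form map; also used by the sensitivity screen
two_state_map <- function(a, a_rev, b, b_rev, c) {
  Delta <- b_rev + c - a - a^2 / a_rev
  g <- Delta * a_rev + a^2
  D <- a_rev * (a_rev * (g + 3 * a * Delta + Delta * (b + Delta)) +
                a^2 * (2 * a + b + 2 * Delta)) + a^4
  list(delta = Delta,
       rho = b * c * a_rev * g / D,
       sigma_u = Delta^3 * a_rev^4 / (g * D),
       sigma_b = a * Delta * a_rev / g)
}

#' Fast-switching limit of the reduction map
#'
#' When `min(b, b') >> max(a, a')` the paused and unpaused promoter
#' states merge into one effective on state and the map reduces to
#' `sigma_b = a`, `sigma_u = a' b' / (b + b')`, `rho = c b / (b + b')`.
#'
#' @inheritParams effective_two_state
#' @return A `two_state_params` object.
#' @export
fast_switching_limit <- function(p, variant = c("telegraph",
                                                "delay_telegraph")) {
  stopifnot(inherits(p, "mechanistic_params"))
  variant <- match.arg(variant)
  rho <- p$c * p$b / (p$b + p$b_rev)
  su <- p$a_rev * p$b_rev / (p$b + p$b_rev)
  if (variant == "telegraph")
    telegraph_params(rho, su, p$a, d = p$d)
  else
    delay_telegraph_params(rho, su, p$a, tau = p$tau)
}

# damped Newton in log-parameter space on a relative-residual function
newton_log <- function(resid_fn, start, tol = 1e-10, max_iter = 200,
                       fd_step = 1e-6) {
  l <- log(start)
  r <- resid_fn(exp(l))
  iter <- 0L
  while (iter < max_iter && sqrt(mean(r^2)) > tol) {
    iter <- iter + 1L
    J <- matrix(0, length(r), length(l))
    for (k in seq_along(l)) {
      lp <- l; lp[k] <- lp[k] + fd_step
      lm <- l; lm[k] <- lm[k] - fd_step
      J[, k] <- (resid_fn(exp(lp)) - resid_fn(exp(lm))) / (2 * fd_step)
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (h in 1:30) {
      lnew <- l - lambda * step
      rnew <- tryCatch(resid_fn(exp(lnew)), error = function(e) NULL)
      if (!is.null(rnew) && all(is.finite(rnew)) &&
          sqrt(mean(rnew^2)) < sqrt(mean(r^2))) {
        l <- lnew; r <- rnew; improved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  list(par = exp(l), residuals = r, iterations = iter,
       converged = sqrt(mean(r^2)) <= tol)
}

new_reduction_result <- function(delta, feasible_waiting,
                                 feasible_mature_number, mapped, method,
                                 converged = TRUE, diagnostics = list()) {
  structure(list(delta = delta, feasible_waiting = feasible_waiting,
                 feasible_mature_number = feasible_mature_number,
                 mapped = mapped, method = method, converged = converged,
                 diagnostics = diagnostics),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("<model reduction (%s)>\n", x$method))
  if (!is.null(x$delta) && !is.na(x$delta))
    cat(sprintf("Delta = %.6g 1/s (waiting-time matching %s)\n", x$delta,
                if (isTRUE(x$feasible_waiting)) "feasible" else "infeasible"))
  if (!is.null(x$mapped)) {
    cat("mapped parameters:\n")
    print(x$mapped)
  } else cat("no mapped parameters\n")
  if (!isTRUE(x$converged)) cat("NOTE: solver did not converge\n")
  if (length(x$diagnostics$residuals))
    cat("max |relative residual| =",
        format(max(abs(x$diagnostics$residuals)), digits = 3), "\n")
  invisible(x)
}

#' Two-state parameters by numerical number-moment matching
#'
#' Root-finds telegraph-family parameters whose first three raw
#' molecule-number moments equal those of the mechanistic model, by
#' damped Newton iteration in log-parameter space starting from the
#' closed-form map. For `species = "active"` both sides use the exact
#' window-count moment equations (window `tau`); for `species = "mature"`
#' both sides use truncated-CME steady states.
#'
#' @param p a `mechanistic_params` object.
#' @param species `"active"` (delay-telegraph target) or `"mature"`
#'   (telegraph target).
#' @param tol relative residual tolerance.
#' @param max_iter Newton iteration cap.
#' @return A `reduction_result`; `converged = FALSE` flags a failed
#'   search (expected when `Delta < 0`, where no two-state model has
#'   matching moments).
#' @export
match_number_moments <- function(p, species = c("active", "mature"),
                                 tol = 1e-10, max_iter = 200) {
  stopifnot(inherits(p, "mechanistic_params"))
  species <- match.arg(species)
  delta <- reduction_delta(p)
  feas <- is_reducible(p)
  start <- if (delta > 0) {
    m <- two_state_map(p$a, p$a_rev, p$b, p$b_rev, p$c)
    c(rho = m$rho, sigma_u = max(m$sigma_u, 1e-8), sigma_b = m$sigma_b)
  } else {
    c(rho = stationary_flux(p) * 2, sigma_u = p$a_rev, sigma_b = p$a)
  }
  if (species == "active") {
    if (is.null(p$tau) || p$tau <= 0)
      stop("'tau' must be positive for active Pol II matching",
           call. = FALSE)
    target <- window_count_moments(p, p$tau, order = 3)
    model_mom <- function(th) {
      q <- delay_telegraph_params(th[1], th[2], th[3], tau = p$tau)
      window_count_moments(q, p$tau, order = 3)
    }
  } else {
    if (is.null(p$d) || p$d <= 0)
      stop("'d' must be positive for mature mRNA matching", call. = FALSE)
    target <- count_moments(mature_distribution(p), 3)
    model_mom <- function(th) {
      q <- telegraph_params(th[1], th[2], th[3], d = p$d)
      count_moments(mature_distribution(q), 3)
    }
  }
  fit <- newton_log(function(th) (model_mom(th) - target) / target,
                    start, tol = tol, max_iter = max_iter)
  mapped <- if (fit$converged) {
    if (species == "active")
      delay_telegraph_params(fit$par[1], fit$par[2], fit$par[3],
                             tau = p$tau)
    else telegraph_params(fit$par[1], fit$par[2], fit$par[3], d = p$d)
  } else NULL
  new_reduction_result(delta, feas$waiting, feas$mature_number, mapped,
                       method = "moment-match", converged = fit$converged,
                       diagnostics = list(residuals = fit$residuals,
                                          iterations = fit$iterations,
                                          target_moments = target))
}

#' Refractory parameters by four-moment waiting-time matching
#'
#' Numerically solves for the four refractory-model rates whose first
#' four waiting-time moments equal those of the mechanistic model
#' (necessary condition: `R >= 1`, i.e. `Delta >= 0`). The refractory
#' family nests the telegraph model as `sigma_u_star -> Inf`, where the
#' Jacobian in `sigma_u_star` degenerates, so a plain four-dimensional
#' Newton search is unreliable; instead the solver follows a continuation
#' path: for each `sigma_u_star` on a geometric grid descending from the
#' telegraph limit it re-solves `(rho, sigma_u, sigma_b)` so the first
#' three moments match exactly, tracks the remaining fourth-moment
#' residual along the path, brackets its sign change, finishes with a
#' scalar root solve, and polishes with a full four-moment Newton step.
#' A four-moment match does not exist for every `Delta >= 0` parameter
#' set (the constrained fourth moment can stay strictly above its
#' mechanistic target along the entire path); such cases are reported
#' with `converged = FALSE` and the smallest attainable fourth-moment
#' residual in the diagnostics.
#'
#' @param p a `mechanistic_params` object with `Delta >= 0`.
#' @param tol relative residual tolerance on the four moments.
#' @param max_iter Newton iteration cap per inner solve.
#' @return A `reduction_result` with a `refractory_params` object in
#'   `mapped` when converged.
#' @export
match_refractory <- function(p, tol = 1e-10, max_iter = 200) {
  stopifnot(inherits(p, "mechanistic_params"))
  delta <- reduction_delta(p)
  feas <- is_reducible(p)
  if (delta < 0)
    stop(sprintf(paste0("Delta = %.4g < 0: R < 1, and the refractory ",
                        "randomness parameter always exceeds 1"), delta),
         call. = FALSE)
  target <- waiting_moments(waiting_lt(p), order = 4)$moments
  m4rel_at <- function(th, sus) {
    q <- refractory_params(th[1], th[2], sus, th[3])
    mm <- waiting_moments(waiting_lt(q), order = 4)$moments
    (mm[4] - target[4]) / target[4]
  }
  inner <- function(sus, start) {
    newton_log(function(th) {
      q <- refractory_params(th[1], th[2], sus, th[3])
      mm <- waiting_moments(waiting_lt(q), order = 4)$moments
      (mm[1:3] - target[1:3]) / target[1:3]
    }, start, tol = 1e-13, max_iter = max_iter, fd_step = 1e-7)
  }
  m <- two_state_map(p$a, p$a_rev, p$b, p$b_rev, p$c)
  start <- c(rho = m$rho, sigma_u = max(m$sigma_u, 1e-9),
             sigma_b = m$sigma_b)
  sus0 <- 100 * (m$sigma_b + max(m$sigma_u, 1e-9))
  grid <- sus0 * 0.93^(0:180)
  prev <- NULL    # list(sus, m4, par)
  bracket <- NULL
  best_abs <- Inf; best_point <- NULL
  for (sus in grid) {
    fit <- tryCatch(inner(sus, start), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) break
    start <- fit$par
    m4 <- m4rel_at(fit$par, sus)
    if (abs(m4) < best_abs) {
      best_abs <- abs(m4); best_point <- list(sus = sus, par = fit$par)
    }
    if (!is.null(prev) && sign(m4) != sign(prev$m4)) {
      bracket <- list(lo = sus, hi = prev$sus, par = fit$par)
      break
    }
    prev <- list(sus = sus, m4 = m4, par = fit$par)
  }
  sol <- NULL
  if (!is.null(bracket)) {
    g <- function(lsus) {
      fit <- inner(exp(lsus), bracket$par)
      bracket$par <<- fit$par
      m4rel_at(fit$par, exp(lsus))
    }
    rt <- tryCatch(stats::uniroot(g, lower = log(bracket$lo),
                                  upper = log(bracket$hi), tol = 1e-14),
                   error = function(e) NULL)
    if (!is.null(rt)) {
      sus <- exp(rt$root)
      fit <- inner(sus, bracket$par)
      # polish on all four moments simultaneously
      pol <- tryCatch(newton_log(function(th) {
        q <- refractory_params(th[1], th[2], th[3], th[4])
        mm <- waiting_moments(waiting_lt(q), order = 4)$moments
        (mm - target) / target
      }, c(fit$par[1], fit$par[2], sus, fit$par[3]), tol = tol,
      max_iter = 50), error = function(e) NULL)
      if (!is.null(pol) && pol$converged) sol <- pol
      else sol <- list(par = c(fit$par[1], fit$par[2], sus, fit$par[3]),
                       residuals = c(fit$residuals,
                                     m4rel_at(fit$par, sus)),
                       iterations = fit$iterations,
                       converged = max(abs(c(fit$residuals,
                                             m4rel_at(fit$par, sus)))) < 1e-6)
    }
  }
  if (is.null(sol)) {
    return(new_reduction_result(delta, feas$waiting, feas$mature_number,
                                NULL, "refractory-moment-match",
                                converged = FALSE,
                                diagnostics = list(
                                  residuals = best_abs,
                                  note = paste("no four-moment match on the",
                                               "continuation path"),
                                  best_sigma_u_star = best_point$sus,
                                  target_moments = target)))
  }
  mapped <- refractory_params(sol$par[1], sol$par[2], sol$par[3],
                              sol$par[4], d = p$d,
                              tau = if (!is.null(p$tau) && p$tau > 0)
                                p$tau else NULL)
  new_reduction_result(delta, feas$waiting, feas$mature_number, mapped,
                       method = "refractory-moment-match",
                       converged = sol$converged,
                       diagnostics = list(residuals = sol$residuals,
                                          iterations = sol$iterations,
                                          target_moments = target))
}

#' Maximum-likelihood two-state fit to molecule-number samples
#'
#' Maximizes the log likelihood of integer molecule-number samples under
#' the telegraph model (`species = "mature"`, needs the decay rate `d`)
#' or the delay telegraph model (`species = "active"`, needs the delay
#' `tau`), over `(rho, sigma_u, sigma_b)` in log space with a
#' derivative-free simplex search and multiple starts around a
#' moment-based initial guess.
#'
#' @param samples non-negative integer molecule numbers (>= 100 values).
#' @param species `"mature"` or `"active"`.
#' @param d decay rate (s^-1), required for `species = "mature"`.
#' @param tau removal delay (s), required for `species = "active"`.
#' @param n_starts number of optimizer starts (first from the
#'   moment-based guess, the rest log-perturbed).
#' @param seed integer seed for the start perturbations.
#' @param maxit simplex iteration cap per start.
#' @return A `reduction_result` with the fitted parameters, the
#'   log likelihood and the Hellinger distance between the fitted and the
#'   empirical distribution in `diagnostics`.
#' @export
mle_two_state <- function(samples, species = c("mature", "active"),
                          d = NULL, tau = NULL, n_starts = 5, seed = 1,
                          maxit = 500) {
  species <- match.arg(species)
  samples <- as.integer(round(samples))
  if (length(samples) < 100)
    stop("at least 100 samples are required", call. = FALSE)
  if (any(samples < 0)) stop("negative molecule numbers", call. = FALSE)
  if (all(samples == 0))
    stop("degenerate samples: all molecule numbers are zero", call. = FALSE)
  if (species == "mature" && (is.null(d) || d <= 0))
    stop("'d' must be supplied for mature-mRNA fits", call. = FALSE)
  if (species == "active" && (is.null(tau) || tau <= 0))
    stop("'tau' must be supplied for active Pol II fits", call. = FALSE)
  counts <- tabulate(samples + 1L, nbins = max(samples) + 1L)
  n_max <- max(samples) + max(10L, ceiling(2 * sqrt(max(samples) + 1)))
  pmf <- function(th) {
    q <- if (species == "mature")
      telegraph_params(th[1], th[2], th[3], d = d)
    else delay_telegraph_params(th[1], th[2], th[3], tau = tau)
    dist <- if (species == "mature")
      mature_distribution(q, n_max = n_max, deficit_tol = 0.01)
    else window_count_distribution(q, window = tau, n_max = n_max,
                                   deficit_tol = 0.01)
    dist
  }
  negll <- function(l) {
    th <- exp(l)
    dist <- tryCatch(pmf(th), error = function(e) NULL)
    if (is.null(dist)) return(1e12)
    pr <- pmax(dist$p[seq_along(counts)], 1e-300)
    -sum(counts * log(pr))
  }
  mu <- mean(samples)
  ff <- stats::var(samples) / mu
  scale0 <- if (species == "mature") d else 1 / tau
  base <- c(rho = max(mu * scale0 * max(ff, 1.5), 1e-6),
            sigma_u = scale0 * max(ff - 1, 0.5),
            sigma_b = scale0)
  set.seed(as.integer(seed))
  best <- NULL
  for (k in seq_len(n_starts)) {
    l0 <- log(base) + if (k == 1) 0 else stats::runif(3, -1.5, 1.5)
    opt <- stats::optim(l0, negll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  th <- exp(best$par)
  fitted <- if (species == "mature")
    telegraph_params(th[1], th[2], th[3], d = d)
  else delay_telegraph_params(th[1], th[2], th[3], tau = tau)
  h <- tryCatch(hellinger(pmf(th), empirical_distribution(samples),
                          deficit_tol = 0.01),
                error = function(e) NA_real_)
  new_reduction_result(NA_real_, NA, NA, fitted, method = "mle",
                       converged = best$convergence == 0,
                       diagnostics = list(logLik = -best$value,
                                          hellinger = h,
                                          n_samples = length(samples)))
}

#' Reduce the mechanistic model to a two-state model
#'
#' One front end to the three reduction routes: the closed-form
#' waiting-time map (`"closed-form"`), numerical number-moment matching
#' (`"moments"`), or maximum likelihood on delay-SSA samples drawn from
#' the mechanistic model itself (`"mle"`).
#'
#' @param p a `mechanistic_params` object.
#' @param method reduction route.
#' @param species which transcript species the reduced model describes.
#' @param n_samples,seed delay-SSA sample size and seed (MLE route only).
#' @param ... passed on to the underlying routine.
#' @return A `reduction_result`.
#' @export
reduce_model <- function(p, method = c("closed-form", "moments", "mle"),
                         species = c("active", "mature"),
                         n_samples = 10000, seed = 1, ...) {
  stopifnot(inherits(p, "mechanistic_params"))
  method <- match.arg(method)
  species <- match.arg(species)
  if (method == "closed-form") {
    delta <- reduction_delta(p)
    feas <- is_reducible(p)
    mapped <- if (delta >= 0)
      effective_two_state(p, variant = if (species == "active")
        "delay_telegraph" else "telegraph")
    else NULL
    return(new_reduction_result(delta, feas$waiting, feas$mature_number,
                                mapped, method = "closed-form"))
  }
  if (method == "moments") return(match_number_moments(p, species, ...))
  sim <- simulate_counts(p, n_samples = n_samples, seed = seed)
  x <- if (species == "active") sim$n_active else sim$n_mature
  out <- mle_two_state(x, species = species, d = p$d, tau = p$tau,
                       seed = seed, ...)
  out$delta <- reduction_delta(p)
  feas <- is_reducible(p)
  out$feasible_waiting <- feas$waiting
  out$feasible_mature_number <- feas$mature_number
  out
}
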