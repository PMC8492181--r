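# Sensitivity of the effective two-state parameters (rho, sigma_u,
# sigma_b, and the burst size beta = rho/sigma_u) to the mechanistic
# rates (a, a', b, b', c), via log-derivatives of the closed-form
# reduction map.

mech_names <- c("a", "a_rev", "b", "b_rev", "c")
tele_names <- c("rho", "sigma_u", "sigma_b", "beta")

# signed d log(theta_tele) / d log(theta_mec); central differences in log
# space, vectorized over rows of the mechanistic parameter matrix
signed_log_sens <- function(mech, step = 1e-6) {
  mech <- as.matrix(mech)
  colnames(mech) <- mech_names
  eval_map <- function(m) {
    r <- two_state_map(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5])
    cbind(rho = r$rho, sigma_u = r$sigma_u, sigma_b = r$sigma_b,
          beta = r$rho / r$sigma_u)
  }
  out <- array(NA_real_, dim = c(nrow(mech), 4L, 5L),
               dimnames = list(NULL, tele_names, mech_names))
  for (j in seq_len(5L)) {
    up <- mech; up[, j] <- up[, j] * exp(step)
    dn <- mech; dn[, j] <- dn[, j] * exp(-step)
    out[, , j] <- (log(eval_map(up)) - log(eval_map(dn))) / (2 * step)
  }
  out
}

#' Relative sensitivities of the two-state parameters
#'
#' Computes `sen(theta_tele, theta_mec) = |d log(theta_tele) /
#' d log(theta_mec)|` for each pair, by central differences in
#' log-parameter space on the closed-form reduction map. Also returns the
#' signed log-derivatives (used for the sign table) and, per two-state
#' parameter, the ordered most- and least-sensitive pair of mechanistic
#' parameters.
#'
#' @param p a `mechanistic_params` object with `Delta > 0`.
#' @param step central-difference step in log space.
#' @return An object of class `sensitivity_record`: list with `sens`
#'   (4 x 5 matrix of absolute sensitivities; rows `rho`, `sigma_u`,
#'   `sigma_b`, `beta`), `signed`, `most` and `least` (character vectors
#'   of ordered pairs).
#' @export
relative_sensitivities <- function(p, step = 1e-6) {
  stopifnot(inherits(p, "mechanistic_params"))
  if (reduction_delta(p) <= 0)
    stop("sensitivities are defined only where Delta > 0", call. = FALSE)
  mech <- matrix(c(p$a, p$a_rev, p$b, p$b_rev, p$c), nrow = 1)
  signed <- signed_log_sens(mech, step)[1, , ]
  sens <- abs(signed)
  ord <- t(apply(sens, 1, order, decreasing = TRUE))
  most <- apply(ord[, 1:2, drop = FALSE], 1,
                function(ix) paste(mech_names[ix], collapse = ","))
  least <- apply(ord[, 5:4, drop = FALSE], 1,
                 function(ix) paste(mech_names[ix], collapse = ","))
  structure(list(params = p, sens = sens, signed = signed,
                 most = stats::setNames(most, tele_names),
                 least = stats::setNames(least, tele_names)),
            class = "sensitivity_record")
}

#' @export
print.sensitivity_record <- function(x, ...) {
  cat("<relative sensitivities |d log(theta_tele) / d log(theta_mec)|>\n")
  print(signif(x$sens, 4))
  cat("most sensitive (ordered pair): ",
      paste(sprintf("%s:{%s}", names(x$most), x$most), collapse = "  "),
      "\n")
  cat("least sensitive (ordered pair):",
      paste(sprintf("%s:{%s}", names(x$least), x$least), collapse = "  "),
      "\n")
  invisible(x)
}

#' Empirical sign table of the reduction-map derivatives
#'
#' Samples mechanistic parameter sets log-uniformly, keeps those with
#' `Delta > 0`, and summarizes the sign of each derivative
#' `d theta_tele / d theta_mec` across the sample: `"+"`, `"-"`, `"0"`
#' (identically zero, e.g. `sigma_b` versus `b`) or `"+-"` when both
#' signs occur.
#'
#' @param n number of retained `Delta > 0` parameter sets.
#' @param seed integer seed.
#' @param range log-uniform sampling range for every rate (s^-1).
#' @param zero_tol absolute threshold below which a log-derivative counts
#'   as zero.
#' @return A 4 x 5 character matrix (rows `rho`, `sigma_u`, `sigma_b`,
#'   `beta`; columns `a`, `a_rev`, `b`, `b_rev`, `c`).
#' @export
sign_table <- function(n = 1000, seed = 1, range = c(1e-4, 10),
                       zero_tol = 1e-7) {
  set.seed(as.integer(seed))
  mech <- sample_mechanistic(n, range, require_delta_pos = TRUE)
  sl <- signed_log_sens(mech)
  out <- matrix("", 4, 5, dimnames = list(tele_names, mech_names))
  for (i in 1:4) for (j in 1:5) {
    v <- sl[, i, j]
    pos <- any(v > zero_tol); neg <- any(v < -zero_tol)
    out[i, j] <- if (pos && neg) "+-" else if (pos) "+"
      else if (neg) "-" else "0"
  }
  out
}

# log-uniform draws of (a, a', b, b', c); optionally rejection-sampled to
# the reducible region Delta > 0
sample_mechanistic <- function(n, range = c(1e-4, 10),
                               require_delta_pos = FALSE) {
  acc <- matrix(numeric(0), 0, 5)
  while (nrow(acc) < n) {
    m <- matrix(exp(stats::runif(5 * 2 * n, log(range[1]), log(range[2]))),
                ncol = 5)
    if (require_delta_pos) {
      delta <- m[, 4] + m[, 5] - m[, 1] - m[, 1]^2 / m[, 2]
      m <- m[delta > 0, , drop = FALSE]
    }
    acc <- rbind(acc, m)
  }
  acc <- acc[seq_len(n), , drop = FALSE]
  colnames(acc) <- mech_names
  acc
}

#' Specification of a constrained parameter screen
#'
#' Describes the experimental targets and the sampling scheme for a
#' random screen of mechanistic parameter sets whose mapped two-state
#' parameters reproduce measured values (e.g. for the Oct4 and Nanog
#' genes): a draw is accepted when all three mapped parameters fall
#' within `k` experimental errors of the targets.
#'
#' @param targets named numeric vector with `rho`, `sigma_u`, `sigma_b`
#'   (s^-1).
#' @param errors named numeric vector of experimental errors (s^-1),
#'   strictly positive.
#' @param k acceptance multiple of the experimental errors.
#' @param range log-uniform sampling range for all five mechanistic rates
#'   (s^-1).
#' @param n_accept target number of accepted sets.
#' @param max_draws cap on the total number of draws.
#' @return An object of class `screen_spec`.
#' @export
screen_spec <- function(targets, errors, k = 2, range = c(1e-4, 10),
                        n_accept = 1000, max_draws = 2e7) {
  targets <- targets[c("rho", "sigma_u", "sigma_b")]
  errors <- errors[c("rho", "sigma_u", "sigma_b")]
  stopifnot(!anyNA(targets), !anyNA(errors), all(errors > 0),
            length(range) == 2, all(range > 0), range[1] < range[2])
  structure(list(targets = targets, errors = errors, k = k, range = range,
                 n_accept = n_accept, max_draws = max_draws),
            class = "screen_spec")
}

#' Constrained random screening of mechanistic parameters
#'
#' Draws mechanistic parameter sets log-uniformly, maps them through the
#' closed-form reduction, accepts sets whose mapped `(rho, sigma_u,
#' sigma_b)` all lie within `k` experimental errors of the targets, and
#' for each accepted set records the ordered most- and least-sensitive
#' pair of mechanistic parameters per two-state parameter (the data
#' behind most/least-sensitive proportion summaries).
#'
#' @param spec a [screen_spec()].
#' @param seed integer seed.
#' @return An object of class `screen_result`: list with `accepted` (a
#'   `data.frame` of mechanistic and mapped parameters), `most` / `least`
#'   (lists of proportion tables per two-state parameter), `n_draws` and
#'   `acceptance_rate`.
#' @export
screen_parameters <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "screen_spec"))
  set.seed(as.integer(seed))
  lo <- spec$targets - spec$k * spec$errors
  hi <- spec$targets + spec$k * spec$errors
  acc <- NULL
  drawn <- 0
  batch <- 200000L
  while (drawn < spec$max_draws &&
         (is.null(acc) || nrow(acc) < spec$n_accept)) {
    m <- matrix(exp(stats::runif(5L * batch, log(spec$range[1]),
                                 log(spec$range[2]))), ncol = 5)
    drawn <- drawn + batch
    r <- two_state_map(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5])
    ok <- r$delta > 0 &
      r$rho >= lo["rho"] & r$rho <= hi["rho"] &
      r$sigma_u >= lo["sigma_u"] & r$sigma_u <= hi["sigma_u"] &
      r$sigma_b >= lo["sigma_b"] & r$sigma_b <= hi["sigma_b"]
    if (any(ok)) {
      keep <- cbind(m[ok, , drop = FALSE], rho = r$rho[ok],
                    sigma_u = r$sigma_u[ok], sigma_b = r$sigma_b[ok])
      acc <- rbind(acc, keep)
    }
  }
  if (is.null(acc) || nrow(acc) == 0)
    stop(sprintf(paste0("no parameter sets accepted after %d draws; ",
                        "raise 'max_draws' or widen the ranges"), drawn),
         call. = FALSE)
  if (nrow(acc) > spec$n_accept)
    acc <- acc[seq_len(spec$n_accept), , drop = FALSE]
  sl <- signed_log_sens(acc[, 1:5, drop = FALSE])
  sens <- abs(sl)
  pair_of <- function(ix) paste(mech_names[ix], collapse = ",")
  most <- least <- vector("list", 4L)
  names(most) <- names(least) <- tele_names
  for (i in 1:4) {
    ords <- apply(sens[, i, , drop = TRUE], 1, order, decreasing = TRUE)
    mp <- apply(ords[1:2, , drop = FALSE], 2, pair_of)
    lp <- apply(ords[5:4, , drop = FALSE], 2, pair_of)
    most[[i]] <- sort(table(mp) / length(mp), decreasing = TRUE)
    least[[i]] <- sort(table(lp) / length(lp), decreasing = TRUE)
  }
  structure(list(accepted = as.data.frame(acc), most = most,
                 least = least, n_draws = drawn,
                 acceptance_rate = nrow(acc) / drawn, spec = spec,
                 seed = as.integer(seed)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "<parameter screen: %d accepted / %g draws (rate %.3g)>\n",
    nrow(x$accepted), x$n_draws, x$acceptance_rate))
  for (nm in names(x$most)) {
    cat(sprintf("%-8s most sensitive pair: %s (%.0f%%); least: %s (%.0f%%)\n",
                nm, names(x$most[[nm]])[1], 100 * x$most[[nm]][1],
                names(x$least[[nm]])[1], 100 * x$least[[nm]][1]))
  }
  invisible(x)
}
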