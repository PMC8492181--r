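# Waiting-time machinery: exact rational Laplace transforms of the
# distribution of the time between two consecutive transcript production
# events, built by a first-passage construction on the marked gene-state
# chain. Polynomials are stored as coefficient vectors in ascending powers
# of the Laplace variable s.

poly_trim <- function(p) {
  scale <- max(abs(p), .Machine$double.xmin)
  keep <- which(abs(p) > 1e-12 * scale)
  if (!length(keep)) return(0)
  p[seq_len(max(keep))]
}

poly_add <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p)))
  q <- c(q, rep(0, n - length(q)))
  p + q
}

poly_mul <- function(p, q) {
  if (length(p) == 1L) return(p * q)
  if (length(q) == 1L) return(q * p)
  out <- rep(0, length(p) + length(q) - 1L)
  for (i in seq_along(p)) out[i:(i + length(q) - 1L)] <-
      out[i:(i + length(q) - 1L)] + p[i] * q
  out
}

poly_eval <- function(p, s) {
  # Horner, works for complex s; vectorized over s
  out <- rep(p[length(p)], length(s))
  if (length(p) > 1L)
    for (k in (length(p) - 1L):1L) out <- out * s + p[k]
  out
}

poly_deriv <- function(p) {
  if (length(p) == 1L) return(0)
  p[-1L] * seq_len(length(p) - 1L)
}

# determinant of a matrix of polynomials (list-matrix), by cofactor
# expansion along the first column; fine for the <= 3-state chains used here
poly_det <- function(M) {
  n <- nrow(M)
  if (n == 1L) return(M[[1, 1]])
  acc <- 0
  for (i in seq_len(n)) {
    entry <- M[[i, 1]]
    if (length(entry) == 1L && entry[1] == 0) next
    minor <- M[-i, -1, drop = FALSE]
    term <- poly_mul(entry, poly_det(minor))
    if (i %% 2L == 0L) term <- -term
    acc <- poly_add(acc, term)
  }
  acc
}

#' Waiting-time Laplace transform of a model
#'
#' Computes the exact Laplace transform `f~(s)` of the distribution of the
#' time between two consecutive transcript production events, as a
#' rational function of `s`. For each gene state `i` the first-passage
#' transform to the next production-marked firing satisfies
#' `(s + r_i) f_i(s) = sum_j D1[i,j] + sum_{j != i} D0[i,j] f_j(s)`
#' (with `r_i` the total exit rate of state `i`); the linear system is
#' solved exactly by polynomial Cramer elimination, and the returned
#' transform is taken from the state entered immediately after a
#' production event (`U*` for the mechanistic model, `G` for the
#' two-state and refractory models; in general the post-production
#' distribution is proportional to `pi D1`).
#'
#' @param x a `gene_chain` or `gene_params` object.
#' @return An object of class `rational_lt` with fields `num` and `den`
#'   (polynomial coefficients, ascending powers of `s`, normalized so that
#'   `f~(0) = 1`) and `model`.
#' @examples
#' lt <- waiting_lt(telegraph_params(0.09, 0.012, 0.029, d = 0.0016))
#' lt_eval(lt, 0)   # 1: proper density
#' @export
waiting_lt <- function(x) {
  ch <- as_chain(x)
  n <- length(ch$states)
  mvec <- rowSums(ch$D1)
  if (all(mvec == 0))
    stop("chain has no production-marked transition", call. = FALSE)
  exit <- rowSums(ch$D0) - diag(ch$D0) + mvec
  # A(s) f = m with A_ii = s + r_i, A_ij = -D0[i,j]
  A <- vector("list", n * n)
  dim(A) <- c(n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    A[[i, j]] <- if (i == j) c(exit[i], 1) else -ch$D0[i, j]
  den <- poly_trim(poly_det(A))
  flux <- sum(ch$stationary * mvec)
  alpha <- as.numeric(ch$stationary %*% ch$D1) / flux  # post-production state
  num <- 0
  for (j in which(alpha > 0)) {
    Aj <- A
    for (i in seq_len(n)) Aj[[i, j]] <- mvec[i]
    num <- poly_add(num, alpha[j] * poly_det(Aj))
  }
  num <- poly_trim(num)
  # normalize so den(0) = 1 (then num(0) = 1 since f~(0) = 1 exactly)
  num <- unname(num / den[1])
  den <- unname(den / den[1])
  structure(list(num = num, den = den, model = ch$model,
                 alpha = alpha, D0 = ch$D0, mvec = mvec),
            class = "rational_lt")
}

#' Evaluate a rational Laplace transform
#'
#' @param lt a `rational_lt` object.
#' @param s Laplace variable values (may be complex).
#' @return `f~(s)`.
#' @export
lt_eval <- function(lt, s) poly_eval(lt$num, s) / poly_eval(lt$den, s)

#' Moments and randomness parameter of a waiting-time distribution
#'
#' Raw moments `<t^i> = (-1)^i d^i f~/ds^i (0)` are obtained exactly by
#' power-series division of the rational transform at `s = 0` (no finite
#' differencing). The randomness parameter is the squared coefficient of
#' variation `R = (<t^2> - <t>^2) / <t>^2`.
#'
#' @param lt a `rational_lt` object.
#' @param order highest moment order, between 1 and 4.
#' @return A list of class `waiting_moments` with `moments` (raw moments
#'   up to `order`), `m1`, `m2`, `m3` (when available) and `R`.
#' @export
waiting_moments <- function(lt, order = 3) {
  if (!is.numeric(order) || order < 1 || order > 4)
    stop("'order' must be between 1 and 4", call. = FALSE)
  order <- as.integer(order)
  nc <- order + 1L
  num <- c(lt$num, rep(0, max(0, nc - length(lt$num))))
  den <- c(lt$den, rep(0, max(0, nc - length(lt$den))))
  co <- numeric(nc)  # Taylor coefficients of f~ about s = 0
  for (k in seq_len(nc)) {
    acc <- num[k]
    if (k > 1L) for (j in 2:k) acc <- acc - den[j] * co[k - j + 1L]
    co[k] <- acc / den[1]
  }
  mom <- (-1)^(1:order) * factorial(1:order) * co[-1L]
  names(mom) <- paste0("m", 1:order)
  out <- list(moments = mom, m1 = mom[[1]],
              m2 = if (order >= 2) mom[[2]] else NULL,
              m3 = if (order >= 3) mom[[3]] else NULL,
              R = if (order >= 2) (mom[[2]] - mom[[1]]^2) / mom[[1]]^2 else NULL)
  class(out) <- "waiting_moments"
  out
}

#' @export
print.waiting_moments <- function(x, ...) {
  cat("<waiting-time moments>\n")
  print(x$moments)
  if (!is.null(x$R)) cat(sprintf("randomness parameter R = %.6g\n", x$R))
  invisible(x)
}

#' Randomness parameter of the telegraph / delay telegraph models
#'
#' Closed form `R = 1 + 2 rho sigma_u / (sigma_b + sigma_u)^2`. The value
#' is the same for the telegraph and delay-telegraph variants because the
#' waiting-time calculation is insensitive to the transcript removal mode.
#'
#' @param p a `two_state_params` object (or a list with `rho`, `sigma_u`,
#'   `sigma_b`).
#' @return Dimensionless randomness parameter (always >= 1).
#' @export
randomness_telegraph <- function(p) {
  1 + 2 * p$rho * p$sigma_u / (p$sigma_b + p$sigma_u)^2
}

#' Randomness parameter of the mechanistic model
#'
#' Closed form
#' `R = 1 + 2 b c (a'(b'+c-a) - a^2) / (a'(b'+c) + a(b+b'+c))^2`.
#' Unlike the two-state models, `R` can fall below 1 (down to 1/2, the
#' two-step floor set by the minimal `U* -> U** -> U*` production cycle).
#'
#' @param p a `mechanistic_params` object (or compatible list).
#' @return Dimensionless randomness parameter.
#' @export
randomness_mechanistic <- function(p) {
  with(p, 1 + 2 * b * c * (a_rev * (b_rev + c - a) - a^2) /
         (a_rev * (b_rev + c) + a * (b + b_rev + c))^2)
}

#' Randomness parameter of the refractory model
#'
#' Closed form
#' `R = 1 + 2 rho sigma_u (sigma_b sigma_u* + sigma_u*^2 + sigma_b^2) /
#' ((sigma_b + sigma_u) sigma_u* + sigma_b sigma_u)^2`, always > 1; in the
#' limit `sigma_u* -> Inf` it reduces to the telegraph value.
#'
#' @param p a `refractory_params` object (or compatible list).
#' @return Dimensionless randomness parameter.
#' @export
randomness_refractory <- function(p) {
  with(p, 1 + 2 * rho * sigma_u *
         (sigma_b * sigma_u_star + sigma_u_star^2 + sigma_b^2) /
         ((sigma_b + sigma_u) * sigma_u_star + sigma_b * sigma_u)^2)
}

#' Randomness parameter of any model
#'
#' Dispatches to the closed forms above; for arbitrary chains it falls
#' back to the first-passage pipeline ([waiting_lt()] +
#' [waiting_moments()]).
#'
#' @param x a `gene_params` or `gene_chain` object.
#' @return Dimensionless randomness parameter.
#' @export
randomness <- function(x) {
  if (inherits(x, "two_state_params")) return(randomness_telegraph(x))
  if (inherits(x, "mechanistic_params")) return(randomness_mechanistic(x))
  if (inherits(x, "refractory_params")) return(randomness_refractory(x))
  waiting_moments(waiting_lt(x), order = 2)$R
}

#' Waiting-time probability density
#'
#' Inverts the rational Laplace transform by partial fractions over the
#' (at most cubic) denominator roots, giving a sum of (possibly
#' complex-conjugate) exponentials with real value. When denominator roots
#' are nearly degenerate (relative separation below `root_tol`) the
#' density falls back to the equivalent phase-type form
#' `f(t) = alpha exp(D0 t) m`, evaluated with a matrix exponential; the
#' route taken is recorded in the `"method"` attribute.
#'
#' @param lt a `rational_lt` object.
#' @param t non-negative times (s).
#' @param root_tol relative root-separation threshold below which the
#'   matrix-exponential fallback is used.
#' @param method `"auto"`, `"partial-fractions"` or `"phase-type"`.
#' @return Density values (s^-1), with attribute `"method"`.
#' @export
waiting_density <- function(lt, t, root_tol = 1e-9,
                            method = c("auto", "partial-fractions",
                                       "phase-type")) {
  method <- match.arg(method)
  if (any(t < 0)) stop("negative times are not allowed", call. = FALSE)
  use_pf <- method != "phase-type"
  roots <- NULL
  if (use_pf) {
    roots <- polyroot(lt$den)
    if (method == "auto" && length(roots) > 1L) {
      sep <- min(abs(outer(roots, roots, "-")[lower.tri(matrix(0,
        length(roots), length(roots)))]))
      if (sep < root_tol * max(abs(roots))) use_pf <- FALSE
    }
  }
  if (use_pf) {
    dden <- poly_deriv(lt$den)
    res <- poly_eval(lt$num, roots) / poly_eval(dden, roots)
    out <- vapply(t, function(ti) Re(sum(res * exp(roots * ti))), 0)
    attr(out, "method") <- "partial-fractions"
  } else {
    out <- vapply(t, function(ti) {
      E <- as.matrix(Matrix::expm(Matrix::Matrix(lt$D0 * ti)))
      as.numeric(lt$alpha %*% E %*% lt$mvec)
    }, 0)
    attr(out, "method") <- "phase-type"
  }
  out
}

#' Density value at the origin
#'
#' `f(0+) = lim_{s -> Inf} s f~(s)`: the ratio of leading coefficients if
#' the numerator degree is exactly one below the denominator degree, and 0
#' otherwise. Two-state and refractory models have `f(0+) = rho > 0`; the
#' mechanistic model has `f(0+) = 0` because production resets the gene
#' state, which is the structural signature that discriminates the model
#' classes.
#'
#' @param lt a `rational_lt` object.
#' @return `f(0+)` (s^-1).
#' @export
density_at_zero <- function(lt) {
  if (length(lt$num) == length(lt$den) - 1L)
    lt$num[length(lt$num)] / lt$den[length(lt$den)]
  else 0
}

#' @export
print.rational_lt <- function(x, ...) {
  cat(sprintf("<waiting-time Laplace transform: %s>\n", x$model))
  cat("numerator coefficients:  ", signif(x$num, 6), "\n")
  cat("denominator coefficients:", signif(x$den, 6), "\n")
  cat(sprintf("f(0+) = %.6g 1/s\n", density_at_zero(x)))
  invisible(x)
}

#' Plot a waiting-time density
#'
#' @param x a `rational_lt` object.
#' @param t_max upper end of the time grid (s); defaults to eight mean
#'   waiting times.
#' @param n grid size.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rational_lt <- function(x, t_max = NULL, n = 400, ...) {
  if (is.null(t_max)) t_max <- 8 * waiting_moments(x, 1)$m1
  tg <- seq(0, t_max, length.out = n)
  graphics::plot(tg, waiting_density(x, tg), type = "l",
                 xlab = "waiting time (s)", ylab = "density (1/s)", ...)
  invisible(x)
}
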