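#' Build the marked gene-state Markov chain of a model
#'
#' Every model is encoded as a Markovian arrival process on its gene
#' states: an unmarked rate matrix `D0` (gene-state transitions that do
#' not emit a transcript; its diagonal carries minus the total exit rate)
#' and a marked rate matrix `D1` (transitions that emit exactly one
#' transcript). The full generator is `Q = D0 + D1`. For the mechanistic
#' model the marked transition is pause release `U** -> U*` at rate `c`;
#' for the two-state and refractory models it is the self-transition of
#' the on state at rate `rho`.
#'
#' @param p a `gene_params` object.
#' @return An object of class `gene_chain`: a list with elements
#'   `states`, `D0`, `D1`, `Q` and `stationary` (the stationary
#'   probability vector of `Q`).
#' @examples
#' ch <- build_chain(telegraph_params(1, 1, 1, d = 1))
#' ch$stationary           # (1/2, 1/2) by symmetry
#' stationary_flux(ch)     # rho * P(on) = 1/2
#' @export
build_chain <- function(p) {
  stopifnot(inherits(p, "gene_params"))
  if (inherits(p, "mechanistic_params")) {
    states <- c("U", "U*", "U**")
    D0 <- matrix(0, 3, 3, dimnames = list(states, states))
    D1 <- D0
    D0["U", "U*"] <- p$a
    D0["U*", "U"] <- p$a_rev
    D0["U*", "U**"] <- p$b
    D0["U**", "U*"] <- p$b_rev
    D1["U**", "U*"] <- p$c
  } else if (inherits(p, "two_state_params")) {
    states <- c("G", "G*")
    D0 <- matrix(0, 2, 2, dimnames = list(states, states))
    D1 <- D0
    D0["G", "G*"] <- p$sigma_u
    D0["G*", "G"] <- p$sigma_b
    D1["G", "G"] <- p$rho
  } else if (inherits(p, "refractory_params")) {
    states <- c("G", "G*", "G**")
    D0 <- matrix(0, 3, 3, dimnames = list(states, states))
    D1 <- D0
    D0["G", "G*"] <- p$sigma_u
    D0["G*", "G**"] <- p$sigma_u_star
    D0["G**", "G"] <- p$sigma_b
    D1["G", "G"] <- p$rho
  } else stop("unknown model class", call. = FALSE)
  new_chain(states, D0, D1, model = model_name(p))
}

#' Construct a custom marked gene-state chain
#'
#' Mostly useful for limiting cases that the model constructors exclude
#' (e.g. a one-state constitutive chain, or a chain with zero production).
#' Diagonal entries of `D0` are ignored and recomputed as minus the total
#' exit rate.
#'
#' @param states character vector of state labels.
#' @param D0 square matrix of unmarked transition rates (s^-1).
#' @param D1 square matrix of production-marked transition rates (s^-1).
#' @return A `gene_chain` object.
#' @examples
#' # constitutive production at rate 2/s
#' gene_chain("G", matrix(0, 1, 1), matrix(2, 1, 1))
#' @export
gene_chain <- function(states, D0, D1) {
  stopifnot(length(states) == nrow(D0), nrow(D0) == ncol(D0),
            all(dim(D0) == dim(D1)), all(D1 >= 0))
  m0 <- D0; diag(m0) <- 0
  stopifnot(all(m0 >= 0))
  dimnames(D0) <- dimnames(D1) <- list(states, states)
  new_chain(states, D0, D1)
}

new_chain <- function(states, D0, D1, model = "custom") {
  # D0 diagonal carries minus the total exit rate (marked + unmarked)
  diag(D0) <- 0
  diag(D0) <- -(rowSums(D0) + rowSums(D1))
  Q <- D0 + D1
  structure(list(states = states, D0 = D0, D1 = D1, Q = Q,
                 stationary = stationary_dist(Q), model = model),
             class = "gene_chain")
}

#' Stationary distribution of a generator matrix
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by replacing one balance equation with
#' the normalization row (deterministic LAPACK pivoting, reproducible).
#'
#' @param Q square generator matrix (rows sum to zero).
#' @return Stationary probability vector.
#' @export
stationary_dist <- function(Q) {
  n <- nrow(Q)
  if (!reachable_all(Q))
    stop("gene-state chain is reducible; stationary distribution not unique",
         call. = FALSE)
  A <- t(Q)
  A[n, ] <- 1
  pi <- solve(A, c(rep(0, n - 1L), 1))
  names(pi) <- rownames(Q)
  pi
}

# strong connectivity of the support graph via boolean reachability
reachable_all <- function(Q) {
  n <- nrow(Q)
  adj <- (Q > 0)
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) reach <- (reach %*% adj) > 0 | reach
  all(reach)
}

#' Stationary transcript-production flux of a chain
#'
#' The stationary rate at which production-marked transitions fire,
#' `sum_i pi_i * sum_j D1[i, j]` (s^-1). For the mechanistic model this is
#' the production rate gamma = a*b*c / (a'(b'+c) + a(b'+b+c)); for the
#' telegraph models it is `rho * sigma_b / (sigma_b + sigma_u)`.
#'
#' @param x a `gene_chain` or a `gene_params` object.
#' @return Production rate (s^-1).
#' @export
stationary_flux <- function(x) {
  ch <- as_chain(x)
  sum(ch$stationary * rowSums(ch$D1))
}

as_chain <- function(x) {
  if (inherits(x, "gene_chain")) x
  else if (inherits(x, "gene_params")) build_chain(x)
  else stop("expected a 'gene_chain' or 'gene_params' object", call. = FALSE)
}

#' @export
print.gene_chain <- function(x, ...) {
  cat(sprintf("<gene-state chain: %s; %d states>\n", x$model,
              length(x$states)))
  cat("stationary:", paste(sprintf("%s=%.4g", x$states, x$stationary),
                           collapse = ", "), "\n")
  cat(sprintf("production flux: %.6g 1/s\n", stationary_flux(x)))
  invisible(x)
}
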