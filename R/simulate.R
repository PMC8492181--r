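#' Simulate molecule numbers with the delay SSA
#'
#' Draws independent steady-state samples of active Pol II (`n_active`)
#' and mature mRNA (`n_mature`) counts, one per trajectory. Markovian
#' gene-state events are simulated by the direct SSA; each production
#' event schedules a completion at `t + tau` which is executed exactly
#' when it precedes the next stochastic firing (removal of an active
#' Pol II, plus conversion to mature mRNA in the mechanistic model).
#' Mature mRNA decays as a first-order channel.
#'
#' Each trajectory starts from the stationary gene-state distribution
#' with zero molecules and runs to `horizon`; since the gene marginal is
#' stationary from the outset, active Pol II is exactly stationary once
#' `horizon >= tau`, and the mature-mRNA transient decays as
#' `exp(-d * horizon)`. The default horizon,
#' `max(20 / min(rate), 5 tau, 5 / d)`, makes both negligible.
#'
#' @param p a `gene_params` object, or a `gene_chain` together with
#'   explicit `tau` / `d` / `completion_to_M` downstream settings (for
#'   limiting cases the validated constructors exclude, e.g. zero
#'   production).
#' @param n_samples number of independent trajectories.
#' @param seed integer seed (required: the simulation is stochastic).
#' @param horizon recording time (s); default as described above.
#' @param tau,d,completion_to_M downstream dynamics when `p` is a raw
#'   `gene_chain`: removal delay, decay rate, and whether a completed
#'   delay converts the transcript to mature mRNA (as in the mechanistic
#'   model) rather than removing it.
#' @return A `data.frame` with columns `sample_id`, `n_active`,
#'   `n_mature`, and attributes `horizon` and `seed`.
#' @examples
#' p <- mechanistic_params(0.112, 0.032, 0.16, 0.016, 0.24,
#'                         d = 0.016, tau = 100)
#' s <- simulate_counts(p, n_samples = 200, seed = 1)
#' colMeans(s[, c("n_active", "n_mature")])
#' @export
simulate_counts <- function(p, n_samples, seed, horizon = NULL,
                            tau = NULL, d = NULL, completion_to_M = NULL) {
  stopifnot(n_samples >= 1)
  if (inherits(p, "gene_chain")) {
    ch <- p
    tau <- if (is.null(tau)) 0 else tau
    d <- if (is.null(d)) 0 else d
    completion_to_M <- isTRUE(completion_to_M)
    track_M <- d > 0 || completion_to_M
  } else {
    stopifnot(inherits(p, "gene_params"))
    ch <- build_chain(p)
    tau <- if (is.null(p$tau)) 0 else p$tau
    d <- if (is.null(p$d)) 0 else p$d
    track_M <- inherits(p, "mechanistic_params") ||
      inherits(p, "telegraph_params") ||
      (inherits(p, "refractory_params") && !is.null(p$d))
    completion_to_M <- inherits(p, "mechanistic_params")
  }
  if (is.null(horizon)) {
    rates <- c(ch$D0[ch$D0 > 0], rowSums(ch$D1)[rowSums(ch$D1) > 0])
    horizon <- max(20 / min(rates), 5 * tau, if (d > 0) 5 / d else 0)
  }
  set.seed(as.integer(seed))
  m <- cpp_dssa_counts(ch$D0, ch$D1, d, tau, horizon,
                       as.integer(n_samples), ch$stationary,
                       completion_to_M, track_M)
  out <- data.frame(sample_id = seq_len(n_samples),
                    n_active = m[, 1], n_mature = m[, 2])
  attr(out, "horizon") <- horizon
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Simulate transcript production-event times
#'
#' Runs one long trajectory of the gene-state chain (downstream dynamics
#' do not affect production times) and records the times of consecutive
#' production-marked firings.
#'
#' @param p a `gene_params` object.
#' @param n_events number of production events to record.
#' @param seed integer seed.
#' @return Strictly increasing numeric vector of event times (s).
#' @export
simulate_events <- function(p, n_events, seed) {
  stopifnot(inherits(p, "gene_params"), n_events >= 1)
  ch <- build_chain(p)
  set.seed(as.integer(seed))
  cpp_dssa_events(ch$D0, ch$D1, ch$stationary, as.integer(n_events))
}

#' Inter-production waiting times from recorded event times
#'
#' Consecutive differences of production-event times, after discarding a
#' burn-in prefix of events so the gene-state marginal at the retained
#' events is close to its post-production stationary value.
#'
#' @param times strictly increasing production-event times (s).
#' @param burn_in number of leading events to discard.
#' @return Numeric vector of waiting times (s); empty if fewer than two
#'   events remain.
#' @examples
#' waiting_intervals(c(1.0, 2.5, 4.0))  # 1.5, 1.5
#' @export
waiting_intervals <- function(times, burn_in = 0) {
  if (burn_in > 0) times <- times[-seq_len(min(burn_in, length(times)))]
  if (length(times) < 2L) return(numeric(0))
  diff(times)
}
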