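#' Parameter set for the mechanistic transcription model
#'
#' The mechanistic model describes a gene cycling through three states:
#' `U` (activator binding site blocked), `U*` (activator bound, promoter
#' accessible) and `U**` (Pol II recruited and proximally paused). Pause
#' release emits one actively transcribing Pol II and resets the gene to
#' `U*`; each active Pol II matures into an mRNA after a deterministic
#' elongation time `tau`, and mature mRNA decays by first-order kinetics.
#'
#' @param a activation rate `U -> U*` (s^-1).
#' @param a_rev deactivation rate `U* -> U` (s^-1).
#' @param b Pol II binding and pause-entry rate `U* -> U**` (s^-1).
#' @param b_rev premature termination rate `U** -> U*` (s^-1).
#' @param c pause-release (production) rate `U** -> U* + A` (s^-1).
#' @param d mature mRNA decay rate (s^-1), or `NULL` if mature-mRNA
#'   statistics are never requested.
#' @param tau elongation delay (s); must be >= 0.
#'
#' @return An object of class `mechanistic_params`.
#' @examples
#' p <- mechanistic_params(a = 0.112, a_rev = 0.032, b = 0.16,
#'                         b_rev = 0.016, c = 0.24, d = 0.016, tau = 100)
#' p
#' @export
mechanistic_params <- function(a, a_rev, b, b_rev, c, d = NULL, tau = 0) {
  check_rate(a, "a"); check_rate(a_rev, "a_rev"); check_rate(b, "b")
  check_rate(b_rev, "b_rev"); check_rate(c, "c")
  if (!is.null(d)) check_rate(d, "d")
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop("'tau' must be a single non-negative number (seconds)", call. = FALSE)
  structure(list(a = a, a_rev = a_rev, b = b, b_rev = b_rev, c = c,
                 d = d, tau = tau),
            class = c("mechanistic_params", "gene_params"))
}

#' Parameter set for the telegraph model
#'
#' Two-state gene switching between an active state `G` (producing mature
#' mRNA at rate `rho`) and an inactive state `G*`; mRNA decays at rate `d`.
#' `sigma_u = 0` is accepted as the constitutive (Poisson) limit, which
#' arises from the reduction map on the feasibility boundary.
#'
#' @param rho transcription rate in the on state (s^-1).
#' @param sigma_u off-switching rate `G -> G*` (s^-1); may be 0.
#' @param sigma_b on-switching rate `G* -> G` (s^-1).
#' @param d mature mRNA decay rate (s^-1).
#' @return An object of class `telegraph_params`. The burst size
#'   `beta = rho / sigma_u` is available through [burst_size()].
#' @examples
#' telegraph_params(rho = 0.09, sigma_u = 0.012, sigma_b = 0.029, d = 0.0016)
#' @export
telegraph_params <- function(rho, sigma_u, sigma_b, d) {
  check_rate(rho, "rho"); check_rate(sigma_u, "sigma_u", zero_ok = TRUE)
  # sigma_b is unidentifiable (and maps to 0) in the constitutive limit
  check_rate(sigma_b, "sigma_b", zero_ok = sigma_u == 0)
  check_rate(d, "d")
  structure(list(rho = rho, sigma_u = sigma_u, sigma_b = sigma_b,
                 d = d, tau = NULL),
            class = c("telegraph_params", "two_state_params", "gene_params"))
}

#' Parameter set for the delay telegraph model
#'
#' As [telegraph_params()], but each transcript (an actively transcribing
#' Pol II) is removed a fixed time `tau` after its production instead of
#' decaying by a first-order reaction.
#'
#' @inheritParams telegraph_params
#' @param tau removal delay (s); must be > 0.
#' @return An object of class `delay_telegraph_params`.
#' @export
delay_telegraph_params <- function(rho, sigma_u, sigma_b, tau) {
  check_rate(rho, "rho"); check_rate(sigma_u, "sigma_u", zero_ok = TRUE)
  check_rate(sigma_b, "sigma_b", zero_ok = sigma_u == 0)
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0)
    stop("'tau' must be a single positive number (seconds)", call. = FALSE)
  structure(list(rho = rho, sigma_u = sigma_u, sigma_b = sigma_b,
                 d = NULL, tau = tau),
            class = c("delay_telegraph_params", "two_state_params",
                      "gene_params"))
}

#' Parameter set for the refractory model
#'
#' Three-state cyclic gene model `G -> G* -> G** -> G` with two sequential
#' off states (rates `sigma_u`, `sigma_u_star`, `sigma_b`) and production
#' at rate `rho` from the on state `G`. The downstream transcript dynamics
#' follow either first-order decay (`d`) or delayed removal (`tau`).
#'
#' @inheritParams telegraph_params
#' @param sigma_u_star rate `G* -> G**` (s^-1).
#' @param d decay rate (s^-1) for the mature-mRNA variant, or `NULL`.
#' @param tau removal delay (s) for the active-Pol II variant, or `NULL`.
#' @return An object of class `refractory_params`.
#' @export
refractory_params <- function(rho, sigma_u, sigma_u_star, sigma_b,
                              d = NULL, tau = NULL) {
  check_rate(rho, "rho"); check_rate(sigma_u, "sigma_u")
  check_rate(sigma_u_star, "sigma_u_star"); check_rate(sigma_b, "sigma_b")
  if (!is.null(d)) check_rate(d, "d")
  if (!is.null(tau) && (!is.numeric(tau) || tau <= 0))
    stop("'tau' must be positive", call. = FALSE)
  structure(list(rho = rho, sigma_u = sigma_u, sigma_u_star = sigma_u_star,
                 sigma_b = sigma_b, d = d, tau = tau),
            class = c("refractory_params", "gene_params"))
}

check_rate <- function(x, name, zero_ok = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (x > 0 || (zero_ok && x == 0))
  if (!ok)
    stop(sprintf("rate '%s' must be a single %s finite number (s^-1)",
                 name, if (zero_ok) "non-negative" else "strictly positive"),
         call. = FALSE)
  invisible(TRUE)
}

#' Burst size of a two-state model
#'
#' The mean number of transcripts produced per on-period,
#' `beta = rho / sigma_u`.
#'
#' @param p a [telegraph_params()] or [delay_telegraph_params()] object.
#' @return Dimensionless burst size (may be `Inf` when `sigma_u = 0`).
#' @export
burst_size <- function(p) {
  stopifnot(inherits(p, "two_state_params"))
  p$rho / p$sigma_u
}

model_name <- function(p) {
  if (inherits(p, "mechanistic_params")) return("mechanistic")
  if (inherits(p, "telegraph_params")) return("telegraph")
  if (inherits(p, "delay_telegraph_params")) return("delay_telegraph")
  if (inherits(p, "refractory_params")) return("refractory")
  stop("unknown model parameter class", call. = FALSE)
}

#' @export
print.gene_params <- function(x, ...) {
  cat(sprintf("<%s model parameters>\n", model_name(x)))
  flds <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flds)) {
    unit <- if (nm == "tau") "s" else "1/s"
    cat(sprintf("  %-12s %g %s\n", nm, flds[[nm]], unit))
  }
  invisible(x)
}

#' Convert a parameter object to/from a flat named list
#'
#' The flat mapping carries a `model` field
#' (`"mechanistic"`, `"telegraph"`, `"delay_telegraph"` or `"refractory"`)
#' plus the rates, and round-trips through YAML or JSON files.
#'
#' @param p a `gene_params` object.
#' @return `params_to_list`: a named list; `params_from_list`: a validated
#'   `gene_params` object.
#' @export
params_to_list <- function(p) {
  stopifnot(inherits(p, "gene_params"))
  out <- c(list(model = model_name(p)), p[!vapply(p, is.null, logical(1))])
  out
}

#' @rdname params_to_list
#' @param x a named list with a `model` entry, as produced by
#'   [params_to_list()] or parsed from a config file.
#' @export
params_from_list <- function(x) {
  if (is.null(x$model))
    stop("parameter mapping lacks a 'model' field", call. = FALSE)
  model <- match.arg(x$model, c("mechanistic", "telegraph",
                                "delay_telegraph", "refractory"))
  known <- switch(model,
    mechanistic = c("a", "a_rev", "b", "b_rev", "c", "d", "tau"),
    telegraph = c("rho", "sigma_u", "sigma_b", "d"),
    delay_telegraph = c("rho", "sigma_u", "sigma_b", "tau"),
    refractory = c("rho", "sigma_u", "sigma_u_star", "sigma_b", "d", "tau"))
  extra <- setdiff(setdiff(names(x), "model"), known)
  if (length(extra))
    stop("unknown parameter field(s) for model '", model, "': ",
         paste(extra, collapse = ", "), call. = FALSE)
  args <- x[intersect(known, names(x))]
  do.call(switch(model,
                 mechanistic = mechanistic_params,
                 telegraph = telegraph_params,
                 delay_telegraph = delay_telegraph_params,
                 refractory = refractory_params),
          args)
}

#' Read or write model parameters from a config file
#'
#' Files ending in `.yml`/`.yaml` are parsed as YAML, anything else as
#' JSON. The mapping is flat, e.g.
#' `{model: mechanistic, a: 0.112, ..., tau: 100}`.
#'
#' @param path file path.
#' @return `read_params`: a `gene_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  params_from_list(lapply(x, function(v) if (is.character(v) || is.null(v)) v else as.numeric(v)))
}

#' @rdname read_params
#' @param p a `gene_params` object to serialize.
#' @export
write_params <- function(p, path) {
  x <- params_to_list(p)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
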