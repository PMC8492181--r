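#' Built-in parameter sets
#'
#' All mechanistic parameter sets used in the reference analyses, keyed
#' by source: `table2_set1` ... `table2_set6` (the mean/variance
#' benchmark rows), `fig2_a` / `fig2_b` / `fig2_c` (the number- and
#' waiting-time-distribution comparisons; `d = 0.0016` 1/s,
#' `tau = 273.62` s), `fig3_b1` / `fig3_b10` / `fig3_b100` (waiting-time
#' peak position as Pol II binding `b` sweeps 1, 10, 100 1/s), `fig5_base`
#' (the Fano-factor-versus-`tau` family; `a` is varied by the caller) and
#' `fig6_d` / `fig6_e` / `fig6_f` (worst-case sets near the `R = 1`
#' boundary). Rates in 1/s, delays in s.
#'
#' @param name optional fixture name; when `NULL` the full named list is
#'   returned.
#' @return A `mechanistic_params` object, or a named list of them.
#' @examples
#' builtin_fixtures("table2_set2")
#' names(builtin_fixtures())
#' @export
builtin_fixtures <- function(name = NULL) {
  fx <- list(
    table2_set1 = mechanistic_params(0.016, 0.08, 0.16, 0.016, 0.24,
                                     d = 0.002, tau = 273.62),
    table2_set2 = mechanistic_params(0.112, 0.032, 0.16, 0.016, 0.24,
                                     d = 0.016, tau = 100),
    table2_set3 = mechanistic_params(0.144, 0.032, 0.96, 0.16, 0.24,
                                     d = 0.002, tau = 273.62),
    table2_set4 = mechanistic_params(0.144, 0.032, 1.12, 0.8, 0.24,
                                     d = 0.1, tau = 80),
    table2_set5 = mechanistic_params(0.032, 0.032, 0.16, 0.016, 0.32,
                                     d = 0.002, tau = 273.62),
    table2_set6 = mechanistic_params(0.016, 0.032, 0.16, 0.016, 0.4,
                                     d = 0.005, tau = 50),
    fig2_a = mechanistic_params(0.001, 0.001, 0.16, 0.016, 0.24,
                                d = 0.0016, tau = 273.62),
    fig2_b = mechanistic_params(0.144, 0.032, 0.016, 0.56, 0.24,
                                d = 0.0016, tau = 273.62),
    fig2_c = mechanistic_params(0.032, 0.032, 0.16, 0.016, 0.32,
                                d = 0.0016, tau = 273.62),
    fig3_b1 = mechanistic_params(0.1, 0.1, 1, 4, 10,
                                 d = 0.0016, tau = 273.62),
    fig3_b10 = mechanistic_params(0.1, 0.1, 10, 4, 10,
                                  d = 0.0016, tau = 273.62),
    fig3_b100 = mechanistic_params(0.1, 0.1, 100, 4, 10,
                                   d = 0.0016, tau = 273.62),
    fig5_base = mechanistic_params(0.032, 0.032, 0.16, 0.0125, 0.4,
                                   d = 0.0016, tau = 273.62),
    fig6_d = mechanistic_params(0.0336, 0.006, 0.16, 0.016, 0.24,
                                d = 0.0016, tau = 13.65),
    fig6_e = mechanistic_params(0.072, 0.0288, 0.16, 0.016, 0.24,
                                d = 0.0016, tau = 8.76),
    fig6_f = mechanistic_params(0.08, 0.005, 2, 0.0001, 1.36,
                                d = 0.0016, tau = 3))
  if (is.null(name)) return(fx)
  if (!name %in% names(fx))
    stop("unknown fixture '", name, "'; see names(builtin_fixtures())",
         call. = FALSE)
  fx[[name]]
}

#' Screen specifications for measured mammalian genes
#'
#' Ready-made [screen_spec()] objects with published two-state parameter
#' estimates and experimental errors: Oct4
#' (`rho = 3.2e-2 +/- 1.0e-2`, `sigma_u = 3e-3 +/- 2e-3`,
#' `sigma_b = 1.5e-4 +/- 0.5e-4` 1/s; sampling range `[1e-4, 10]` 1/s)
#' and Nanog (`rho = 1.3e-2 +/- 0.3e-2`, `sigma_u = 1.2e-4 +/- 0.2e-4`,
#' `sigma_b = 3.2e-5 +/- 0.3e-5` 1/s; range `[1e-5, 1e-1]` 1/s);
#' acceptance within 2 experimental errors.
#'
#' @param n_accept target number of accepted parameter sets.
#' @param max_draws cap on total draws.
#' @return A `screen_spec`.
#' @export
oct4_screen <- function(n_accept = 1000, max_draws = 2e7) {
  screen_spec(targets = c(rho = 3.2e-2, sigma_u = 3e-3, sigma_b = 1.5e-4),
              errors = c(rho = 1.0e-2, sigma_u = 2e-3, sigma_b = 0.5e-4),
              k = 2, range = c(1e-4, 10), n_accept = n_accept,
              max_draws = max_draws)
}

#' @rdname oct4_screen
#' @export
nanog_screen <- function(n_accept = 1000, max_draws = 2e7) {
  screen_spec(targets = c(rho = 1.3e-2, sigma_u = 1.2e-4, sigma_b = 3.2e-5),
              errors = c(rho = 0.3e-2, sigma_u = 0.2e-4, sigma_b = 0.3e-5),
              k = 2, range = c(1e-5, 1e-1), n_accept = n_accept,
              max_draws = max_draws)
}
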