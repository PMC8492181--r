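test_that("Delta and the reducibility conditions are computed correctly", {
  expect_equal(reduction_delta(builtin_fixtures("fig2_a")), 0.254,
               tolerance = 1e-12)
  expect_equal(reduction_delta(builtin_fixtures("fig2_b")), 0.008,
               tolerance = 1e-12)
  # a -> 0: Delta -> b' + c
  expect_equal(reduction_delta(mechanistic_params(1e-9, 1, 1, 0.3, 0.7)),
               1, tolerance = 1e-6)
  for (nm in c("fig2_a", "fig2_b", "fig2_c")) {
    r <- is_reducible(builtin_fixtures(nm))
    expect_true(r$waiting); expect_true(r$mature_number)
  }
  r <- is_reducible(mechanistic_params(0.144, 0.032, 1, 0.05, 0.05,
                                       d = 0.01))
  expect_false(r$waiting); expect_false(r$mature_number)
})

test_that("Delta >= 0, R >= 1 and the two conditions chain correctly", {
  for (p in draw_mech(60, seed = 31, d = 0.02)) {
    red <- is_reducible(p)
    expect_identical(reduction_delta(p) >= 0, red$waiting)
    expect_identical(randomness_mechanistic(p) >= 1, red$waiting)
    if (!red$waiting) expect_false(red$mature_number)
  }
})

test_that("closed-form map reproduces the reference effective parameters", {
  ea <- effective_two_state(builtin_fixtures("fig2_a"))
  eb <- effective_two_state(builtin_fixtures("fig2_b"))
  ec <- effective_two_state(builtin_fixtures("fig2_c"))
  expect_equal(ea$rho, 0.092, tolerance = 5e-3)
  expect_equal(ea$sigma_b, 0.001, tolerance = 5e-3)
  expect_equal(eb$sigma_u, 3.8e-8, tolerance = 1e-2)
  expect_equal(eb$rho, 0.004, tolerance = 5e-2)
  expect_equal(ec$sigma_u, 0.012, tolerance = 2e-2)
  expect_equal(ec$sigma_b, 0.029, tolerance = 2e-2)
})

test_that("the map matches the first three waiting-time moments exactly", {
  for (p in draw_mech(30, seed = 32, d = 0.01, tau = 50)) {
    if (reduction_delta(p) <= 0) next
    e <- effective_two_state(p, "delay_telegraph")
    wm_m <- waiting_moments(waiting_lt(p), 3)$moments
    wm_t <- waiting_moments(waiting_lt(e), 3)$moments
    expect_equal(wm_t, wm_m, tolerance = 1e-9)
    # mean waiting times match, so production fluxes do too
    expect_equal(stationary_flux(e), stationary_flux(p), tolerance = 1e-9)
  }
})

test_that("map refuses the infeasible region and handles the boundary", {
  p_bad <- mechanistic_params(0.144, 0.032, 1, 0.05, 0.05, d = 0.01)
  expect_error(effective_two_state(p_bad), "Delta")
  p0 <- mechanistic_params(a = 0.2, a_rev = 0.1, b = 0.5, b_rev = 0.1,
                           c = 0.2 + 0.4 - 0.1, d = 0.01)
  expect_equal(reduction_delta(p0), 0, tolerance = 1e-15)
  e0 <- effective_two_state(p0)
  expect_equal(e0$sigma_u, 0)   # constitutive reduced model
})

test_that("map scales linearly under a global rescaling of the rates", {
  p <- builtin_fixtures("fig2_c")
  e1 <- effective_two_state(p)
  lam <- 3.7
  p2 <- mechanistic_params(lam * p$a, lam * p$a_rev, lam * p$b,
                           lam * p$b_rev, lam * p$c, d = p$d, tau = p$tau)
  e2 <- effective_two_state(p2)
  expect_equal(e2$rho, lam * e1$rho, tolerance = 1e-12)
  expect_equal(e2$sigma_u, lam * e1$sigma_u, tolerance = 1e-12)
  expect_equal(e2$sigma_b, lam * e1$sigma_b, tolerance = 1e-12)
})

test_that("fast-switching limit has the stated closed form and is reached", {
  p <- mechanistic_params(0.01, 0.02, 100, 50, 10, d = 0.01, tau = 10)
  f <- fast_switching_limit(p)
  expect_equal(f$sigma_b, 0.01)
  expect_equal(f$sigma_u, 0.0066667, tolerance = 1e-4)
  expect_equal(f$rho, 6.6667, tolerance = 1e-4)
  # b' -> 0: rho -> c, sigma_u -> 0
  f0 <- fast_switching_limit(mechanistic_params(0.01, 0.02, 100, 1e-9, 10,
                                                d = 0.01))
  expect_equal(f0$rho, 10, tolerance = 1e-9)
  expect_lt(f0$sigma_u, 1e-9)
  # with b' = gamma_c * b, the full map converges to the limit as b grows
  dev <- sapply(c(10, 100, 1000), function(b) {
    pp <- mechanistic_params(0.01, 0.02, b, 0.5 * b, 10, d = 0.01)
    e <- effective_two_state(pp); fl <- fast_switching_limit(pp)
    max(abs(c(e$rho / fl$rho, e$sigma_u / fl$sigma_u,
              e$sigma_b / fl$sigma_b) - 1))
  })
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 0.02)
})

test_that("number-moment matching recovers embedded two-state targets", {
  # a nearly fast-switching mechanistic model is essentially two-state;
  # the Newton solver must converge onto the closed-form map's solution
  p <- builtin_fixtures("fig2_c")
  mm <- match_number_moments(p, "active")
  expect_true(mm$converged)
  expect_lt(max(abs(mm$diagnostics$residuals)), 1e-8)
  # the matched model reproduces the mechanistic number moments
  got <- window_count_moments(mm$mapped, p$tau, 3)
  expect_equal(got, mm$diagnostics$target_moments, tolerance = 1e-7)
  mm2 <- match_number_moments(p, "mature")
  expect_true(mm2$converged)
  expect_lt(max(abs(mm2$diagnostics$residuals)), 1e-8)
})

test_that("number-moment matching flags the infeasible region", {
  p_bad <- mechanistic_params(0.144, 0.032, 1, 0.05, 0.05, d = 0.01,
                              tau = 50)
  expect_lt(randomness_mechanistic(p_bad), 1)
  mm <- match_number_moments(p_bad, "mature", max_iter = 60)
  expect_false(isTRUE(mm$converged) &&
                 all(c(mm$mapped$rho, mm$mapped$sigma_u,
                       mm$mapped$sigma_b) > 0) &&
                 max(abs(mm$diagnostics$residuals)) < 1e-8)
})

test_that("MLE fit recovers telegraph parameters from samples", {
  tp <- telegraph_params(0.05, 0.01, 0.005, d = 0.002)
  dist <- mature_distribution(tp)
  set.seed(9)
  x <- sample(dist$support, 10000, replace = TRUE, prob = dist$p)
  fit <- mle_two_state(x, "mature", d = 0.002, seed = 3, n_starts = 3)
  expect_true(fit$converged)
  expect_lt(abs(fit$mapped$rho / tp$rho - 1), 0.2)
  expect_lt(abs(fit$mapped$sigma_u / tp$sigma_u - 1), 0.2)
  expect_lt(abs(fit$mapped$sigma_b / tp$sigma_b - 1), 0.2)
  # reproducibility of the fit under a fixed seed
  fit2 <- mle_two_state(x, "mature", d = 0.002, seed = 3, n_starts = 3)
  expect_identical(fit$mapped, fit2$mapped)
  expect_error(mle_two_state(rep(0L, 200), "mature", d = 1), "degenerate")
  expect_error(mle_two_state(x[1:50], "mature", d = 1), "100 samples")
})

test_that("refractory four-moment matching hits its targets where feasible", {
  for (nm in c("fig2_a", "table2_set6")) {
    p <- builtin_fixtures(nm)
    r <- match_refractory(p)
    expect_true(r$converged)
    expect_lt(max(abs(r$diagnostics$residuals)), 1e-6)
    got <- waiting_moments(waiting_lt(r$mapped), 4)$moments
    expect_equal(got, r$diagnostics$target_moments, tolerance = 1e-6)
    expect_gt(randomness_refractory(r$mapped), 1)
  }
  # R < 1 region is refused outright
  expect_error(match_refractory(table2(2)), "Delta")
})

test_that("reduce_model wraps the three reduction routes", {
  p <- builtin_fixtures("fig2_c")
  r1 <- reduce_model(p, "closed-form", "active")
  expect_s3_class(r1$mapped, "delay_telegraph_params")
  expect_equal(r1$delta, 0.272, tolerance = 1e-12)
  r3 <- reduce_model(p, "mle", "mature", n_samples = 2000, seed = 6,
                     n_starts = 2, maxit = 200)
  expect_s3_class(r3$mapped, "telegraph_params")
  h <- hellinger(mature_distribution(r3$mapped), mature_distribution(p))
  expect_lt(h, 0.05)
})
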