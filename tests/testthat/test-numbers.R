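test_that("closed-form means reproduce the benchmark table", {
  expect_equal(mean_active(table2(1)), 6.195, tolerance = 1e-4)
  expect_equal(mean_active(table2(4)), 8.993, tolerance = 1e-4)
  expect_equal(mean_mature(table2(2)), 4.907, tolerance = 1e-4)
  expect_equal(mean_mature(table2(6)), 9.091, tolerance = 1e-4)
  p <- table2(2); p$tau <- 0
  expect_equal(mean_active(p), 0)
  expect_error(mean_mature(mechanistic_params(1, 1, 1, 1, 1)), "'d'")
})

test_that("two-state Fano factors obey their limits", {
  dt <- delay_telegraph_params(0.09, 0.012, 0.029, tau = 50)
  expect_equal(fano_active_delay_telegraph(dt, tau = 1e7),
               randomness_telegraph(dt), tolerance = 1e-5)
  expect_equal(fano_active_delay_telegraph(dt, tau = 0), 1)
  expect_equal(fano_active_delay_telegraph(dt, tau = 1e-9), 1,
               tolerance = 1e-6)
  expect_equal(fano_active_delay_telegraph(
    delay_telegraph_params(1, 0, 1, tau = 10), tau = 10), 1)
  tp <- telegraph_params(0.5, 0.1, 0.2, d = 0.01)
  expect_gt(fano_mature_telegraph(tp), 1)
  expect_equal(fano_mature_telegraph(tp, d = 1e9), 1, tolerance = 1e-6)
  expect_equal(fano_mature_telegraph(telegraph_params(1, 0, 1, d = 1)), 1)
})

test_that("mechanistic mature Fano factor and its threshold hold", {
  expect_equal(fano_mature_mechanistic(table2(2)) * mean_mature(table2(2)),
               4.384, tolerance = 1e-3)
  expect_equal(fano_mature_mechanistic(table2(6)) * mean_mature(table2(6)),
               21.629, tolerance = 1e-4)
  # FF >= 1 iff b' + c >= (a/a')(a + a' + d), across random draws
  for (p in draw_mech(40, seed = 21, d = 0.05)) {
    cond <- with(p, b_rev + c >= a / a_rev * (a + a_rev + d))
    expect_identical(fano_mature_mechanistic(p) >= 1, cond)
  }
})

test_that("window-count engine is exact on Poisson and degenerate cases", {
  # constitutive one-state chain: counts in a window are Poisson(rho tau)
  ch <- gene_chain("G", matrix(0, 1, 1), matrix(0.4, 1, 1))
  wd <- window_count_distribution(ch, window = 10)
  expect_equal(wd$p[1:15], dpois(0:14, 4), tolerance = 1e-9)
  # zero production: point mass at zero
  ch0 <- gene_chain(c("G", "G*"),
                    matrix(c(0, 1, 1, 0), 2, 2), matrix(0, 2, 2))
  wd0 <- window_count_distribution(ch0, window = 5)
  expect_equal(wd0$p[1], 1)
  expect_error(window_count_distribution(as_tel <- build_chain(
    telegraph_params(5, 0.01, 5, d = 1)), window = 100, n_max = 20),
    "deficit")
})

test_that("window-count mean equals flux times window", {
  for (p in draw_mech(8, seed = 22, tau = 3)) {
    mu <- stationary_flux(p) * 3
    wd <- window_count_distribution(p, n_max = max(30, ceiling(mu * 6)))
    expect_equal(number_moments(wd)$mean, mu, tolerance = 1e-8)
    mom <- window_count_moments(p, 3)
    expect_equal(mom[1], mu, tolerance = 1e-9)
    # moment ODE and full distribution agree
    expect_equal(mom[2], count_moments(wd, 2)[2], tolerance = 1e-7)
  }
})

test_that("window engine reproduces the benchmark active Pol II variance", {
  wd <- window_count_distribution(table2(2))
  nm <- number_moments(wd)
  expect_equal(nm$mean, 7.85, tolerance = 1e-3)
  expect_equal(nm$variance, 6.194, tolerance = 1e-3)
  expect_lt(wd$deficit, 1e-9)
})

test_that("active Pol II Fano factor interpolates 1 -> dip -> R", {
  p <- builtin_fixtures("fig5_base")   # R > 1 family
  R <- randomness_mechanistic(p)
  expect_gt(R, 1)
  expect_equal(fano_active_mechanistic(p, tau = 1e-6), 1, tolerance = 1e-4)
  rates <- c(p$a, p$a_rev, p$b, p$b_rev, p$c)
  expect_equal(fano_active_mechanistic(p, tau = 100 / min(rates)), R,
               tolerance = 1e-2)
  ffs <- vapply(c(1, 5, 20), function(tt)
    fano_active_mechanistic(p, tau = tt), 0)
  expect_lt(min(ffs), 1)   # sub-Poissonian dip at intermediate tau
  # R < 1 parameter set: Fano below 1 for all tau probed
  p2 <- table2(2)
  expect_lt(randomness_mechanistic(p2), 1)
  for (tt in c(1, 10, 100, 1000))
    expect_lt(fano_active_mechanistic(p2, tau = tt), 1)
})

test_that("telegraph CME matches flux balance, Fano and Peccoud-Ycart", {
  tp <- telegraph_params(0.05, 0.01, 0.005, d = 0.002)
  dist <- mature_distribution(tp)
  nm <- number_moments(dist)
  expect_equal(nm$mean,
               tp$rho * tp$sigma_b / (tp$d * (tp$sigma_b + tp$sigma_u)),
               tolerance = 1e-10)
  expect_equal(nm$fano, fano_mature_telegraph(tp), tolerance = 1e-8)
  pmf <- oracle_telegraph_pmf(tp$rho, tp$sigma_u, tp$sigma_b, tp$d,
                              max(dist$support))
  expect_equal(dist$p, pmf, tolerance = 1e-8)
  # sigma_u -> 0: Poisson(rho / d)
  d0 <- mature_distribution(telegraph_params(0.05, 1e-12, 0.005,
                                             d = 0.002), n_max = 90)
  expect_equal(d0$p[1:40], dpois(0:39, 25), tolerance = 1e-6)
})

test_that("mechanistic mature CME agrees with the analytic moments", {
  for (p in list(table2(2), table2(6))) {
    dist <- mature_distribution(p)
    nm <- number_moments(dist)
    expect_equal(nm$mean, mean_mature(p), tolerance = 1e-9)
    expect_equal(nm$fano, fano_mature_mechanistic(p), tolerance = 1e-8)
  }
})

test_that("mature CME agrees with delay-SSA sampling", {
  p <- table2(2)
  n <- 30000
  s <- simulate_counts(p, n, seed = 23)
  h <- hellinger(mature_distribution(p), empirical_distribution(s$n_mature))
  expect_lt(h, 0.03)
  vm <- fano_mature_mechanistic(p) * mean_mature(p)
  expect_lt(abs(var(s$n_mature) - vm), 3 * vm * sqrt(2 / n) * 1.5)
})

test_that("hellinger distance behaves like a metric on pmfs", {
  p <- count_distribution(c(0.2, 0.5, 0.3))
  q <- count_distribution(c(0.5, 0.5))
  expect_equal(hellinger(p, p), 0)
  expect_equal(hellinger(count_distribution(c(1, 0)),
                         count_distribution(c(0, 1))), 1)
  expect_equal(hellinger(count_distribution(c(1, 0)), q),
               sqrt(1 - sqrt(0.5)), tolerance = 1e-12)
  expect_equal(hellinger(p, q), hellinger(q, p))
  bad <- count_distribution(c(0.5, 0.3))  # deficit 0.2
  expect_error(hellinger(p, bad), "deficit")
})
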