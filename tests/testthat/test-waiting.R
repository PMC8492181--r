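test_that("telegraph first-passage transform equals the hand-derived form", {
  set.seed(3)
  for (k in 1:10) {
    rho <- exp(runif(1, -4, 1)); su <- exp(runif(1, -4, 1))
    sb <- exp(runif(1, -4, 1))
    lt <- waiting_lt(telegraph_params(rho, su, sb, d = 1))
    s <- exp(runif(4, -3, 2))
    expect_equal(lt_eval(lt, s), oracle_lt_tele(rho, su, sb, s),
                 tolerance = 1e-12)
  }
})

test_that("transforms are proper densities with the right structure", {
  models <- list(table2(2), telegraph_params(0.09, 0.012, 0.029, d = 1),
                 refractory_params(0.1, 0.02, 0.05, 0.01))
  for (p in models) {
    lt <- waiting_lt(p)
    expect_equal(lt_eval(lt, 0), 1, tolerance = 1e-12)       # normalization
    expect_lt(length(lt$num), length(lt$den))                # proper rational
  }
  # f(0+) discriminates the model classes: zero iff production resets state
  expect_equal(density_at_zero(waiting_lt(table2(2))), 0)
  expect_equal(density_at_zero(waiting_lt(telegraph_params(0.09, 0.012,
                                                           0.029, d = 1))),
               0.09, tolerance = 1e-12)
  expect_equal(density_at_zero(waiting_lt(refractory_params(0.1, 0.02,
                                                            0.05, 0.01))),
               0.1, tolerance = 1e-12)
})

test_that("moments follow from exact series expansion of the transform", {
  p <- table2(2)
  wm <- waiting_moments(waiting_lt(p), 3)
  expect_equal(wm$m1, 1 / oracle_gamma(p), tolerance = 1e-12)  # 12.738 s
  expect_gte(wm$m2, wm$m1^2)
  expect_error(waiting_moments(waiting_lt(p), 5), "between 1 and 4")
})

test_that("pipeline randomness equals the closed forms on random draws", {
  set.seed(4)
  for (k in 1:15) {
    rho <- exp(runif(1, -4, 1)); su <- exp(runif(1, -4, 1))
    sb <- exp(runif(1, -4, 1)); ss <- exp(runif(1, -4, 1))
    tp <- telegraph_params(rho, su, sb, d = 1)
    expect_equal(waiting_moments(waiting_lt(tp), 2)$R,
                 randomness_telegraph(tp), tolerance = 1e-10)
    rp <- refractory_params(rho, su, ss, sb)
    expect_equal(waiting_moments(waiting_lt(rp), 2)$R,
                 randomness_refractory(rp), tolerance = 1e-10)
    expect_gt(randomness_refractory(rp), 1)
  }
  for (p in draw_mech(15, seed = 5))
    expect_equal(waiting_moments(waiting_lt(p), 2)$R,
                 randomness_mechanistic(p), tolerance = 1e-10)
})

test_that("randomness closed forms agree with the reference values", {
  # mapped Fig 2(c) two-state parameters and their mechanistic source
  expect_equal(oracle_R_tele(0.086981, 0.011837, 0.028632), 2.2574,
               tolerance = 1e-4)
  pc <- builtin_fixtures("fig2_c")
  expect_equal(randomness_mechanistic(pc), 2.2574, tolerance = 1e-4)
  e <- effective_two_state(pc)
  expect_equal(randomness_telegraph(e), randomness_mechanistic(pc),
               tolerance = 1e-12)
  # sigma_u -> 0 gives a Poisson production process
  expect_equal(randomness_telegraph(telegraph_params(1, 0, 1, d = 1)), 1)
  # Delta = 0 boundary: b' + c = a + a^2/a', randomness exactly 1
  p0 <- mechanistic_params(a = 0.2, a_rev = 0.1, b = 0.5, b_rev = 0.1,
                           c = 0.2 + 0.2^2 / 0.1 - 0.1)
  expect_equal(reduction_delta(p0), 0, tolerance = 1e-15)
  expect_equal(randomness_mechanistic(p0), 1, tolerance = 1e-12)
})

test_that("refractory model collapses to telegraph as sigma_u* grows", {
  tp <- telegraph_params(0.09, 0.012, 0.029, d = 1)
  rp <- refractory_params(0.09, 0.012, 1e7, 0.029)
  expect_equal(randomness_refractory(rp), randomness_telegraph(tp),
               tolerance = 1e-5)
})

test_that("densities integrate to one and have the documented shape", {
  pc <- builtin_fixtures("fig2_c")
  lt <- waiting_lt(pc)
  quad <- integrate(function(t) waiting_density(lt, t), 0, Inf,
                    rel.tol = 1e-12, subdivisions = 500L)
  expect_lt(abs(quad$value - 1), 1e-8)
  tg <- seq(0, 3000, length.out = 6001)
  f <- waiting_density(lt, tg)
  expect_true(all(f > -1e-12))
  # mechanistic density rises to an interior maximum
  expect_gt(which.max(f), 1)
  expect_gt(max(f), f[1] + 1e-6)
  # two-state density is maximal at the origin and monotone decreasing
  lt2 <- waiting_lt(effective_two_state(pc))
  tg2 <- seq(0, 500, 0.5)
  f2 <- waiting_density(lt2, tg2)
  expect_equal(which.max(f2), 1L)
  expect_true(all(diff(f2) <= 1e-12))
  expect_error(waiting_density(lt, -1), "negative")
})

test_that("partial-fraction and phase-type inversions agree", {
  lt <- waiting_lt(table2(4))
  tg <- c(0, 0.5, 2, 10, 40)
  f_pf <- waiting_density(lt, tg, method = "partial-fractions")
  f_mx <- waiting_density(lt, tg, method = "phase-type")
  expect_equal(as.numeric(f_pf), as.numeric(f_mx), tolerance = 1e-9)
  expect_identical(attr(f_mx, "method"), "phase-type")
})
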