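test_that("delay SSA is bit-reproducible under a fixed seed", {
  p <- table2(2)
  s1 <- simulate_counts(p, 300, seed = 7)
  s2 <- simulate_counts(p, 300, seed = 7)
  expect_identical(s1, s2)
  e1 <- simulate_events(p, 500, seed = 7)
  e2 <- simulate_events(p, 500, seed = 7)
  expect_identical(e1, e2)
  expect_true(all(diff(e1) > 0))
})

test_that("zero production leaves all molecule numbers at zero", {
  ch <- gene_chain(c("U", "U*", "U**"),
                   matrix(c(0, 0.112, 0,
                            0.032, 0, 0.16,
                            0, 0.016, 0), 3, 3, byrow = TRUE),
                   matrix(0, 3, 3))
  s <- simulate_counts(ch, 200, seed = 1, horizon = 500, tau = 100,
                       d = 0.016, completion_to_M = TRUE)
  expect_true(all(s$n_active == 0))
  expect_true(all(s$n_mature == 0))
})

test_that("constitutive limit of the telegraph model is Poisson", {
  tp <- telegraph_params(1, 1e-12, 1, d = 0.1)
  s <- simulate_counts(tp, 20000, seed = 5, horizon = 200)
  m <- mean(s$n_mature)
  ff <- var(s$n_mature) / m
  expect_equal(m, 10, tolerance = 0.05)
  # Fano within 3 SE of 1 (SE of the Fano estimate ~ sqrt(2/n))
  expect_lt(abs(ff - 1), 3 * sqrt(2 / 20000))
})

test_that("steady-state moments reproduce the mechanistic theory", {
  p <- table2(2)
  n <- 30000
  s <- simulate_counts(p, n, seed = 11)
  expect_lt(abs(mean(s$n_active) - 7.85), 3 * sqrt(6.194 / n))
  expect_lt(abs(mean(s$n_mature) - 4.907), 3 * sqrt(4.384 / n))
  expect_lt(abs(var(s$n_active) / 6.194 - 1), 3 * sqrt(2 / n) + 0.01)
})

test_that("delay telegraph occupancy satisfies Little's law", {
  dt <- delay_telegraph_params(0.09, 0.012, 0.029, tau = 100)
  n <- 20000
  s <- simulate_counts(dt, n, seed = 3)
  mu <- stationary_flux(dt) * 100
  R <- randomness_telegraph(dt)
  expect_lt(abs(mean(s$n_active) - mu), 3 * sqrt(mu * max(1, R) / n))
})

test_that("waiting intervals difference event times and match theory", {
  expect_equal(waiting_intervals(c(1.0, 2.5, 4.0)), c(1.5, 1.5))
  expect_identical(waiting_intervals(c(3.2)), numeric(0))
  expect_identical(waiting_intervals(c(1, 2), burn_in = 1), numeric(0))
  p <- table2(2)
  ev <- simulate_events(p, 20000, seed = 13)
  w <- waiting_intervals(ev, burn_in = 100)
  m1 <- 1 / oracle_gamma(p)                 # 12.74 s
  R <- oracle_R_mech(p)
  n <- length(w)
  # intervals are i.i.d. (production always restarts from U*), so plain
  # standard errors apply; CV^2 estimate SE from the delta method
  expect_lt(abs(mean(w) - m1), 3 * sqrt(R * m1^2 / n))
  cv2 <- var(w) / mean(w)^2
  expect_lt(abs(cv2 - R), 3 * R * sqrt(8 / n))
})

test_that("empirical waiting-time histograms converge to the density", {
  p <- builtin_fixtures("fig2_c")
  lt <- waiting_lt(p)
  tg <- seq(0, 4000, 0.25)
  Fgrid <- cumsum(waiting_density(lt, tg)) * 0.25   # numeric CDF
  ks <- sapply(c(500, 20000), function(n) {
    w <- waiting_intervals(simulate_events(p, n + 101, seed = 17),
                           burn_in = 100)[seq_len(n)]
    Fem <- ecdf(w)
    max(abs(Fem(tg) - pmin(Fgrid, 1)))
  })
  expect_lt(ks[2], ks[1])          # KS distance decreases with samples
  expect_lt(ks[2], 0.02)
})
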