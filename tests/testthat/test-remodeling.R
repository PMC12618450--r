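test_that("the piecewise rate law reproduces hand-computed rates", {
  p <- remodeling_params()
  # reference stimulus sits inside the dead band
  expect_equal(density_rate(0.004, p), 0)
  # inclusive boundaries: exactly (1 +/- delta) k gives zero rate
  expect_equal(density_rate(0.0044, p), 0)
  expect_equal(density_rate(0.0036, p), 0)
  # overload resorption: B x - D x^2 with x = S - (1+delta)k
  expect_equal(density_rate(0.05, p), 1 * 0.0456 - 60 * 0.0456^2)
  expect_equal(density_rate(0.05, p), -0.0791616)
  # disuse resorption: B (S - (1-delta)k)
  expect_equal(density_rate(0.001, p), -0.0026)
  # vectorised across branches
  expect_equal(density_rate(c(0.004, 0.05, 0.001), p),
               c(0, -0.0791616, -0.0026))
  # D = 0 recovers the linear law: apposition never turns negative
  lin <- remodeling_params(D = 0)
  s <- seq(0.005, 0.2, by = 0.005)
  expect_true(all(diff(density_rate(s, lin)) > 0))
  expect_true(all(density_rate(s, lin) > 0))
  # with the quadratic term the rate decreases beyond the peak
  expect_lt(density_rate(0.05, p), density_rate(0.0127333, p))
})

test_that("rate-curve landmarks follow the closed forms", {
  lm <- rate_curve_landmarks(remodeling_params())
  expect_equal(lm$S_peak, 0.0044 + 1 / 120)
  expect_equal(lm$rate_peak, 1 / 240)
  expect_equal(lm$S_zero, 0.0044 + 1 / 60)
  # doubling D halves the peak rate
  lm2 <- rate_curve_landmarks(remodeling_params(D = 120))
  expect_equal(lm2$rate_peak, lm$rate_peak / 2)
  # collapsed lazy zone
  lm0 <- rate_curve_landmarks(remodeling_params(delta = 0))
  expect_equal(lm0$S_zero, 0.004 + 1 / 60)
  expect_error(rate_curve_landmarks(remodeling_params(D = 0)), "D = 0")
})

test_that("the forward-Euler step integrates and clamps", {
  p <- remodeling_params()
  expect_equal(step_density(0.81, 0.01, p), 0.810037184)
  # the floor absorbs disuse resorption
  expect_equal(step_density(0.01, 0.001, p), 0.01)
  # near the cap a single apposition step stays below it, then clamps
  expect_equal(step_density(1.9999, 0.01, p),
               min(2.0, 1.9999 + 0.01 * 0.0037184))
  expect_equal(step_density(1.99999, 0.01, p), 2.0)
})

test_that("constant-stimulus iteration reaches the absorbing bounds", {
  # apposition at S = 0.01 caps the density at 2.0
  up <- remodel_fixed_stimulus(0.81, 0.01)
  expect_equal(up$rho, 2.0)
  # disuse at S = 0.001 and overload at S = 0.05 floor it at 0.01
  expect_equal(remodel_fixed_stimulus(1.0, 0.001)$rho, 0.01)
  expect_equal(remodel_fixed_stimulus(1.0, 0.05)$rho, 0.01)
  # lazy stimulus leaves the density untouched
  expect_equal(remodel_fixed_stimulus(0.81, 0.004)$steps, 0L)
  # step count matches the constant-rate trajectory
  expect_equal(up$steps, as.integer(ceiling((2 - 0.81) / (0.01 * 0.0037184))))
})

test_that("frozen-energy iteration converges to U/((1+delta)k)", {
  res <- remodel_fixed_energy(1.0, 0.008)
  expect_true(res$converged)
  expect_lt(abs(res$rho - 0.008 / 0.0044) / (0.008 / 0.0044), 0.01)
  expect_equal(res$rho, 1.81818, tolerance = 0.01)
  # final stimulus lands at the upper lazy-zone edge
  expect_lt(abs(res$S - 0.0044) / 0.0044, 0.005)
  # approaching from above settles at the lower edge
  res2 <- remodel_fixed_energy(1.9, 0.005)
  expect_equal(res2$S, 0.0036, tolerance = 0.005)
  expect_equal(res2$rho, 0.005 / 0.0036, tolerance = 0.01)
})

test_that("coarse and fine Euler trajectories agree", {
  # dt = 0.01 vs dt/100, compared at whole-time-unit checkpoints
  p1 <- remodeling_params(dt = 0.01)
  p2 <- remodeling_params(dt = 1e-4)
  t1 <- remodel_fixed_energy(1.0, 0.008, p1, record_every = 100,
                             max_steps = 3000)$trajectory
  t2 <- remodel_fixed_energy(1.0, 0.008, p2, record_every = 10000,
                             max_steps = 300000)$trajectory
  expect_equal(nrow(t1), 30)
  expect_true(all(abs(t1$rho - t2$rho) / t2$rho < 0.001))
})

test_that("final density is monotone in stimulus only below the overload crossing", {
  horizon <- function(S, p) {
    rho <- 1.0
    for (i in 1:2000) rho <- step_density(rho, S, p)
    rho
  }
  lin <- remodeling_params(D = 0)
  s_grid <- c(0.005, 0.008, 0.012, 0.03, 0.08)
  fin_lin <- sapply(s_grid, horizon, p = lin)
  expect_true(all(diff(fin_lin) >= 0))
  quad <- remodeling_params()
  fin_quad <- sapply(s_grid, horizon, p = quad)
  expect_false(all(diff(fin_quad) >= 0))   # breaks beyond S_zero
})

test_that("an unloaded coupled model is in global disuse and floors", {
  blk <- block_model(n = 3)
  p <- remodeling_params(max_steps = 400)
  hist <- run_remodeling(blk$mesh, blk$mat, 0, blk$bc, p)
  expect_true(hist$converged)
  expect_true(all(hist$mat$density <= p$rho_min + 1e-12))
})

test_that("a baseline stimulus holds unloaded bone in the lazy zone", {
  blk <- block_model(n = 3)
  p <- remodeling_params(s_baseline = 0.004, max_steps = 50)
  hist <- run_remodeling(blk$mesh, blk$mat, 0, blk$bc, p)
  expect_true(hist$converged)
  expect_equal(nrow(hist$summary), 1L)   # stationary immediately
  expect_equal(hist$mat$density, blk$mat$density)
})

test_that("coupled runs clamp densities and are deterministic", {
  m <- lame_disc_model(32, e0 = 0.02)
  m$mat$density[m$mat$remodels] <- 1.0
  m$mat$modulus[m$mat$remodels] <- density_to_modulus(1.0)
  p <- remodeling_params(max_steps = 30, s_baseline = 0.004)
  h1 <- run_remodeling(m$mesh, m$mat, m$eig0, m$bc, p)
  expect_true(all(h1$mat$density[h1$mat$remodels] >= 0.01 - 1e-12))
  expect_true(all(h1$mat$density[h1$mat$remodels] <= 2 + 1e-12))
  expect_true(all(h1$summary$max_density <= 2 + 1e-12))
  m2 <- lame_disc_model(32, e0 = 0.02)
  m2$mat$density[m2$mat$remodels] <- 1.0
  m2$mat$modulus[m2$mat$remodels] <- density_to_modulus(1.0)
  h2 <- run_remodeling(m2$mesh, m2$mat, m2$eig0, m2$bc, p)
  expect_identical(h1$mat$density, h2$mat$density)
  expect_identical(h1$summary, h2$summary)
})

test_that("element classification labels bounds and regimes", {
  m <- lame_disc_model(32, e0 = 0.02)
  m$mat$density[m$mat$remodels] <- 1.0
  m$mat$modulus[m$mat$remodels] <- density_to_modulus(1.0)
  p <- remodeling_params(max_steps = 120, s_baseline = 0.004)
  hist <- run_remodeling(m$mesh, m$mat, m$eig0, m$bc, p)
  cls <- classify_elements(hist, m$mesh, axis_center = m$center,
                           anchor_radius = 4)
  b <- hist$mat$remodels
  expect_true(all(!is.na(cls$regime[b])))
  expect_true(all(is.na(cls$regime[!b])))
  expect_setequal(unique(cls$zone), c("anchor", "interface", "far"))
  # capped elements really are at the cap, floored at the floor
  expect_true(all(hist$mat$density[which(cls$regime == "capped")] >=
                    2 - 1e-9))
  expect_true(all(hist$mat$density[which(cls$regime == "floored")] <=
                    0.01 + 1e-9))
})
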