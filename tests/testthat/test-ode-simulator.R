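test_that("integration reaches the analytic geometric steady state", {
  for (d in c(0, 0.02)) {
    par <- sim_params(p = 2, e = 3, d = d, L = 40)
    st <- pol_integrate(par, polymerase_field(numeric(40)), "no4sU", 1000)
    ss <- steady_state_occupancy(par)
    expect_lt(max(abs(st$o - ss) / ss), 1e-6)
    if (d == 0) expect_equal(st$o, rep(1 / 6, 40), tolerance = 1e-6)
    # geometric decline ratio (1+d)^-1 between consecutive windows
    expect_equal(st$o[-1] / st$o[-40], rep(1 / (1 + d), 39),
                 tolerance = 1e-6)
  }
})

test_that("flux is conserved at equilibrium without a defect", {
  par <- sim_params(p = 2, e = 3, d = 0, L = 30)
  st <- pol_integrate(par, polymerase_field(numeric(30)), "no4sU", 1000)
  expect_equal(1 / par$p, par$e * st$o[30], tolerance = 1e-6)
})

test_that("integration guards its inputs", {
  par <- sim_params(2, 3, 0, 10)
  st <- polymerase_field(numeric(10))
  expect_identical(pol_integrate(par, st, "no4sU", 0), st)
  expect_error(pol_integrate(par, st, "no4sU", -1), "duration")
  expect_error(pol_integrate(par, polymerase_field(numeric(5)),
                             "no4sU", 1), "length")
  bad <- st; bad$o[1] <- NaN
  expect_error(pol_integrate(par, bad, "no4sU", 1), "finite")
  expect_error(sim_params(p = 0, e = 3, d = 0, L = 10))
  expect_error(sim_params(p = 2, e = 3, d = -0.1, L = 10))
})

test_that("labeling from equilibrium matches the closed form and keeps o+b", {
  par <- sim_params(2, 3, 0.02, 40)
  eq <- pol_integrate(par, polymerase_field(numeric(40)), "no4sU", 1000)
  st <- pol_integrate(par, eq, "4sU", 15)
  # total occupancy is continuous across the mode switch and conserved
  expect_equal(st$o + st$b, eq$o + eq$b, tolerance = 1e-7)
  expect_equal(st$b, pulse_occupancy(par, 15), tolerance = 1e-6)
})

test_that("DRB labeling from an empty gene matches the Erlang closed form", {
  par <- sim_params(2, 3, 0, 80)
  st <- pol_integrate(par, polymerase_field(numeric(80)), "4sU", 20)
  expect_equal(st$b, drb_occupancy(par, 20), tolerance = 1e-8)
  expect_equal(max(abs(st$o)), 0)
})

test_that("simulated profiles have the defining shape properties", {
  par <- sim_params(2, 3, 0, 60)
  prof <- simulate_experiment(par, "pulse", label_min = 15)
  # 4sU profile is a suffix sum: non-increasing, window 1 = total mass
  expect_true(all(diff(prof$foursu) <= 1e-12))
  expect_equal(prof$foursu[1], sum(prof$b))
  expect_true(all(prof$chip >= 0))
  expect_error(simulate_experiment(par, "pulse", label_min = 0),
               "label_min")
})

test_that("the DRB front (half-maximum) advances by e*t", {
  # the exact solution's front is Erlang-smeared (sd ~ sqrt(e t w)); its
  # median - the half-maximum crossing - sits at the advection distance
  for (e in c(1.5, 3)) {
    par <- sim_params(2, e, 0, 80)
    prof <- simulate_experiment(par, "drb", label_min = 20)
    expect_lte(abs(profile_front(prof$chip, 0.5) - e * 20), 1)
  }
  # the 1e-6 tail extends far beyond e*t (numerical diffusion)
  prof <- simulate_experiment(sim_params(2, 3, 0, 80), "drb", 20)
  expect_gt(profile_front(prof$chip, 1e-6), 70)
})

test_that("log fold-change profiles compare channels element-wise", {
  pu <- sim_params(2, 3, 0, 50)
  prof <- simulate_experiment(pu, "pulse")
  expect_equal(lfc_profile(prof, prof, "chip"), rep(0, 50))
  # unprocessive vs unperturbed occupancy: constant per-window log2 ratio
  un <- simulate_experiment(sim_params(2, 3, 0.02, 50), "pulse")
  l <- lfc_profile(un, prof, "chip")
  expect_equal(diff(l), rep(-log2(1.02), 49), tolerance = 1e-6)
  short <- simulate_experiment(sim_params(2, 3, 0, 20), "pulse")
  expect_error(lfc_profile(prof, short, "chip"), "length")
})

test_that("fine-resolution DRB profiles agree with the coarse integrator", {
  # aggregating the exact sub-kb solution reproduces the per-kb closed
  # form's total labeled mass
  p <- 2; e <- 3; t <- 10; Lkb <- 40
  fine <- drb_foursu_kb(p, e, 0, Lkb, t, resolution_kb = 0.05)
  par1 <- sim_params(p, e, 0, Lkb)
  coarse <- rev(cumsum(rev(drb_occupancy(par1, t))))
  # same total signal and same front midpoint
  expect_equal(which.min(abs(fine - fine[1] / 2)),
               which.min(abs(coarse - coarse[1] / 2)), tolerance = 1)
  expect_gt(cor(fine, coarse), 0.99)
})
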