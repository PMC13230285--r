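test_that("exit hazards are proportional to lesion size with constant ratio", {
  p <- ref_params()
  expect_equal(hazard_dcis_symptom(0, 1, p), p$eta_D * p$l0)
  expect_equal(hazard_transition(0, 1, p), p$eta_T * p$l0)
  for (t in c(0.5, 3, 12)) for (r in c(0.3, 0.5, 2))
    expect_equal(hazard_dcis_symptom(t, r, p) / hazard_transition(t, r, p),
                 exp(-2), tolerance = 1e-12)
})

test_that("cumulative hazards match quadrature of the hazards", {
  p <- ref_params()
  for (r in c(0.4, 1.3)) {
    for (t in c(1, 6)) {
      expect_equal(cumhaz_dcis_symptom(t, r, p),
                   integrate(function(u) hazard_dcis_symptom(u, r, p),
                             0, t, rel.tol = 1e-10)$value, tolerance = 1e-8)
      expect_equal(cumhaz_invasive_symptom(t, r, p),
                   integrate(function(u) hazard_invasive_symptom(u, r, p),
                             0, t, rel.tol = 1e-10)$value, tolerance = 1e-8)
    }
    # closed form eta_I v0 r (e^(t/r) - 1), incl. one doubling time
    expect_equal(cumhaz_invasive_symptom(r * log(2), r, p),
                 p$eta_I * p$v0 * r, tolerance = 1e-12)
  }
  t <- seq(0, 50, length.out = 200)
  s <- surv_dcis_symptom(t, 0.7, p) * surv_transition(t, 0.7, p)
  expect_true(all(diff(s) < 0))
  expect_equal(s[1], 1)
  expect_lt(tail(s, 1), 1e-6)
})

test_that("inversion sampler reproduces the competing-risk structure", {
  p <- ref_params()
  set.seed(42)
  s <- sample_sojourns(2e5, NULL, p)
  a <- prob_symptomatic_before_invasive(p)
  se <- sqrt(a * (1 - a) / 2e5)
  expect_lt(abs(mean(s$t_D < s$t_T) - a), 3 * se)
  # symmetric hazards give a half/half split
  psym <- nh_params(eta_D = exp(-5), eta_T = exp(-5))
  s2 <- sample_sojourns(1e5, NULL, psym)
  expect_lt(abs(mean(s2$t_D < s2$t_T) - 0.5), 3 * sqrt(0.25 / 1e5))
  # (V_I - v0) | r is exponential with rate eta_I r
  set.seed(7)
  s3 <- sample_sojourns(5e4, r = 0.67, params = p)
  vi <- s3$v_I[!is.na(s3$v_I)]
  ks <- suppressWarnings(ks.test(vi - p$v0, "pexp", rate = p$eta_I * 0.67))
  expect_gt(ks$p.value, 0.01)
})

test_that("latent-failure and combined-hazard samplers agree in distribution", {
  p <- ref_params()
  set.seed(1)
  s1 <- sample_sojourns(4e4, NULL, p, method = "latent")
  set.seed(2)
  s2 <- sample_sojourns(4e4, NULL, p, method = "combined")
  te1 <- pmin(s1$t_D, s1$t_T)
  te2 <- pmin(s2$t_D, s2$t_T)
  expect_gt(suppressWarnings(ks.test(te1, te2))$p.value, 0.01)
  expect_lt(abs(mean(s1$t_D < s1$t_T) - mean(s2$t_D < s2$t_T)),
            3 * sqrt(2 * 0.105 / 4e4))
  # exit type independent of exit time under proportional hazards
  expect_gt(suppressWarnings(
    ks.test(te1[s1$t_D < s1$t_T], te1[s1$t_D > s1$t_T]))$p.value, 0.01)
})

test_that("Laplace transform of the shifted Gamma prior is correct", {
  p <- ref_params()
  expect_equal(laplace_gamma_shifted(0, 2.36, 3), 1)
  s <- c(0.1, 1, 10)
  expect_true(all(diff(laplace_gamma_shifted(s, 2.36, 3)) < 0))
  # tau1 = 0 reduces to the Laplace transform of Exponential(tau2)
  expect_equal(laplace_gamma_shifted(2, 0, 3), 3 / (3 + 2))
  # (tau1/tau2) F(s) = E[R exp(-s R)] by quadrature over the prior
  for (ss in s) {
    mc <- integrate(function(r) r * exp(-ss * r) * dgamma(r, 2.36, rate = 3),
                    0, Inf, rel.tol = 1e-10)$value
    expect_equal(2.36 / 3 * laplace_gamma_shifted(ss, 2.36, 3), mc,
                 tolerance = 1e-8)
  }
  expect_error(laplace_gamma_shifted(-1, 2.36, 3), "non-negative")
})

test_that("closed-form symptomatic size densities normalise and match their mixtures", {
  p <- ref_params()
  expect_equal(integrate(function(v) density_symptomatic_volume(v, p),
                         p$v0, Inf, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  expect_equal(integrate(function(l) density_symptomatic_lesion(l, p),
                         p$l0, Inf, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  expect_equal(integrate(function(l)
    density_symptomatic_lesion(l, p, competing = TRUE),
    p$l0, Inf, rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  # pointwise: f_VI(v) = integral of eta_I r exp(-eta_I r (v - v0)) f_R(r) dr
  for (v in c(0.1, 1, 10, 100)) {
    mix <- integrate(function(r)
      p$eta_I * r * exp(-p$eta_I * r * (v - p$v0)) *
        dgamma(r, p$tau1, rate = p$tau2), 0, Inf, rel.tol = 1e-10)$value
    expect_equal(density_symptomatic_volume(v, p), mix, tolerance = 1e-7)
  }
  # cdfs differentiate back to the densities
  v <- c(0.5, 5, 50); h <- 1e-5 * v
  expect_equal((cdf_symptomatic_volume(v + h, p) -
                  cdf_symptomatic_volume(v - h, p)) / (2 * h),
               density_symptomatic_volume(v, p), tolerance = 1e-6)
  # vanishing transition hazard: competing density converges to the plain one
  p0 <- nh_params(eta_T = 1e-12)
  l <- c(0.1, 1, 10)
  expect_equal(density_symptomatic_lesion(l, p0, competing = TRUE),
               density_symptomatic_lesion(l, p0, competing = FALSE),
               tolerance = 1e-6)
})

test_that("de-novo piecewise hazard has the stated early mass and limits", {
  p <- ref_params()
  dn0 <- de_novo_config(0)
  expect_equal(de_novo_transition_hazard(0.005, 1, dn0, p), 0)
  expect_equal(de_novo_transition_hazard(0.01 + 3, 1, dn0, p),
               hazard_transition(3, 1, p), tolerance = 1e-12)
  dn <- de_novo_config(0.1)
  tt <- seq(0, 0.0099, length.out = 50)
  expect_true(all(de_novo_transition_hazard(tt, 1, dn, p) >= 0))
  set.seed(3)
  draws <- sample_transition_de_novo(2e5, 0.67, dn, p)
  expect_lt(abs(mean(draws < dn$window) - 0.1), 3 * sqrt(0.09 / 2e5))
  # beyond the window the sampler follows the shifted standard law
  set.seed(4)
  std <- sample_transition_de_novo(2e5, 0.67, de_novo_config(0), p)
  expect_gt(suppressWarnings(ks.test(
    draws[draws >= dn$window], std[std >= dn$window]))$p.value, 0.01)
})
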