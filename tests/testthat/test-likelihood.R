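test_that("logistic sensitivities have the right structure", {
  p <- ref_params()
  p00 <- nh_params(b1 = 1e-300, b2 = 1e-300)   # effectively size-free
  expect_equal(sensitivity_dcis(c(0, 5, 50), p00), rep(plogis(-5), 3),
               tolerance = 1e-12)
  l <- seq(0, 60, length.out = 30)
  expect_true(all(diff(sensitivity_dcis(l, p)) > 0))
  expect_true(all(diff(sensitivity_invasive(5, l, p)) > 0))
  expect_true(all(sensitivity_invasive(l, 10, p) > sensitivity_dcis(l, p)))
  # reference sensitivity values: logistic(-5 + 0.56 d) at l = 0
  expect_equal(sensitivity_invasive(0, 0, p), plogis(-5))
  expect_equal(sensitivity_invasive(0, 10, p), plogis(-5 + 5.6))
})

test_that("screening-history probability matches a forward Bernoulli simulation", {
  p <- ref_params()
  expect_equal(history_probability(0.7, 8, numeric(), "dcis",
                                   "all_negative", params = p), 1)
  # a screen before onset contributes nothing
  r <- 0.7; l_det <- 8
  g <- time_from_dcis_size(l_det, r, p)
  expect_equal(history_probability(r, l_det, g + 3, "dcis",
                                   "all_negative", params = p), 1)
  # forward oracle, DCIS case: screens at fixed ages before detection
  offs <- c(1, 3, 5)
  set.seed(60)
  n <- 2e5
  ages <- g - offs
  sens <- sensitivity_dcis(dcis_size(pmax(ages, 0), r, p), p)
  sens[ages < 0] <- 0
  p_all_neg <- mean(rowSums(matrix(runif(n * 3), n, 3) <
                              matrix(sens, n, 3, byrow = TRUE)) == 0)
  form <- history_probability(r, l_det, offs, "dcis", "all_negative",
                              params = p)
  expect_lt(abs(p_all_neg - form), 3 * sqrt(form * (1 - form) / n))
  # invasive case with back-projection across the transition
  v <- volume_from_diameter(25)
  t_t <- 4
  age_det <- t_t + time_from_invasive_volume(v, r, p)
  offs2 <- c(0.5, 2, 6)
  probs <- vapply(offs2, function(u) {
    age <- age_det - u
    if (age < 0) return(0)
    l <- dcis_size(age, r, p)
    if (age >= t_t)
      sensitivity_invasive(l, diameter_from_volume(
        invasive_volume(age - t_t, r, p)), p)
    else sensitivity_dcis(l, p)
  }, numeric(1))
  form2 <- history_probability(r, 25, offs2, "invasive", "all_negative",
                               t_t = t_t, params = p)
  expect_equal(form2, prod(1 - probs), tolerance = 1e-12)
  set.seed(61)
  sim2 <- mean(rowSums(matrix(runif(n * 3), n, 3) <
                         matrix(probs, n, 3, byrow = TRUE)) == 0)
  expect_lt(abs(sim2 - form2), 3 * sqrt(form2 * (1 - form2) / n))
  expect_error(history_probability(r, 25, c(3, 1), "invasive",
                                   t_t = 1, params = p), "increasing")
})

test_that("empty-history contributions reduce to the closed-form class densities", {
  p <- ref_params()
  q <- quad_settings(32, 32, 48)
  a <- prob_symptomatic_before_invasive(p)
  v <- c(0.1, 1, 10, 100, 1000)
  d <- diameter_from_volume(v)
  expect_equal(contribution_symptomatic_invasive(d, numeric(), p, q),
               (1 - a) * density_symptomatic_volume(v, p),
               tolerance = 1e-10)
  l <- c(0.05, 0.5, 5, 50)
  expect_equal(contribution_symptomatic_dcis(l, numeric(), p, q),
               a * density_symptomatic_lesion(l, p, competing = TRUE),
               tolerance = 1e-10)
  # unit sensitivity: screen-detected DCIS density is the stationary one
  p1 <- nh_params(b0 = 50, b1 = 0, b2 = 0)
  ratio <- contribution_screen_dcis(l, 0, p1, q) /
    stationary_dcis_size_density(l, p1)
  expect_equal(ratio / ratio[1], rep(1, length(l)), tolerance = 1e-6)
  # and the screen-detected invasive density is the length-biased one
  ratio2 <- contribution_screen_invasive(d, 0, p1, q) /
    stationary_invasive_size_density(v, p1, scale = "volume")
  expect_equal(ratio2 / ratio2[1], rep(1, length(v)), tolerance = 1e-6)
})

test_that("the two arrangements of the screen-detected invasive density agree", {
  p <- ref_params()
  q <- quad_settings(64, 64, 64)
  v <- c(0.1, 1, 10, 100, 1000)
  d <- diameter_from_volume(v)
  # the algebraic identity (survival-function form vs conditional-density
  # form of the sojourn kernel) on an empty history, where the integrand is
  # smooth and both quadratures are fully converged
  hz <- contribution_screen_invasive(d, 0, p, q, method = "hazard")
  de <- contribution_screen_invasive(d, 0, p, q, method = "density")
  expect_equal(hz / de, rep(1, length(v)), tolerance = 1e-6)
  # with a long screening history the integrand acquires kinks in r; the
  # two discretisations then agree to quadrature accuracy only
  offs <- seq(0, 40, 2)
  hz2 <- contribution_screen_invasive(d, offs, p, q, method = "hazard")
  de2 <- contribution_screen_invasive(d, offs, p, q, method = "density")
  expect_equal(hz2 / de2, rep(1, length(v)), tolerance = 5e-3)
})

test_that("class normalizers behave as probabilities of the detection classes", {
  p <- ref_params()
  q <- quad_settings(32, 32, 48)
  # empty symptomatic history: the two reduced integrals are the exit-type
  # probabilities and sum to one
  expect_equal(class_normalizer(numeric(), "symptomatic", p, q), 1,
               tolerance = 1e-9)
  # the constant is invariant to re-evaluation (cache-free path) and
  # positive for the screening patterns in use
  offs <- seq(0, 40, 2)
  n1 <- class_normalizer(offs, "screen", p, q)
  expect_gt(n1, 0)
  expect_equal(class_normalizer(offs, "screen", p, q), n1)
  # recent negative screens make large tumours less plausible: the
  # normalized symptomatic density loses mass at large sizes
  d <- diameter_from_volume(c(10, 1000))
  none <- contribution_symptomatic_invasive(d, numeric(), p, q)
  scr <- contribution_symptomatic_invasive(d, 1, p, q)
  expect_lt((scr[2] / scr[1]) / (none[2] / none[1]), 1)
})

test_that("interpolated symptomatic normalizers match exact evaluation", {
  po <- screened_population()
  set.seed(5)
  cs <- sample_case_dataset(po, 340, c(340, 342), 0.14)
  p <- ref_params()
  q_int <- quad_settings(12, 12, 24, n_shift = 9, shift_interp = TRUE)
  q_ex <- quad_settings(12, 12, 24, shift_interp = FALSE)
  cl_int <- case_loglik(cs, p, q_int)
  cl_ex <- case_loglik(cs, p, q_ex)
  # the shift profile of the log-normalizer carries weak fine structure on
  # top of a smooth trend; the spline tracks it to a few parts in a thousand,
  # commensurate with the quadrature accuracy at fitting orders
  expect_lt(max(abs(cl_int$log_normalizer - cl_ex$log_normalizer)), 5e-3)
})

test_that("total log-likelihood is additive, order-invariant and discriminating", {
  po <- screened_population()
  set.seed(6)
  cs <- sample_case_dataset(po, 340, c(340, 342), 0.1)
  p <- ref_params()
  q <- quad_settings(12, 12, 24)
  ll <- total_loglik(cs, p, q)
  expect_true(is.finite(ll))
  perm <- cs[sample(nrow(cs)), ]
  attr(perm, "nh_patterns") <- NULL
  expect_equal(total_loglik(perm, p, q), ll, tolerance = 1e-10)
  twice <- rbind(cs, cs)
  class(twice) <- class(cs)
  expect_equal(total_loglik(twice, p, q), 2 * ll, tolerance = 1e-8)
  # the data-generating parameters beat coarse distortions
  p_up <- nh_params(eta_T = 2 * p$eta_T, eta_D = 2 * p$eta_D,
                    eta_I = 2 * p$eta_I)
  p_dn <- nh_params(eta_T = p$eta_T / 2, eta_D = p$eta_D / 2,
                    eta_I = p$eta_I / 2)
  expect_gt(ll, total_loglik(cs, p_up, q))
  expect_gt(ll, total_loglik(cs, p_dn, q))
})
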