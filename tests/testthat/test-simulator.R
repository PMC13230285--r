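test_that("without screening the exit-type split and symptomatic sizes are correct", {
  p <- ref_params()
  pop <- population_config(onsets_per_step = 20L, step = 0.01,
                           t_start = 0, t_end = 60, seed = 31)
  po <- simulate_population(p, pop, NULL)
  ind <- po$individuals
  a <- prob_symptomatic_before_invasive(p)
  n <- nrow(ind)
  expect_lt(abs(mean(ind$fate == "dcis_symptomatic") - a),
            3 * sqrt(a * (1 - a) / n))
  # symptomatic sizes follow the closed-form densities
  dc <- ind$size_mm[ind$fate == "dcis_symptomatic"]
  ks1 <- suppressWarnings(ks.test(dc, function(l)
    cdf_symptomatic_lesion(l, p, competing = TRUE)))
  expect_gt(ks1$p.value, 0.01)
  vi <- volume_from_diameter(ind$size_mm[ind$fate == "invasive_symptomatic"])
  ks2 <- suppressWarnings(ks.test(vi, function(v)
    cdf_symptomatic_volume(v, p)))
  expect_gt(ks2$p.value, 0.01)
})

test_that("snapshot counts match stationary expectations and invariants", {
  p <- ref_params()
  pop <- population_config(onsets_per_step = 20L, step = 0.01,
                           t_start = 0, t_end = 150, seed = 8)
  po <- simulate_population(p, pop, NULL, keep_window = c(150, 150))
  sn <- snapshot_preclinical(po, 150)
  rate <- 20 / 0.01
  exp_dcis <- rate * expected_sojourn_dcis(p)
  exp_inv <- rate * expected_weighted_invasive_sojourn(p)
  expect_lt(abs(sn$counts[["dcis"]] - exp_dcis), 4 * sqrt(exp_dcis))
  expect_lt(abs(sn$counts[["invasive"]] - exp_inv), 4 * sqrt(exp_inv))
  # every invasive member transitioned before DCIS symptoms
  ind <- po$individuals
  inv <- ind$t_T < ind$t_D & ind$onset + ind$t_T <= 150 &
    150 < ind$onset + ind$t_T + ind$t_I
  expect_true(all(ind$t_T[inv] < ind$t_D[inv]))
  expect_equal(sum(inv), sn$counts[["invasive"]])
  # querying at the very start of the process finds nobody
  pop0 <- population_config(onsets_per_step = 5L, step = 0.01,
                            t_start = 0, t_end = 10, seed = 1)
  po0 <- simulate_population(p, pop0, NULL)
  expect_warning(sn0 <- snapshot_preclinical(po0, 0), "burn-in")
  # at the very first instant only the time-zero onset cohort can be present
  expect_true(all(sn0$snapshot$onset == 0))
  expect_lte(sum(sn0$counts), 5)
})

test_that("perfect screening sensitivity leaves no symptomatic case with a missed screen", {
  p1 <- nh_params(b0 = 40, b1 = 0, b2 = 0)   # sensitivity ~ 1
  pop <- population_config(onsets_per_step = 5L, step = 0.01,
                           t_start = 0, t_end = 60, seed = 12)
  sched <- screening_schedule(seq(20, 60, 1))
  po <- simulate_population(p1, pop, sched)
  ind <- po$individuals
  sym <- ind[ind$mode == "symptomatic", ]
  # no offered screen strictly between onset and symptomatic detection
  missed <- vapply(seq_len(nrow(sym)), function(i)
    any(sched >= sym$onset[i] & sched < sym$detection_time[i]),
    logical(1))
  expect_false(any(missed))
  # screens never detect before onset
  scr <- ind[ind$mode == "screen", ]
  expect_true(all(scr$detection_time >= scr$onset))
  expect_true(all(scr$size_mm >= p1$l0 * (1 - 1e-9)))
})

test_that("simulation is reproducible under a fixed seed", {
  p <- ref_params()
  pop <- population_config(onsets_per_step = 5L, step = 0.01,
                           t_start = 0, t_end = 40, seed = 77)
  po1 <- simulate_population(p, pop, screening_schedule(c(20, 30)))
  po2 <- simulate_population(p, pop, screening_schedule(c(20, 30)))
  expect_identical(po1$individuals, po2$individuals)
  # schedule times outside the window are dropped with a warning
  expect_warning(simulate_population(p, pop, screening_schedule(c(30, 50))),
                 "outside")
})

test_that("case sampling fractions and record structure behave as specified", {
  po <- screened_population()
  set.seed(3)
  cs0 <- sample_case_dataset(po, 340, c(340, 342), 0)
  expect_equal(nrow(cs0), 0)
  cs1 <- sample_case_dataset(po, 340, c(340, 342), 1)
  ind <- po$individuals
  n_eligible <- sum(ind$mode == "screen" &
                      abs(ind$detection_time - 340) < 1e-9) +
    sum(ind$mode == "symptomatic" & ind$detection_time >= 340 &
          ind$detection_time < 342)
  expect_equal(nrow(cs1), n_eligible)
  # screen-detected records end their screen list at the detection time
  scr <- cs1[cs1$detection_mode == "screen", ]
  expect_true(all(vapply(scr$screen_times, max, numeric(1)) == 340))
  validate_cases(cs1, ref_params())
})

test_that("case records survive a CSV round trip and malformed input is caught", {
  po <- screened_population()
  set.seed(4)
  cs <- sample_case_dataset(po, 340, c(340, 342), 0.5)
  cs <- cs[seq_len(min(1000, nrow(cs))), ]
  f <- tempfile(fileext = ".csv")
  write_cases(cs, f)
  cs2 <- read_cases(f)
  expect_equal(cs2$size_mm, cs$size_mm, tolerance = 1e-12)
  expect_equal(cs2$disease_type, cs$disease_type)
  expect_equal(cs2$screen_times, cs$screen_times, tolerance = 1e-9)
  # a screen-detected record whose last screen is not the detection time
  bad <- cs
  bad$screen_times[[which(bad$detection_mode == "screen")[1]]] <- c(300, 302)
  expect_error(validate_cases(bad, ref_params()), "last screen")
  # an empty file with a header reads back as an empty collection
  f2 <- tempfile(fileext = ".csv")
  writeLines(paste("case_id", "disease_type", "detection_mode", "size_mm",
                   "detection_time", "screen_times", sep = ","), f2)
  expect_equal(nrow(read_cases(f2)), 0)
  # malformed screen_times are reported with the row number
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("case_id,disease_type,detection_mode,size_mm,detection_time,screen_times",
               '1,dcis,symptomatic,5.2,341,"300;30x"'), f3)
  expect_error(read_cases(f3), "row 1")
})
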