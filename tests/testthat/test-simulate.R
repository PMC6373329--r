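test_that("reference simulation matches an independent ODE solution", {
  skip_if_not_installed("deSolve")
  kin <- subject_kinetics()   # k2' = 0.0322 1/min
  t_min <- seq(0, 120, by = 0.01)
  ref <- simulate_reference_tac(kin, t_min)
  mids <- frame_mid_min(build_schedule(default_schedule_spec()))
  ode <- deSolve::ode(
    y = c(C = 0), times = c(0, mids),
    func = function(t, y, p) list(kin$k1p * feng_input(kin$input, t) - kin$k2p * y),
    rtol = 1e-10, atol = 1e-12)
  ours <- approx(t_min, ref, xout = mids)$y
  expect_equal(ours, ode[-1, "C"], tolerance = 1e-4)
})

test_that("reference curve is linear in K1' and zero when K1' is zero", {
  t_min <- seq(0, 120, by = 0.05)
  base <- simulate_reference_tac(subject_kinetics(k1p = 0.15), t_min)
  expect_equal(simulate_reference_tac(subject_kinetics(k1p = 0.30), t_min),
               2 * base, tolerance = 1e-12)
  expect_equal(simulate_reference_tac(subject_kinetics(k1p = 0), t_min),
               rep(0, length(t_min)))
})

test_that("coarse simulation grids are refused", {
  kin <- subject_kinetics()
  expect_error(simulate_reference_tac(kin, seq(0, 120, by = 0.1)), "coarse")
})

test_that("zero-binding unit-delivery target collapses onto the reference", {
  s <- ideal_subject()
  tgt <- simulate_target_tac(list(true_bp = 0, r1 = 1), s$ref_fine,
                             s$kin$k2p, s$t_min)
  expect_equal(tgt, s$ref_fine, tolerance = 1e-12)
})

test_that("target simulation matches a two-compartment ODE oracle", {
  skip_if_not_installed("deSolve")
  s <- ideal_subject()
  r1 <- 0.9; bp <- 0.19
  k2a <- r1 * s$kin$k2p / (1 + bp)
  tgt <- simulate_target_tac(list(true_bp = bp, r1 = r1), s$ref_fine,
                             s$kin$k2p, s$t_min)
  mids <- frame_mid_min(s$sched)
  ode <- deSolve::ode(
    y = c(CR = 0, CT = 0), times = c(0, mids),
    func = function(t, y, p) {
      cp <- feng_input(s$kin$input, t)
      list(c(s$kin$k1p * cp - s$kin$k2p * y[1],
             r1 * s$kin$k1p * cp - k2a * y[2]))
    },
    rtol = 1e-10, atol = 1e-12)
  ours <- approx(s$t_min, tgt, xout = mids)$y
  expect_equal(ours, ode[-1, "CT"], tolerance = 1e-4)
})

test_that("late target/reference ratio climbs from below towards its
           transient-equilibrium asymptote", {
  # For input washout rate lam3 the ratio tends to
  # R1 (k2' - lam3) / (k2a - lam3); only for lam3 -> 0 does this equal
  # 1 + BP.  Checked on a 600-min extension.
  for (lam3 in c(0.01, 1e-5)) {
    kin <- subject_kinetics(input = feng_params(lam3 = lam3))
    t_min <- seq(0, 600, by = 0.01)
    ref <- simulate_reference_tac(kin, t_min)
    tgt <- simulate_target_tac(list(true_bp = 0.24, r1 = 1), ref,
                               kin$k2p, t_min)
    k2a <- kin$k2p / 1.24
    asym <- (kin$k2p - lam3) / (k2a - lam3)
    late <- tgt[t_min > 30] / ref[t_min > 30]
    expect_true(all(late < asym))
    expect_true(all(diff(late) > 0))
    expect_equal(tail(late, 1), asym, tolerance = 1e-3)
  }
  # the slow-washout limit recovers the true binding potential
  expect_equal((0.0322 - 1e-5) / (0.0322 / 1.24 - 1e-5) - 1, 0.24,
               tolerance = 1e-3)
})

test_that("forward model satisfies the SRTM2 operational equation", {
  # plugging the true parameters into the model residual on noiseless data
  s <- ideal_subject()
  for (bp in c(0.24, -0.07)) {
    r1 <- 0.95
    k2a <- r1 * s$kin$k2p / (1 + bp)
    tgt_fine <- simulate_target_tac(list(true_bp = bp, r1 = r1), s$ref_fine,
                                    s$kin$k2p, s$t_min)
    dt <- s$t_min[2] - s$t_min[1]
    conv <- refkin:::conv_exp(s$ref_fine, dt, k2a)
    resid <- tgt_fine - (r1 * s$ref_fine + r1 * (s$kin$k2p - k2a) * conv)
    expect_lt(max(abs(resid)), 1e-6 * max(s$ref_fine))
  }
})

test_that("noise follows the stated frame-duration SD law", {
  sched <- build_schedule("10000x300")   # 10,000 replicate 5-min frames
  tc <- new_tac("r", sched, rep(1, 10000))
  noisy <- add_noise(tc, alpha = 0.5, seed = 99)
  expect_equal(sd(noisy$values - 1), 0.5 * sqrt(1 / 5), tolerance = 0.02)
  # alpha = 0 is the identity; a fixed seed reproduces bit-identically
  expect_identical(add_noise(tc, 0), tc)
  expect_identical(add_noise(tc, 0.5, seed = 1)$values,
                   add_noise(tc, 0.5, seed = 1)$values)
  expect_error(add_noise(tc, -0.1), "non-negative")
})

test_that("degenerate cohort configs collapse to identical subjects", {
  cfg <- cohort_config(n_subjects = 3, noise_alpha = 0, k2p_sd = 0,
                       bp_jitter_sd = 0, seed = 5,
                       schedule_spec = "3x60,2x300")
  co <- generate_cohort(cfg)
  v1 <- co$subjects[[1]]$tacs$value_kbq_ml
  expect_equal(co$subjects[[2]]$tacs$value_kbq_ml, v1)
  expect_equal(co$subjects[[3]]$tacs$value_kbq_ml, v1)
})

test_that("cohort generation is deterministic and extensible by subject", {
  cfg <- cohort_config(n_subjects = 3, seed = 1, schedule_spec = "3x60,2x300")
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  # adding subjects never perturbs earlier ones (per-subject substreams)
  cfg5 <- cohort_config(n_subjects = 5, seed = 1, schedule_spec = "3x60,2x300")
  c5 <- generate_cohort(cfg5)
  expect_identical(c5$subjects[1:3], a$subjects)
})

test_that("sampled k2' distribution recovers the population mean", {
  co <- noiseless_cohort()
  k2ps <- vapply(co$subjects, `[[`, 0, "k2p")
  se <- 0.0105 / sqrt(length(k2ps))
  expect_lt(abs(mean(k2ps) - 0.0322), 3 * se)
  expect_true(all(k2ps > 0.005))
})

test_that("every TAC carries its ground truth and round-trips losslessly", {
  cfg <- cohort_config(n_subjects = 2, seed = 3, schedule_spec = "3x60,2x300")
  co <- generate_cohort(cfg)
  tr <- co$subjects[[1]]$truth
  expect_setequal(tr$region, tac_regions(co$subjects[[1]]$tacs))
  expect_true(all(c("true_bp", "r1", "k2a", "k2p") %in% names(tr)))
  expect_equal(tr$k2a, tr$r1 * tr$k2p / (1 + tr$true_bp))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(back$subjects[[1]]$tacs$value_kbq_ml,
                   co$subjects[[1]]$tacs$value_kbq_ml)
  expect_equal(back$subjects[[2]]$truth$true_bp,
               co$subjects[[2]]$truth$true_bp)
  expect_identical(back$config, co$config)
})

test_that("scaling the input function scales every TAC linearly", {
  cfgs <- list(feng_params(), feng_params(a1 = 1600, a2 = 40, a3 = 20))
  t_min <- seq(0, 60, by = 0.02)
  kin1 <- subject_kinetics(input = cfgs[[1]])
  kin2 <- subject_kinetics(input = cfgs[[2]])
  r1 <- simulate_reference_tac(kin1, t_min)
  r2 <- simulate_reference_tac(kin2, t_min)
  expect_equal(r2, 2 * r1, tolerance = 1e-10)
  t1 <- simulate_target_tac(list(true_bp = 0.24, r1 = 1), r1, 0.0322, t_min)
  t2 <- simulate_target_tac(list(true_bp = 0.24, r1 = 1), r2, 0.0322, t_min)
  expect_equal(t2, 2 * t1, tolerance = 1e-10)
})

test_that("registry defaults satisfy their invariants", {
  reg <- default_regions()
  expect_equal(n_target_vois(reg), 17L)
  expect_equal(sum(reg$role == "reference"), 1L)
  expect_equal(reg$true_bp[reg$role == "reference"], 0)
  expect_true(all(reg$true_bp > -1))
  expect_true(all(reg$r1 > 0))
  expect_error(subject_kinetics(k2p = -1), "positive")
  expect_error(simulate_target_tac(list(true_bp = -1.5, r1 = 1),
                                   rep(0, 100), 0.03,
                                   seq(0, 1, length.out = 100)),
               "true_bp")
})
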