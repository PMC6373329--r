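test_that("running integral is exact for curves linear through the origin", {
  sched <- build_schedule(default_schedule_spec())
  mid <- frame_mid_min(sched)
  # linear curve a*t sampled as exact frame averages a*(start+end)/2:
  # mid-time nodes lie on the line, so the trapezoid from (0,0) is exact
  a <- 0.7
  tc <- new_tac("lin", sched, a * mid)
  expect_equal(cumulative_integral(tc), a * mid^2 / 2, tolerance = 1e-12)
  # zero curve
  expect_equal(cumulative_integral(new_tac("z", sched, rep(0, 33))),
               rep(0, 33))
  # constant curve: the (0,0) anchor costs exactly half the first segment
  tc1 <- new_tac("c", sched, rep(1, 33))
  expect_equal(cumulative_integral(tc1), mid - mid[1] / 2, tolerance = 1e-12)
})

test_that("MRTM recovers k2' and BP from noiseless consistent data", {
  s <- ideal_subject()
  thal <- ideal_target(0.24, r1 = 1, region = "thalamus")
  f <- mrtm_fit(truncate_to(thal, 90), truncate_to(s$ref, 90))
  expect_lt(abs(f$k2p - 0.0322) / 0.0322, 0.01)
  expect_lt(abs(f$bp - 0.24), 0.005)
  # noiseless residuals are tiny relative to the signal
  expect_lt(f$rss, 1e-8 * mean(truncate_to(thal, 90)$values^2) * f$n)
  expect_true(is.finite(f$cond))
})

test_that("proportional target and reference trip the collinearity guard", {
  s <- ideal_subject()
  prop <- new_tac("prop", s$sched, 0.8 * s$ref$values)
  expect_error(mrtm_fit(prop, s$ref), "collinearity")
})

test_that("MRTM needs enough usable frames", {
  s <- ideal_subject()
  thal <- ideal_target(0.24)
  expect_error(mrtm_fit(thal, s$ref, t_star_min = 119), "fewer than")
})

test_that("MRTM2 recovers every registry binding level with the true k2'", {
  s <- ideal_subject()
  reg <- default_regions()
  reg <- reg[!(reg$role %in% c("reference", "merged")), ]
  for (i in seq_len(nrow(reg))) {
    tgt <- ideal_target(reg$true_bp[i], reg$r1[i], reg$name[i])
    f <- mrtm2_fit(truncate_to(tgt, 90), truncate_to(s$ref, 90), 0.0322)
    expect_lt(abs(f$bp - reg$true_bp[i]), 0.005)
  }
})

test_that("MRTM2 on the reference against itself gives zero binding", {
  s <- ideal_subject()
  f <- mrtm2_fit(s$ref, s$ref, 0.0322)
  expect_lt(abs(f$bp), 1e-6)
})

test_that("a mis-set k2' biases MRTM2 but keeps it finite and bounded", {
  s <- ideal_subject()
  reg <- default_regions()
  reg <- reg[!(reg$role %in% c("reference", "merged")), ]
  for (i in seq_len(nrow(reg))) {
    tgt <- ideal_target(reg$true_bp[i], reg$r1[i], reg$name[i])
    f <- mrtm2_fit(truncate_to(tgt, 90), truncate_to(s$ref, 90), 2 * 0.0322)
    expect_true(is.finite(f$bp))
    expect_lt(abs(f$bp), 1)
  }
})

test_that("SRTM2 on identical TACs returns unit delivery and zero binding", {
  s <- ideal_subject()
  f <- suppressWarnings(srtm2_fit(s$ref, s$ref, 0.0322))
  expect_equal(f$r1, 1, tolerance = 1e-6)
  expect_equal(f$k2a, 0.0322, tolerance = 1e-4)
  expect_lt(abs(f$bp), 1e-3)
})

test_that("SRTM2 recovers thalamus- and locus-coeruleus-like kinetics", {
  s <- ideal_subject()
  ref90 <- truncate_to(s$ref, 90)
  basis <- srtm2_basis(ref90, 0.0322)
  thal <- srtm2_fit(truncate_to(ideal_target(0.24, 1), 90), basis = basis)
  expect_lt(abs(thal$bp - 0.24), 0.005)
  lc <- srtm2_fit(truncate_to(ideal_target(0.19, 0.9), 90), basis = basis)
  expect_lt(abs(lc$bp - 0.19), 0.005)
  expect_lt(abs(lc$r1 - 0.9), 0.01)
  expect_false(thal$boundary || lc$boundary)
})

test_that("all fitted quantities are invariant to a common rescaling", {
  s <- ideal_subject()
  tgt <- truncate_to(ideal_target(0.24, 1), 90)
  ref <- truncate_to(s$ref, 90)
  sc <- 37.2
  tgt2 <- new_tac(tgt$region, tgt$schedule, sc * tgt$values)
  ref2 <- new_tac(ref$region, ref$schedule, sc * ref$values)
  f1 <- mrtm_fit(tgt, ref); f2 <- mrtm_fit(tgt2, ref2)
  expect_equal(f2$k2p, f1$k2p, tolerance = 1e-10)
  expect_equal(f2$bp, f1$bp, tolerance = 1e-10)
  m1 <- mrtm2_fit(tgt, ref, 0.0322); m2 <- mrtm2_fit(tgt2, ref2, 0.0322)
  expect_equal(m2$bp, m1$bp, tolerance = 1e-10)
  s1 <- srtm2_fit(tgt, ref, 0.0322); s2 <- srtm2_fit(tgt2, ref2, 0.0322)
  expect_equal(s2$bp, s1$bp, tolerance = 1e-8)
  expect_equal(s2$k2a, s1$k2a, tolerance = 1e-6)
})

test_that("fits do not depend on t* for noiseless consistent data", {
  s <- ideal_subject()
  tgt <- truncate_to(ideal_target(0.24, 1), 90)
  ref <- truncate_to(s$ref, 90)
  k2p <- sapply(c(0, 10, 20), function(ts) mrtm_fit(tgt, ref, t_star_min = ts)$k2p)
  bp <- sapply(c(0, 10, 20), function(ts) mrtm2_fit(tgt, ref, 0.0322, t_star_min = ts)$bp)
  expect_lt(max(k2p) - min(k2p), 0.01 * 0.0322)
  expect_lt(max(bp) - min(bp), 1e-3)
})

test_that("population k2' estimation averages per-subject MRTM estimates", {
  co <- ideal_cohort()   # all true k2' = 0.0322, noiseless
  pop <- estimate_population_k2p(co)
  expect_equal(nrow(pop$per_subject), 10L)
  expect_lt(abs(pop$mean - 0.0322) / 0.0322, 0.01)
  # a single-subject cohort's mean is that subject's estimate
  one <- structure(list(schedule = co$schedule, config = co$config,
                        clinical = co$clinical[1, ],
                        subjects = co$subjects[1]),
                   class = "pet_cohort")
  p1 <- estimate_population_k2p(one)
  expect_equal(p1$mean, p1$per_subject$k2p[1])
  expect_equal(p1$mean, pop$per_subject$k2p[1])
})

test_that("population k2' under noise stays within 10% of the truth", {
  co <- generate_cohort(cohort_config(noise_alpha = 0.3, k2p_sd = 0,
                                      bp_jitter_sd = 0, seed = 1))
  pop <- estimate_population_k2p(co)
  expect_gt(sd(pop$per_subject$k2p), 0)
  expect_lt(abs(pop$mean - 0.0322) / 0.0322, 0.10)
})

test_that("a failing subject aborts population estimation by name", {
  co <- ideal_cohort()
  bad <- co$subjects[[2]]
  flat <- bad$tacs
  # make the high-binding region exactly proportional to the reference
  occ <- tac_get(flat, "occipital")
  tacs <- lapply(tac_regions(flat), function(r) {
    if (r == "thalamus_merged") new_tac(r, occ$schedule, 0.8 * occ$values)
    else tac_get(flat, r)
  })
  co$subjects[[2]]$tacs <- tac_table(tacs)
  expect_error(estimate_population_k2p(co), "sub02")
})

test_that("MRTM2 and SRTM2 agree with each other and with the truth", {
  fits <- ideal_fits()$fits
  truth <- ideal_cohort()$subjects[[1]]$truth
  m <- merge(fits, truth[, c("region", "true_bp")], by = "region")
  expect_true(all(abs(m$bp - m$true_bp) < 0.005))
  wide <- merge(m[m$method == "MRTM2", c("subject", "region", "bp")],
                m[m$method == "SRTM2", c("subject", "region", "bp")],
                by = c("subject", "region"), suffixes = c("_m", "_s"))
  expect_true(all(abs(wide$bp_m - wide$bp_s) < 0.005))
})
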