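# Convolution of a piecewise-linear curve with exp(-k t) on a uniform grid.
# Exact for piecewise-linear f; evaluated via the linear recursion
#   y[i+1] = E y[i] + A f[i] + B f[i+1],  E = exp(-k dt),
# which stats::filter runs in C.  For k ~ 0 it degenerates to the running
# trapezoidal integral.
conv_exp <- function(f, dt, k) {
  n <- length(f)
  if (k * dt < 1e-12) {
    return(c(0, cumsum((f[-n] + f[-1L]) / 2 * dt)))
  }
  E <- exp(-k * dt)
  A <- (1 - E * (1 + k * dt)) / (k^2 * dt)
  B <- (1 - E) / k - A
  b <- c(0, f[-n] * A + f[-1L] * B)
  as.numeric(stats::filter(b, E, method = "recursive"))
}

#' Region registry with default ground-truth binding
#'
#' The region set used for simulation and reporting: eight bilateral target
#' regions (amygdala, caudate, cerebellum, frontal lobe, hippocampus,
#' parietal lobe, putamen, thalamus) plus the brainstem -- the 17 atlas target
#' VOIs -- together with a bilateral locus coeruleus, the occipital reference
#' region (zero specific binding by construction) and a bookkeeping entry for
#' the fused left+right thalamus used in k2' estimation.
#'
#' Default `true_bp` levels are representative noradrenaline-transporter
#' binding potentials for this tracer class (high binding in thalamus,
#' putamen and locus coeruleus; near zero elsewhere); `r1` is the delivery
#' ratio K1/K1'.
#'
#' @return Data frame with columns `name`, `group`, `side`, `role`
#'   (`"target"`, `"lc"`, `"reference"`, `"merged"`), `true_bp`, `r1`.
#' @export
default_regions <- function() {
  lvl <- function(group, bp, r1, role = "target") {
    data.frame(name = paste0(group, c("_l", "_r")), group = group,
               side = c("l", "r"), role = role, true_bp = bp, r1 = r1)
  }
  paired <- rbind(
    lvl("amygdala",       -0.01, 0.95),
    lvl("caudate",        -0.03, 1.00),
    lvl("cerebellum",     -0.04, 1.00),
    lvl("frontal",         0.02, 0.95),
    lvl("hippocampus",    -0.04, 0.95),
    lvl("parietal",       -0.04, 0.95),
    lvl("putamen",         0.25, 1.00),
    lvl("thalamus",        0.24, 1.00),
    lvl("locus_coeruleus", 0.19, 0.90, role = "lc")
  )
  single <- data.frame(
    name = c("brainstem", "occipital", "thalamus_merged"),
    group = c("brainstem", "occipital", "thalamus_merged"),
    side = NA_character_,
    role = c("target", "reference", "merged"),
    true_bp = c(-0.07, 0, 0.24),
    r1 = c(0.95, 1, 1))
  out <- rbind(paired, single)
  rownames(out) <- NULL
  out
}

#' Count of atlas target VOIs in a region registry
#' @param regions A registry data frame as from [default_regions()].
#' @return Integer count of regions with role `"target"`.
#' @export
n_target_vois <- function(regions = default_regions()) {
  sum(regions$role == "target")
}

#' Subject-level kinetic ground truth
#'
#' @param k2p Reference-region efflux rate k2' (1/min).
#' @param k1p Reference-region influx K1' (mL/min/mL); pure scale factor.
#' @param regions Region registry (see [default_regions()]).
#' @param input Plasma input parameters ([feng_params()]).
#' @return Object of class `subject_kinetics`.
#' @export
subject_kinetics <- function(k2p = 0.0322, k1p = 0.15,
                             regions = default_regions(),
                             input = feng_params()) {
  if (k2p <= 0) stop("k2p must be positive", call. = FALSE)
  if (k1p < 0) stop("k1p must be non-negative", call. = FALSE)
  stopifnot(is.data.frame(regions),
            all(c("name", "true_bp", "r1", "role") %in% names(regions)))
  if (sum(regions$role == "reference") != 1L)
    stop("exactly one region must have role 'reference'", call. = FALSE)
  if (any(regions$true_bp <= -1))
    stop("true_bp must exceed -1", call. = FALSE)
  if (any(regions$r1 <= 0)) stop("r1 must be positive", call. = FALSE)
  k2a <- regions$r1 * k2p / (1 + regions$true_bp)
  if (any(!is.finite(k2a) | k2a <= 0))
    stop("implied k2a must be finite and positive", call. = FALSE)
  structure(list(k2p = k2p, k1p = k1p, regions = regions, input = input),
            class = "subject_kinetics")
}

#' Simulate the continuous reference-region curve
#'
#' One-tissue reference kinetics: `C_R(t) = K1' (C_p (x) e^{-k2' t})`, the
#' convolution evaluated exactly for the piecewise-linear plasma curve on the
#' fine grid.  The grid must be uniform with spacing at most 0.05 min to
#' protect convolution accuracy.
#'
#' @param kin A [subject_kinetics()] object.
#' @param t_min Uniform fine time grid (min) starting at 0.
#' @return Reference concentration (kBq/mL) on `t_min`.
#' @export
simulate_reference_tac <- function(kin, t_min) {
  stopifnot(inherits(kin, "subject_kinetics"))
  dt <- check_fine_grid(t_min)
  cp <- feng_input(kin$input, t_min)
  kin$k1p * conv_exp(cp, dt, kin$k2p)
}

check_fine_grid <- function(t_min, max_dt = 0.05) {
  stopifnot(length(t_min) >= 2L)
  d <- diff(t_min)
  if (any(d <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  dt <- d[1L]
  if (any(abs(d - dt) > 1e-9 * max(1, dt)))
    stop("time grid must be uniform", call. = FALSE)
  if (dt > max_dt + 1e-12)
    stop(sprintf("time grid too coarse (%.4g min > %.4g min)", dt, max_dt),
         call. = FALSE)
  if (abs(t_min[1L]) > 1e-12) stop("time grid must start at 0", call. = FALSE)
  dt
}

#' Simulate a continuous target-region curve
#'
#' Two-parameter simplified reference tissue kinetics:
#' `C_T(t) = R1 C_R(t) + R1 (k2' - k2a) (C_R (x) e^{-k2a t})` with
#' `k2a = R1 k2' / (1 + BPND)`, so the curve's true non-displaceable binding
#' potential is exactly `true_bp`.
#'
#' @param region One row of a region registry (list or data frame row with
#'   `true_bp` and `r1`).
#' @param ref_curve Continuous reference curve on `t_min`
#'   (from [simulate_reference_tac()]).
#' @param k2p Reference efflux rate k2' (1/min).
#' @param t_min The shared uniform fine grid (min).
#' @return Target concentration (kBq/mL) on `t_min`.
#' @export
simulate_target_tac <- function(region, ref_curve, k2p, t_min) {
  dt <- check_fine_grid(t_min)
  stopifnot(length(ref_curve) == length(t_min))
  bp <- region$true_bp
  r1 <- region$r1
  if (bp <= -1) stop("true_bp must exceed -1", call. = FALSE)
  k2a <- r1 * k2p / (1 + bp)
  if (!is.finite(k2a) || k2a <= 0)
    stop("implied k2a must be finite and positive", call. = FALSE)
  r1 * ref_curve + r1 * (k2p - k2a) * conv_exp(ref_curve, dt, k2a)
}

#' Add frame-duration-dependent noise to a TAC
#'
#' Count-statistics surrogate: each frame value is perturbed by independent
#' Gaussian noise with standard deviation
#' `alpha * sqrt(max(value, 0.01) / dur_min)`, so short early frames are
#' noisier than long late frames.  `alpha = 0` returns the input unchanged;
#' a fixed seed gives identical output.
#'
#' @param x A `tac` or `tac_table`.
#' @param alpha Non-negative noise scale (unitless).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @return Object of the same class as `x`.
#' @export
add_noise <- function(x, alpha, seed = NULL) {
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (alpha == 0) return(x)
  noisy_one <- function(tc) {
    sd <- alpha * sqrt(pmax(tc$values, 0.01) / frame_dur_min(tc$schedule))
    new_tac(tc$region, tc$schedule, tc$values + stats::rnorm(length(sd), 0, sd))
  }
  if (inherits(x, "tac")) return(noisy_one(x))
  stopifnot(inherits(x, "tac_table"))
  tac_table(lapply(tac_regions(x), function(r) noisy_one(tac_get(x, r))))
}

#' Cohort generation settings
#'
#' Defaults emulate the study conditions this package targets: a 10-subject
#' cohort on the 33-frame 120-min protocol, population k2' of
#' 0.0322 +/- 0.0105 1/min, inter-subject binding spread of 0.05 (the scale of
#' the region-level SDs reported for this tracer), and moderate
#' frame-duration-dependent noise.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param schedule_spec Frame schedule string (see [build_schedule()]).
#' @param noise_alpha Noise scale for [add_noise()]; 0 = noiseless.
#' @param k2p_mean,k2p_sd Population mean and SD of k2' (1/min); samples are
#'   truncated to > 0.005 1/min.
#' @param bp_jitter_sd Inter-subject SD of region binding potential; one draw
#'   per region group, shared by left/right.
#' @param seed Integer cohort seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 10,
                          schedule_spec = default_schedule_spec(),
                          noise_alpha = 0.3,
                          k2p_mean = 0.0322, k2p_sd = 0.0105,
                          bp_jitter_sd = 0.05,
                          seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (noise_alpha < 0) stop("noise_alpha must be >= 0", call. = FALSE)
  if (k2p_mean <= 0) stop("k2p_mean must be positive", call. = FALSE)
  if (k2p_sd < 0 || bp_jitter_sd < 0)
    stop("spread parameters must be non-negative", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 schedule_spec = schedule_spec,
                 noise_alpha = noise_alpha,
                 k2p_mean = k2p_mean, k2p_sd = k2p_sd,
                 bp_jitter_sd = bp_jitter_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic dynamic-PET cohort with known ground truth
#'
#' Per subject: k2' is sampled from the truncated population normal, region
#' binding potentials are jittered around the registry defaults (one draw per
#' region group, so left and right share a level), continuous reference and
#' target curves are simulated on a 0.01-min grid, frame-binned on the
#' schedule, and perturbed with frame-duration-dependent noise.  The fused
#' thalamus TAC is the equal-weight average of the left and right thalamus
#' curves.  Ground-truth parameters are stored alongside every TAC.
#'
#' The cohort seed spawns one independent per-subject substream, so extending
#' the cohort never perturbs earlier subjects.  Clinical covariates from the
#' packaged patient table are attached (recycled if `n_subjects` exceeds the
#' table).
#'
#' @param cfg A [cohort_config()].
#' @param template A [subject_kinetics()] providing the region registry,
#'   input-function parameters and K1'.
#' @param fine_dt Simulation grid spacing (min).
#' @param keep_fine Keep the continuous reference curve per subject (for
#'   diagnostics); default drops it.
#' @return Object of class `pet_cohort`: list with `schedule`, `config`,
#'   `clinical`, and `subjects` (each with `id`, `k2p`, `tacs`, `truth`).
#' @export
generate_cohort <- function(cfg = cohort_config(),
                            template = subject_kinetics(),
                            fine_dt = 0.01,
                            keep_fine = FALSE) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(template, "subject_kinetics"))
  sched <- build_schedule(cfg$schedule_spec)
  t_min <- seq(0, total_duration_min(sched), by = fine_dt)
  regions <- template$regions
  groups <- unique(regions$group[!(regions$role %in% c("reference", "merged"))])

  set.seed(cfg$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_subjects)

  subjects <- lapply(seq_len(cfg$n_subjects), function(i) {
    set.seed(sub_seeds[i])
    k2p <- rtrunc_norm(cfg$k2p_mean, cfg$k2p_sd, lower = 0.005)
    jit <- stats::rnorm(length(groups), 0, cfg$bp_jitter_sd)
    names(jit) <- groups

    reg <- regions
    idx <- !(reg$role %in% c("reference", "merged"))
    reg$true_bp[idx] <- pmax(reg$true_bp[idx] + jit[reg$group[idx]], -0.95)
    mrow <- reg$role == "merged"
    if (any(mrow)) {
      thal <- reg$group == "thalamus" & !mrow
      if (any(thal)) reg$true_bp[mrow] <- mean(reg$true_bp[thal])
    }

    kin <- subject_kinetics(k2p = k2p, k1p = template$k1p,
                            regions = reg, input = template$input)
    ref_fine <- simulate_reference_tac(kin, t_min)
    tacs <- lapply(seq_len(nrow(reg)), function(j) {
      r <- reg[j, ]
      curve <- if (r$role == "reference") ref_fine
               else simulate_target_tac(r, ref_fine, k2p, t_min)
      bin_to_frames(t_min, curve, sched, region = r$name)
    })
    tactab <- tac_table(tacs)
    # fused thalamus is the average of the (already binned) l/r TACs
    if (any(reg$role == "merged")) {
      merged_name <- reg$name[reg$role == "merged"][1L]
      thal_names <- reg$name[reg$group == "thalamus" & reg$role != "merged"]
      if (length(thal_names) == 2L) {
        fused <- merge_regions(tactab, thal_names, name = merged_name)
        tacs[[which(reg$name == merged_name)]] <- fused
        tactab <- tac_table(tacs)
      }
    }
    tactab <- add_noise(tactab, cfg$noise_alpha)
    truth <- data.frame(region = reg$name, group = reg$group, role = reg$role,
                        true_bp = reg$true_bp, r1 = reg$r1,
                        k2a = reg$r1 * k2p / (1 + reg$true_bp),
                        k2p = k2p)
    out <- list(id = sprintf("sub%02d", i), k2p = k2p,
                tacs = tactab, truth = truth)
    if (keep_fine) out$fine <- list(t_min = t_min, reference = ref_fine)
    out
  })

  clin <- read_clinical()
  clin <- clin[((seq_len(cfg$n_subjects) - 1L) %% nrow(clin)) + 1L, , drop = FALSE]
  clin$subject <- vapply(subjects, `[[`, "", "id")
  rownames(clin) <- NULL

  structure(list(schedule = sched, config = cfg, clinical = clin,
                 subjects = subjects),
            class = "pet_cohort")
}

rtrunc_norm <- function(mean, sd, lower) {
  if (sd == 0) return(max(mean, lower))
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x > lower) return(x)
  }
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf("<pet_cohort> %d subjects, %d regions, %d frames (%g min)\n",
              length(x$subjects), length(tac_regions(x$subjects[[1L]]$tacs)),
              nrow(x$schedule), total_duration_min(x$schedule)))
  invisible(x)
}
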