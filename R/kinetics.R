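#' Running integral of a TAC at frame mid-times
#'
#' Cumulative integral from time 0 to each frame mid-time, by the trapezoidal
#' rule on the mid-time nodes with an initial segment anchored at (0, 0) --
#' the discretization used by the multilinear operational equations.  Exact
#' for curves that are linear through the origin.
#'
#' @param tac A `tac` on a contiguous schedule starting at 0.
#' @return Numeric vector (kBq/mL * min), one value per frame.
#' @export
cumulative_integral <- function(tac) {
  stopifnot(inherits(tac, "tac"))
  mid <- frame_mid_min(tac$schedule)
  tn <- c(0, mid)
  vn <- c(0, tac$values)
  cumsum(diff(tn) * (vn[-length(vn)] + vn[-1L]) / 2)
}

mrtm_design_check <- function(X, cond_limit = 1e8) {
  sc <- apply(abs(X), 2, max)
  sc[sc == 0] <- 1
  cond <- kappa(sweep(X, 2, sc, "/"), exact = TRUE)
  if (!is.finite(cond) || cond > cond_limit)
    stop(sprintf(
      "collinearity error: design condition number %.3g exceeds %.0e",
      cond, cond_limit), call. = FALSE)
  cond
}

fit_rows <- function(mid, t_star_min, min_frames = 4L) {
  keep <- mid >= t_star_min - 1e-9
  if (sum(keep) < min_frames)
    stop(sprintf("fewer than %d usable frames at or after t* = %g min",
                 min_frames, t_star_min), call. = FALSE)
  keep
}

check_pair <- function(target, reference) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (!schedules_equal(target$schedule, reference$schedule))
    stop("target and reference TACs must share a schedule", call. = FALSE)
  invisible(TRUE)
}

#' Fit the multilinear reference tissue model (MRTM)
#'
#' Ordinary least squares on the operational equation
#' `C_T(T) = g1 Int C_R + g2 Int C_T + g3 C_R(T)` over frames with mid-time at
#' or after `t_star_min`.  The reference efflux rate is recovered as
#' `k2' = g1 / g3` and the binding potential as `BPND = -(g1/g2 + 1)`.
#' Applied to a transporter-rich region (fused thalamus) against the
#' reference region, this is the per-subject k2' estimator.
#'
#' @param target,reference `tac` objects on one schedule.
#' @param t_star_min Start of the fit window (min); 0 uses all frames.
#' @param weights Optional frame weights (e.g. `frame_dur_min(schedule)`);
#'   unweighted by default.
#' @return Object of class `mrtm_fit`: list with `gamma` (3 coefficients),
#'   `k2p`, `bp`, `rss`, `cond`, `n`.
#' @export
mrtm_fit <- function(target, reference, t_star_min = 0, weights = NULL) {
  check_pair(target, reference)
  mid <- frame_mid_min(target$schedule)
  X <- cbind(int_ref = cumulative_integral(reference),
             int_tgt = cumulative_integral(target),
             ref = reference$values)
  keep <- fit_rows(mid, t_star_min)
  Xk <- X[keep, , drop = FALSE]
  yk <- target$values[keep]
  cond <- mrtm_design_check(Xk)
  fit <- if (is.null(weights)) stats::lm.fit(Xk, yk)
         else stats::lm.wfit(Xk, yk, w = weights[keep])
  g <- unname(fit$coefficients)
  structure(list(gamma = g,
                 k2p = g[1L] / g[3L],
                 bp = -(g[1L] / g[2L] + 1),
                 rss = sum(fit$residuals^2),
                 cond = cond,
                 n = sum(keep),
                 t_star_min = t_star_min),
            class = "mrtm_fit")
}

#' Fit MRTM2 with a fixed reference efflux rate
#'
#' Two-coefficient least squares on
#' `C_T(T) = g1 (Int C_R + C_R(T)/k2') + g2 Int C_T`, with k2' fixed (usually
#' to the population mean from [estimate_population_k2p()]).  Returns
#' `BPND = -(g1/g2 + 1)`; `g1 = R1 k2'` and `-g2 = k2a` are also reported.
#'
#' @inheritParams mrtm_fit
#' @param k2p_fixed Fixed reference efflux rate k2' (1/min), > 0.
#' @return Object of class `mrtm2_fit`: list with `gamma`, `bp`, `r1`, `k2a`,
#'   `k2p_fixed`, `rss`, `cond`, `n`.
#' @export
mrtm2_fit <- function(target, reference, k2p_fixed, t_star_min = 0,
                      weights = NULL) {
  check_pair(target, reference)
  if (!is.finite(k2p_fixed) || k2p_fixed <= 0)
    stop("k2p_fixed must be positive", call. = FALSE)
  mid <- frame_mid_min(target$schedule)
  X <- cbind(ref_comb = cumulative_integral(reference) +
               reference$values / k2p_fixed,
             int_tgt = cumulative_integral(target))
  keep <- fit_rows(mid, t_star_min, min_frames = 3L)
  Xk <- X[keep, , drop = FALSE]
  yk <- target$values[keep]
  cond <- mrtm_design_check(Xk)
  fit <- if (is.null(weights)) stats::lm.fit(Xk, yk)
         else stats::lm.wfit(Xk, yk, w = weights[keep])
  g <- unname(fit$coefficients)
  structure(list(gamma = g,
                 bp = -(g[1L] / g[2L] + 1),
                 r1 = g[1L] / k2p_fixed,
                 k2a = -g[2L],
                 k2p_fixed = k2p_fixed,
                 rss = sum(fit$residuals^2),
                 cond = cond,
                 n = sum(keep),
                 t_star_min = t_star_min),
            class = "mrtm2_fit")
}

#' Precompute the SRTM2 basis for one reference TAC
#'
#' The SRTM2 solution is `C_T = R1 [C_R + (k2' - k2a) (C_R (x) e^{-k2a t})]`.
#' For each candidate `k2a` on a log-spaced grid the convolution term is
#' evaluated on a fine uniform grid (the frame-sampled reference curve is
#' linearly interpolated through its mid-times, anchored at (0,0)) and then
#' frame-binned.  Computing the basis once per subject makes fitting all of
#' that subject's regions cheap.
#'
#' @param reference Reference-region `tac`.
#' @param k2p_fixed Fixed k2' (1/min).
#' @param k2a_grid Candidate apparent efflux rates (1/min); default 100
#'   log-spaced points in `[1e-4, 1]`.
#' @param fine_dt Fine grid spacing (min).
#' @return Object of class `srtm2_basis`.
#' @export
srtm2_basis <- function(reference, k2p_fixed,
                        k2a_grid = 10^seq(-4, 0, length.out = 100),
                        fine_dt = 0.01) {
  stopifnot(inherits(reference, "tac"))
  if (!is.finite(k2p_fixed) || k2p_fixed <= 0)
    stop("k2p_fixed must be positive", call. = FALSE)
  sched <- reference$schedule
  t_end <- total_duration_min(sched)
  t_min <- seq(0, t_end, by = fine_dt)
  mid <- frame_mid_min(sched)
  ref_fine <- stats::approx(c(0, mid), c(0, reference$values),
                            xout = t_min, rule = 2)$y
  binner <- make_frame_binner(t_min, sched)
  basis_for <- function(k2a) {
    conv <- conv_exp(ref_fine, fine_dt, k2a)
    if (any(!is.finite(conv))) stop("non-finite basis", call. = FALSE)
    binner(conv)
  }
  B <- vapply(k2a_grid, basis_for, numeric(nrow(sched)))
  structure(list(reference = reference, k2p_fixed = k2p_fixed,
                 k2a_grid = k2a_grid, B = B,
                 basis_for = basis_for, fine_dt = fine_dt),
            class = "srtm2_basis")
}

# Closure that frame-bins any curve on the fixed fine grid.
make_frame_binner <- function(t_min, sched) {
  dt <- t_min[2L] - t_min[1L]
  i0 <- round(sched$start_s / 60 / dt) + 1L
  i1 <- round(sched$end_s / 60 / dt) + 1L
  if (any(abs(t_min[i1] - sched$end_s / 60) > 1e-6))
    stop("frame boundaries do not align to the fine grid", call. = FALSE)
  dur <- (sched$end_s - sched$start_s) / 60
  function(values) {
    ct <- c(0, cumsum(dt * (values[-length(values)] + values[-1L]) / 2))
    (ct[i1] - ct[i0]) / dur
  }
}

#' Fit the two-parameter simplified reference tissue model (SRTM2)
#'
#' Basis-function fit: for each candidate `k2a` the model collapses to a
#' one-amplitude linear regression of the target TAC on
#' `C_R + (k2' - k2a) B(k2a)`; the candidate with minimal residual sum of
#' squares wins and is refined by golden-section search between its grid
#' neighbours.  `BPND = R1 k2' / k2a - 1`.  An optimum at a grid boundary is
#' flagged, not silently accepted.
#'
#' @param target Target-region `tac`.
#' @param reference Reference `tac` (ignored when `basis` is supplied).
#' @param k2p_fixed Fixed k2' (1/min) (ignored when `basis` is supplied).
#' @param basis Optional precomputed [srtm2_basis()] for the subject.
#' @param ... Passed to [srtm2_basis()] when one must be built.
#' @return Object of class `srtm2_fit`: list with `r1`, `k2a`, `bp`,
#'   `k2p_fixed`, `rss`, `boundary` (logical flag).
#' @export
srtm2_fit <- function(target, reference = NULL, k2p_fixed = NULL,
                      basis = NULL, ...) {
  stopifnot(inherits(target, "tac"))
  if (is.null(basis)) {
    if (is.null(reference) || is.null(k2p_fixed))
      stop("supply either a basis or reference + k2p_fixed", call. = FALSE)
    basis <- srtm2_basis(reference, k2p_fixed, ...)
  }
  check_pair(target, basis$reference)
  y <- target$values
  refv <- basis$reference$values
  k2p <- basis$k2p_fixed

  rss_amp <- function(x) {
    xx <- sum(x * x)
    if (xx == 0) return(list(r1 = 0, rss = sum(y * y)))
    r1 <- sum(x * y) / xx
    list(r1 = r1, rss = sum((y - r1 * x)^2))
  }
  grid <- basis$k2a_grid
  rss <- numeric(length(grid))
  for (j in seq_along(grid))
    rss[j] <- rss_amp(refv + (k2p - grid[j]) * basis$B[, j])$rss
  j <- which.min(rss)
  boundary <- j == 1L || j == length(grid)
  if (boundary)
    warning("SRTM2 optimum at the k2a grid boundary", call. = FALSE)

  obj <- function(log_k2a) {
    k2a <- 10^log_k2a
    rss_amp(refv + (k2p - k2a) * basis$basis_for(k2a))$rss
  }
  lo <- log10(grid[max(j - 1L, 1L)])
  hi <- log10(grid[min(j + 1L, length(grid))])
  log_opt <- if (hi > lo) golden_section(obj, lo, hi, tol = 1e-6)
             else log10(grid[j])
  k2a <- 10^log_opt
  best <- rss_amp(refv + (k2p - k2a) * basis$basis_for(k2a))

  structure(list(r1 = best$r1, k2a = k2a,
                 bp = best$r1 * k2p / k2a - 1,
                 k2p_fixed = k2p, rss = best$rss,
                 boundary = boundary),
            class = "srtm2_fit")
}

golden_section <- function(f, lo, hi, tol = 1e-6) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
  }
  (a + b) / 2
}

#' Estimate the population reference efflux rate k2'
#'
#' Runs [mrtm_fit()] per subject with the fused (volume-weighted, equal
#' weights by default) thalamus as the transporter-rich region and the
#' occipital reference region, and averages the per-subject k2' estimates.
#' Any failing subject aborts the estimate with its identity -- no silent
#' exclusion.
#'
#' @param cohort A `pet_cohort`, or a list of `tac_table`s (one per subject).
#' @param high_region Transporter-rich region label; if absent from the data
#'   it is fused from `merge_parts`.
#' @param merge_parts Regions fused into `high_region` when needed.
#' @param reference Reference region label.
#' @param t_star_min Fit window start (min).
#' @param t_end_min Model window end (min); TACs are truncated to it first.
#' @return Object of class `population_k2p`: list with `per_subject`
#'   (data frame `subject`, `k2p`, `bp`, `rss`, `cond`) and `mean`.
#' @export
estimate_population_k2p <- function(cohort,
                                    high_region = "thalamus_merged",
                                    merge_parts = c("thalamus_l", "thalamus_r"),
                                    reference = "occipital",
                                    t_star_min = 0,
                                    t_end_min = 90) {
  tabs <- cohort_tac_tables(cohort)
  per <- lapply(names(tabs), function(id) {
    tt <- tabs[[id]]
    if (!is.null(t_end_min) && t_end_min < total_duration_min(tac_schedule(tt)))
      tt <- truncate_to(tt, t_end_min)
    high <- if (high_region %in% tac_regions(tt)) tac_get(tt, high_region)
            else merge_regions(tt, merge_parts, name = high_region)
    fit <- tryCatch(
      mrtm_fit(high, tac_get(tt, reference), t_star_min = t_star_min),
      error = function(e)
        stop(sprintf("k2' estimation failed for subject '%s': %s",
                     id, conditionMessage(e)), call. = FALSE))
    data.frame(subject = id, k2p = fit$k2p, bp = fit$bp,
               rss = fit$rss, cond = fit$cond)
  })
  per <- do.call(rbind, per)
  structure(list(per_subject = per, mean = mean(per$k2p)),
            class = "population_k2p")
}

#' @export
print.population_k2p <- function(x, ...) {
  cat(sprintf("<population_k2p> mean k2' = %.4f 1/min (SD %.4f, n = %d)\n",
              x$mean, stats::sd(x$per_subject$k2p), nrow(x$per_subject)))
  invisible(x)
}

cohort_tac_tables <- function(cohort) {
  if (inherits(cohort, "pet_cohort")) {
    tabs <- lapply(cohort$subjects, `[[`, "tacs")
    names(tabs) <- vapply(cohort$subjects, `[[`, "", "id")
    return(tabs)
  }
  stopifnot(is.list(cohort), length(cohort) >= 1L)
  if (is.null(names(cohort)))
    names(cohort) <- sprintf("sub%02d", seq_along(cohort))
  cohort
}

#' Model-based binding potentials for every subject and region
#'
#' The full kinetic chain: TACs are truncated to the modeling window, the
#' population k2' is estimated by MRTM (unless a fixed value is supplied),
#' and MRTM2 and SRTM2 binding potentials are fitted for every analyzed
#' region.  The SRTM2 basis is computed once per subject and shared across
#' its regions.
#'
#' @inheritParams estimate_population_k2p
#' @param methods Which of `"MRTM2"`, `"SRTM2"` to fit.
#' @param k2p Either `"estimate"` (default) or a fixed positive value (1/min).
#' @param regions Regions to fit; default all except the reference and the
#'   fused-thalamus bookkeeping region.
#' @param t_star_min Fit window start for the multilinear fits (min).
#' @return List with `k2p` (the value used), `population` (a
#'   `population_k2p` or `NULL`) and `fits`, a data frame with columns
#'   `subject`, `region`, `method`, `bp`, `r1`, `k2a`, `k2p`, `rss`, `cond`,
#'   `boundary`.
#' @export
fit_cohort <- function(cohort, methods = c("MRTM2", "SRTM2"),
                       k2p = "estimate",
                       regions = NULL,
                       reference = "occipital",
                       t_star_min = 0,
                       t_end_min = 90) {
  methods <- match.arg(methods, c("MRTM2", "SRTM2"), several.ok = TRUE)
  tabs <- cohort_tac_tables(cohort)
  pop <- NULL
  if (identical(k2p, "estimate")) {
    pop <- estimate_population_k2p(cohort, reference = reference,
                                   t_star_min = t_star_min,
                                   t_end_min = t_end_min)
    k2p_val <- pop$mean
  } else {
    k2p_val <- as.numeric(k2p)
    if (!is.finite(k2p_val) || k2p_val <= 0)
      stop("k2p must be 'estimate' or a positive value", call. = FALSE)
  }

  rows <- list()
  for (id in names(tabs)) {
    tt <- tabs[[id]]
    if (!is.null(t_end_min) && t_end_min < total_duration_min(tac_schedule(tt)))
      tt <- truncate_to(tt, t_end_min)
    regs <- regions
    if (is.null(regs))
      regs <- setdiff(tac_regions(tt), c(reference, "thalamus_merged"))
    ref <- tac_get(tt, reference)
    basis <- if ("SRTM2" %in% methods) srtm2_basis(ref, k2p_val) else NULL
    for (r in regs) {
      tgt <- tac_get(tt, r)
      if ("MRTM2" %in% methods) {
        f <- mrtm2_fit(tgt, ref, k2p_val, t_star_min = t_star_min)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = id, region = r, method = "MRTM2", bp = f$bp, r1 = f$r1,
          k2a = f$k2a, k2p = k2p_val, rss = f$rss, cond = f$cond,
          boundary = FALSE)
      }
      if ("SRTM2" %in% methods) {
        f <- srtm2_fit(tgt, basis = basis)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = id, region = r, method = "SRTM2", bp = f$bp, r1 = f$r1,
          k2a = f$k2a, k2p = k2p_val, rss = f$rss, cond = NA_real_,
          boundary = f$boundary)
      }
    }
  }
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  list(k2p = k2p_val, population = pop, fits = fits)
}
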