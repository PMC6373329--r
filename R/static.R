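#' Static ratio binding potential
#'
#' The late-scan surrogate for model-based BPND:
#' `(mean VOI concentration - mean reference concentration) / mean reference
#' concentration`, computed over one static acquisition window.
#'
#' @param voi_mean Window-mean concentration(s) of the target VOI (kBq/mL);
#'   vectorized.
#' @param ref_mean Window-mean concentration of the reference region (kBq/mL),
#'   must be positive.
#' @return Unitless binding potential(s).
#' @export
static_bp <- function(voi_mean, ref_mean) {
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("reference window mean must be positive", call. = FALSE)
  (voi_mean - ref_mean) / ref_mean
}

#' Static binding potentials for every subject, region and window
#'
#' For each subject and each 30-min window start, extracts the window
#' (duration-weighted frame averaging) and computes the static ratio binding
#' potential of every region against the reference region's window mean.
#'
#' @param cohort A `pet_cohort` or a (named) list of `tac_table`s.
#' @param window_starts Window start times (min); each window must align to
#'   frame boundaries.
#' @param duration_min Window length (min).
#' @param reference Reference region label.
#' @return Data frame with columns `subject`, `region`, `window` (e.g.
#'   `"30-60"`), `bp`.
#' @export
static_bp_table <- function(cohort, window_starts = c(30, 40, 50, 60),
                            duration_min = 30, reference = "occipital") {
  tabs <- cohort_tac_tables(cohort)
  rows <- list()
  for (id in names(tabs)) {
    tt <- tabs[[id]]
    for (s in window_starts) {
      w <- extract_window(tt, s, duration_min)
      ref_mean <- w$mean_kbq_ml[w$region == reference]
      if (!length(ref_mean))
        stop(sprintf("reference region '%s' missing for subject '%s'",
                     reference, id), call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = id, region = w$region,
        window = sprintf("%g-%g", s, s + duration_min),
        bp = static_bp(w$mean_kbq_ml, ref_mean))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool left/right hemispheres of paired regions
#'
#' Averages the per-side binding values of `<group>_l` / `<group>_r` pairs
#' into one value per region group (pooling is done on binding potentials,
#' after per-side computation).  Unpaired regions pass through unchanged.
#'
#' @param df Data frame with a `region` column and a value column, plus any
#'   grouping columns (e.g. `subject`, `window`, `method`).
#' @param value_col Name of the value column to average.
#' @return Data frame like `df` with `region` replaced by the pooled group
#'   label.
#' @export
pool_hemispheres <- function(df, value_col = "bp") {
  stopifnot("region" %in% names(df), value_col %in% names(df))
  group <- sub("_(l|r)$", "", df$region)
  keys <- setdiff(names(df), c("region", value_col))
  agg <- stats::aggregate(df[[value_col]],
                          by = c(list(region = group),
                                 lapply(df[keys], identity)),
                          FUN = mean)
  names(agg)[names(agg) == "x"] <- value_col
  agg[, c(setdiff(names(df), value_col), value_col), drop = FALSE]
}
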