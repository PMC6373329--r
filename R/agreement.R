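#' Spearman rank correlation with large-sample p-value
#'
#' Rank-based correlation with average ranks for ties; the p-value comes from
#' the standard t approximation `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Equal-length finite numeric vectors, `n >= 3`.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Intraclass correlation for two-method agreement
#'
#' Two-way mixed-effects, single-measurement intraclass correlation between
#' two measurement columns of the same subjects.  The default absolute
#' agreement form ICC(A,1) is
#' `(MS_R - MS_E) / (MS_R + MS_E + (2/n)(MS_C - MS_E))`, where `MS_R`, `MS_C`
#' and `MS_E` are the row (subject), column (method) and error mean squares of
#' the two-way table; it penalizes systematic offsets between the methods.
#' The consistency form ICC(C,1), `(MS_R - MS_E) / (MS_R + MS_E)`, is also
#' available.
#'
#' @param x,y Paired measurements of the two methods, `n >= 3`.
#' @param variant `"A1"` (absolute agreement, default) or `"C1"` (consistency).
#' @return List with `icc`, `variant`, `n`, and the mean squares `msr`,
#'   `msc`, `mse`.
#' @export
icc_agreement <- function(x, y, variant = c("A1", "C1")) {
  variant <- match.arg(variant)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  m <- cbind(x, y)
  grand <- mean(m)
  if (sum((m - grand)^2) == 0)
    stop("undefined ICC: zero total variance", call. = FALSE)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  msr <- 2 * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / 1
  mse <- sum((m - outer(rowm, c(0, 0), "+") -
                rep(colm, each = n) + grand)^2) / (n - 1)
  icc <- switch(variant,
    A1 = (msr - mse) / (msr + mse + (2 / n) * (msc - mse)),
    C1 = (msr - mse) / (msr + mse))
  list(icc = icc, variant = variant, n = n, msr = msr, msc = msc, mse = mse)
}

#' Ordinary least-squares regression of static on model binding values
#'
#' Simple linear regression `y = slope * x + intercept` via [stats::lm()],
#' reporting the coefficient of determination and the two-sided p-value of
#' the slope.
#'
#' @param x Predictor (model-based BP, pooled points).
#' @param y Response (static BP, pooled points).
#' @return List with `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in x: slope undefined", call. = FALSE)
  if (stats::var(y) == 0)   # flat response: no slope, no explained variance
    return(list(slope = 0, intercept = y[1], r2 = 0, p = 1, n = length(x)))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- stats::coef(sm)
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r2 = sm$r.squared,
       p = unname(co["x", "Pr(>|t|)"]),
       n = length(x))
}

#' Significance stars at the conventional thresholds
#' @param p Numeric p-value(s).
#' @return `""`, `"*"` (p < 0.05), `"**"` (p < 0.01) or `"***"` (p < 0.001).
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", ""), right = FALSE) |> as.character()
}

#' Region-wise agreement tables and pooled regressions
#'
#' The method-comparison report: for every region, window and kinetic model,
#' the across-subject Spearman correlation and intraclass correlation between
#' static and model-based binding potentials (with means and SDs of both),
#' plus one pooled regression (all regions x subjects) per window x model.
#'
#' @param static_df Output of [static_bp_table()], hemispheres already pooled
#'   (see [pool_hemispheres()]); columns `subject`, `region`, `window`, `bp`.
#' @param model_df Pooled model fits; columns `subject`, `region`, `method`,
#'   `bp`.
#' @param icc_variant Passed to [icc_agreement()].
#' @return List with `agreement` (one row per region x window x model) and
#'   `regressions` (one row per window x model).
#' @export
build_agreement_tables <- function(static_df, model_df, icc_variant = "A1") {
  stopifnot(all(c("subject", "region", "window", "bp") %in% names(static_df)),
            all(c("subject", "region", "method", "bp") %in% names(model_df)))
  regions <- intersect(unique(model_df$region), unique(static_df$region))
  windows <- unique(static_df$window)
  methods <- unique(model_df$method)

  agree <- list()
  for (m in methods) for (w in windows) for (r in regions) {
    sd_ <- static_df[static_df$region == r & static_df$window == w, ]
    md_ <- model_df[model_df$region == r & model_df$method == m, ]
    j <- merge(sd_[, c("subject", "bp")], md_[, c("subject", "bp")],
               by = "subject", suffixes = c("_static", "_model"))
    if (nrow(j) < nrow(sd_) || nrow(j) < nrow(md_))
      stop(sprintf("join mismatch for region '%s' (%s, %s): missing subjects",
                   r, m, w), call. = FALSE)
    if (nrow(j) < 3L)
      stop(sprintf("region '%s': fewer than 3 paired subjects", r),
           call. = FALSE)
    sp <- spearman_rho(j$bp_model, j$bp_static)
    ic <- icc_agreement(j$bp_model, j$bp_static, variant = icc_variant)
    agree[[length(agree) + 1L]] <- data.frame(
      region = r, window = w, model = m, n = nrow(j),
      mean_model = mean(j$bp_model), sd_model = stats::sd(j$bp_model),
      mean_static = mean(j$bp_static), sd_static = stats::sd(j$bp_static),
      rho = sp$rho, rho_p = sp$p, stars = significance_stars(sp$p),
      icc = ic$icc)
  }

  regr <- list()
  for (m in methods) for (w in windows) {
    sd_ <- static_df[static_df$window == w & static_df$region %in% regions, ]
    md_ <- model_df[model_df$method == m & model_df$region %in% regions, ]
    j <- merge(sd_[, c("subject", "region", "bp")],
               md_[, c("subject", "region", "bp")],
               by = c("subject", "region"), suffixes = c("_static", "_model"))
    f <- ols_fit(j$bp_model, j$bp_static)
    regr[[length(regr) + 1L]] <- data.frame(
      window = w, model = m, slope = f$slope, intercept = f$intercept,
      r2 = f$r2, p = f$p, stars = significance_stars(f$p), n_points = f$n)
  }

  agree <- do.call(rbind, agree)
  regr <- do.call(rbind, regr)
  rownames(agree) <- rownames(regr) <- NULL
  list(agreement = agree, regressions = regr)
}
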