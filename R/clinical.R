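#' Read the packaged patient characteristics table
#'
#' Per-patient demographics and clinical scores of the 10-subject cohort the
#' package emulates: sex, age, disease duration (years), Hoehn-Yahr stage,
#' UPDRS-III motor score in the medication-off and -on state, and
#' levodopa-equivalent daily dose (mg).
#'
#' @param path Optional path to a CSV with the same columns; default the
#'   packaged fixture.
#' @return Data frame with columns `patient`, `sex`, `age_y`, `dd_y`, `hy`,
#'   `updrs3_off`, `updrs3_on`, `ledd_mg`.
#' @export
read_clinical <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pd_cohort_clinical.csv",
                        package = "refkin", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "sex", "age_y", "dd_y", "hy",
            "updrs3_off", "updrs3_on", "ledd_mg")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("clinical table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out
}

#' Correlations of regional binding with demographic and clinical variables
#'
#' Spearman correlation of a per-subject binding value (typically the pooled
#' thalamic BP) with age, disease duration, Hoehn-Yahr stage, UPDRS-III
#' (off state) and levodopa-equivalent daily dose, with multiplicity
#' adjustment across the variable family (Bonferroni by default).
#'
#' Subjects with a missing covariate are excluded pairwise for that variable,
#' with a warning.
#'
#' At these sample sizes (around 10 subjects, with heavily tied ordinal
#' covariates such as the Hoehn-Yahr stage) the large-sample t approximation
#' of the Spearman p-value is anti-conservative, so the default raw p-value
#' is a two-sided Monte-Carlo permutation p (with `n_perm` permutations of
#' the binding values, drawn from the caller's RNG stream); set
#' `p_method = "asymptotic"` for the t approximation.
#'
#' @param bp Numeric vector of per-subject binding values, aligned with the
#'   rows of `clinical`.
#' @param clinical Covariate data frame (see [read_clinical()]).
#' @param variables Covariate columns to test.
#' @param adjust Method for [stats::p.adjust()].
#' @param p_method `"permutation"` (default) or `"asymptotic"`.
#' @param n_perm Number of permutations for the permutation p-value.
#' @return Data frame with columns `variable`, `n`, `rho`, `p_raw`,
#'   `p_adjusted`.
#' @export
clinical_correlations <- function(bp, clinical,
                                  variables = c("age_y", "dd_y", "hy",
                                                "updrs3_off", "ledd_mg"),
                                  adjust = "bonferroni",
                                  p_method = c("permutation", "asymptotic"),
                                  n_perm = 9999L) {
  p_method <- match.arg(p_method)
  stopifnot(is.numeric(bp), nrow(clinical) == length(bp))
  miss <- setdiff(variables, names(clinical))
  if (length(miss))
    stop("covariates not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- lapply(variables, function(v) {
    xv <- clinical[[v]]
    ok <- is.finite(bp) & is.finite(xv)
    if (!all(ok))
      warning(sprintf("variable '%s': %d subject(s) excluded pairwise",
                      v, sum(!ok)), call. = FALSE)
    sp <- spearman_rho(bp[ok], xv[ok])
    p_raw <- if (p_method == "permutation")
      spearman_perm_p(bp[ok], xv[ok], n_perm) else sp$p
    data.frame(variable = v, n = sp$n, rho = sp$rho, p_raw = p_raw)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(stats::p.adjust(out$p_raw, method = adjust), 1)
  rownames(out) <- NULL
  out
}

# Two-sided Monte-Carlo permutation p-value for the Spearman correlation.
# Vectorized over permutations: rho is linear in the permuted rank vector
# once the covariate ranks are centered.
spearman_perm_p <- function(x, y, n_perm) {
  rx <- rank(x)
  ry <- rank(y) - mean(rank(y))
  obs <- abs(sum((rx - mean(rx)) * ry))
  perm <- matrix(rx[vapply(seq_len(n_perm), function(i) sample.int(length(rx)),
                           integer(length(rx)))], nrow = length(rx))
  stat <- abs(as.numeric(crossprod(perm, ry)))
  (1 + sum(stat >= obs - 1e-9)) / (n_perm + 1)
}
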