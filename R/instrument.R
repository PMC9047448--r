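#' Normalize lipid intensities to a reference lipid
#'
#' Cross-instrument comparison works on ratios: within each
#' (instrument, cell) profile every lipid intensity is divided by that
#' profile's intensity of the reference lipid (the most abundant
#' differentiating species, PC 34:1 by default in this workflow), so
#' the reference ratio is exactly 1 everywhere and absolute instrument
#' response cancels.
#'
#' @param profiles Data frame with columns `instrument`, `cell_id`,
#'   `lipid`, `intensity` (one row per lipid per cell per instrument).
#' @param reference Reference lipid name; must be present with non-zero
#'   intensity in every profile.
#' @return A `ratio_table`: the input with a `ratio` column and
#'   attributes `reference`, `instruments`, `lipids`.
#' @export
normalize_to_reference <- function(profiles, reference) {
  need <- c("instrument", "cell_id", "lipid", "intensity")
  if (!all(need %in% names(profiles))) {
    stop(sprintf("profiles must have columns %s", paste(need, collapse = ",")))
  }
  if (any(profiles$intensity < 0)) stop("intensities must be non-negative")
  key <- paste(profiles$instrument, profiles$cell_id, sep = "\r")
  out <- lapply(split(profiles, factor(key, levels = unique(key))),
                function(d) {
    ref <- d$intensity[d$lipid == reference]
    if (length(ref) != 1 || ref == 0) {
      stop(sprintf(
        "reference lipid %s absent or zero in profile (%s, %s)",
        reference, d$instrument[1], d$cell_id[1]))
    }
    d$ratio <- d$intensity / ref
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("ratio_table", "data.frame"),
            reference = reference,
            instruments = sort(unique(out$instrument)),
            lipids = sort(unique(out$lipid)))
}

#' Upper-tail critical value of the F distribution
#'
#' The critical value a one-way ANOVA F statistic is compared against:
#' the upper-`alpha` quantile of the F distribution with `df1` and
#' `df2` degrees of freedom. With 6 instruments of 3 replicates each
#' (df 5, 12) and alpha 0.05 this is 3.106 (3 d.p.).
#'
#' @param alpha Upper-tail probability in (0, 1).
#' @param df1,df2 Degrees of freedom (>= 1).
#' @return The critical value.
#' @export
f_critical <- function(alpha, df1, df2) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1")
  stats::qf(alpha, df1, df2, lower.tail = FALSE)
}

#' Per-lipid one-way ANOVA across instruments
#'
#' For every non-reference lipid, a single-factor analysis of variance
#' of its ratios with instrument as the factor:
#' `F = between-instrument mean square / within-instrument mean square`,
#' compared against [f_critical()] at `alpha`. `F` below the critical
#' value means no significant instrument effect on that lipid ratio.
#' Verdicts are per lipid against the single critical value; an
#' optional Bonferroni correction divides `alpha` by the number of
#' lipids tested.
#'
#' @param table A `ratio_table` from [normalize_to_reference()].
#' @param alpha Significance level (default 0.05).
#' @param bonferroni If `TRUE`, divide `alpha` by the number of lipids.
#' @return An `anova_report` data frame: `lipid`, `F`, `df_between`,
#'   `df_within`, `critical_F`, `significant`. Zero within-group
#'   variance with non-zero between-group variance reports `F = Inf`.
#' @export
anova_per_lipid <- function(table, alpha = 0.05, bonferroni = FALSE) {
  stopifnot(inherits(table, "ratio_table"))
  reference <- attr(table, "reference")
  lipids <- setdiff(attr(table, "lipids"), reference)
  instruments <- attr(table, "instruments")
  if (length(instruments) < 2) stop("need at least 2 instruments")
  alpha_eff <- if (bonferroni) alpha / length(lipids) else alpha
  rows <- lapply(lipids, function(lp) {
    d <- table[table$lipid == lp, ]
    groups <- split(d$ratio, d$instrument)
    if (any(lengths(groups) < 2)) {
      stop(sprintf("lipid %s: need >= 2 replicates per instrument", lp))
    }
    k <- length(groups)
    n <- length(d$ratio)
    grand <- mean(d$ratio)
    ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                      numeric(1)))
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
    msb <- ssb / (k - 1)
    msw <- ssw / (n - k)
    f <- if (msw == 0) {
      if (msb == 0) 0 else Inf
    } else {
      msb / msw
    }
    data.frame(lipid = lp, F = f, df_between = k - 1, df_within = n - k,
               critical_F = f_critical(alpha_eff, k - 1, n - k),
               significant = NA, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$F >= out$critical_F
  structure(out, class = c("anova_report", "data.frame"),
            alpha = alpha, bonferroni = bonferroni, reference = reference)
}
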