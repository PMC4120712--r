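#' Bland-Altman agreement between two paired diameter series
#'
#' Computes the mean and SD (n-1 denominator) of the paired differences
#' `d = a - b`, limits of agreement at `mean +/- loa_multiplier * SD`, the
#' coefficient of determination of the ordinary least-squares fit of `b`
#' on `a`, and a paired two-sided t-test of zero mean difference. The
#' difference direction is reference-minus-algorithm when `a` is the
#' reference series. The default multiplier is 2 SDs; set
#' `loa_multiplier = 1.96` for the conventional normal-quantile limits.
#'
#' @param a Reference measurements (cm).
#' @param b Comparison measurements (cm), same length (>= 3).
#' @param loa_multiplier SD multiplier for the limits of agreement.
#' @return Object of class `agreement_stats` with fields `n`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `r_squared`, `r`, `t_statistic`,
#'   `p_value`, `loa_multiplier`, `degenerate` (TRUE when the differences
#'   have zero variance, in which case the limits collapse to the mean and
#'   the t-test p-value is undefined).
#' @export
bland_altman <- function(a, b, loa_multiplier = 2) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("paired series differ in length (", length(a), " vs ", length(b),
         ")", call. = FALSE)
  }
  if (length(a) < 3L) stop("need at least 3 pairs", call. = FALSE)

  d <- a - b
  md <- mean(d)
  sdd <- sd(d)
  degenerate <- !is.finite(sdd) || sdd == 0

  r <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  # identical series are perfect agreement even though the OLS fit of b on
  # a is then only defined when a varies
  r2 <- if (all(a == b)) 1 else r^2

  tt <- if (degenerate) {
    list(statistic = NA_real_, p.value = NA_real_)
  } else {
    t.test(a, b, paired = TRUE)
  }

  structure(
    list(n = length(a), mean_diff = md, sd_diff = sdd,
         loa_low = md - loa_multiplier * sdd,
         loa_high = md + loa_multiplier * sdd,
         r_squared = r2, r = r,
         t_statistic = unname(tt$statistic), p_value = tt$p.value,
         loa_multiplier = loa_multiplier, degenerate = degenerate),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> n = %d\n", x$n))
  cat(sprintf("  mean diff %.3f cm, SD %.3f cm\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  LoA (mean +/- %g SD): [%.3f, %.3f] cm\n",
              x$loa_multiplier, x$loa_low, x$loa_high))
  cat(sprintf("  R^2 = %.4f (r = %.4f), paired t = %.3f, p = %.3g\n",
              x$r_squared, x$r, x$t_statistic, x$p_value))
  invisible(x)
}

#' Size-stratified agreement summary
#'
#' Partitions paired measurements into three clinically motivated size
#' groups by the reference value — `d <= bounds[1]`,
#' `bounds[1] < d <= bounds[2]` and `d > bounds[2]` (default cuts 3 and
#' 5 cm, the staging limits separating small, intermediate and large
#' lesions) — and computes [bland_altman()] statistics per group. Groups
#' with fewer than 3 pairs are reported with `n` and `NULL` statistics.
#'
#' @param reference Reference diameters (cm).
#' @param measured Algorithm diameters (cm), same length.
#' @param bounds Ascending numeric length-2 group bounds in cm.
#' @param loa_multiplier Passed to [bland_altman()].
#' @return Named list of three elements (`"d<=3cm"`-style names) each with
#'   fields `n`, `indices` and `stats` (an `agreement_stats` or `NULL`).
#' @export
group_summary <- function(reference, measured, bounds = c(3, 5),
                          loa_multiplier = 2) {
  if (length(reference) != length(measured)) {
    stop("paired series differ in length", call. = FALSE)
  }
  if (length(bounds) != 2L || diff(bounds) <= 0) {
    stop("bounds must be two ascending values", call. = FALSE)
  }
  groups <- list()
  cuts <- list(
    reference <= bounds[1],
    reference > bounds[1] & reference <= bounds[2],
    reference > bounds[2]
  )
  names(cuts) <- c(sprintf("d<=%gcm", bounds[1]),
                   sprintf("%g<d<=%gcm", bounds[1], bounds[2]),
                   sprintf("d>%gcm", bounds[2]))
  for (nm in names(cuts)) {
    idx <- which(cuts[[nm]])
    st <- if (length(idx) >= 3L) {
      bland_altman(reference[idx], measured[idx],
                   loa_multiplier = loa_multiplier)
    } else NULL
    groups[[nm]] <- list(n = length(idx), indices = idx, stats = st)
  }
  groups
}

#' Agreement report as a JSON-ready list
#'
#' Flattens overall and per-group agreement statistics into plain lists
#' for serialization.
#'
#' @inheritParams group_summary
#' @param path Optional output path; when given, JSON is written there.
#' @return The report list, invisibly when written to file.
#' @export
agreement_report <- function(reference, measured, bounds = c(3, 5),
                             loa_multiplier = 2, path = NULL) {
  flatten <- function(st) {
    if (is.null(st)) return(NULL)
    st[c("n", "mean_diff", "sd_diff", "loa_low", "loa_high",
         "r_squared", "r", "t_statistic", "p_value")]
  }
  rep <- list(
    overall = flatten(bland_altman(reference, measured,
                                   loa_multiplier = loa_multiplier)),
    groups = lapply(group_summary(reference, measured, bounds,
                                  loa_multiplier),
                    function(g) c(list(n = g$n), flatten(g$stats)))
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(rep))
  }
  rep
}
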