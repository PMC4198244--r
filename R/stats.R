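#' Wilcoxon--Mann--Whitney rank-sum test
#'
#' Two-sided rank-sum test reporting W as the sum of the pooled ranks of
#' the first sample (midranks under ties), so that at n = m = 20 complete
#' separation in favour of the first sample attains W = 610 (the rank sum
#' of ranks 21--40) and the attainable range is 210--610. The p-value uses
#' exact enumeration when the pooled sample is small (n + m <= 20) and
#' untied, otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y nonempty numeric samples; `x` is the first-listed group.
#' @return List: `W` (rank sum of x), `U` (Mann--Whitney statistic),
#'   `p`, `exact` (logical), `n`, `m`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 1 || length(y) < 1)
    stop("both samples must be nonempty", call. = FALSE)
  n <- length(x); m <- length(y)
  ranks <- rank(c(x, y))
  W <- sum(ranks[seq_len(n)])
  ties <- any(duplicated(c(x, y)))
  exact <- (n + m) <= 20 && !ties
  if (stats::var(ranks) == 0) {  # every observation tied: no separation
    p <- 1
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    p <- ht$p.value
  }
  list(W = W, U = W - n * (n + 1) / 2, p = p, exact = exact,
       n = n, m = m)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test; the Welch--Satterthwaite degrees of freedom are
#' kept at full precision internally and additionally reported rounded down
#' to an integer for display.
#'
#' @param x,y numeric samples of size >= 2.
#' @param pooled force the pooled (equal-variance) test instead.
#' @return List: `T`, `df`, `df_display`, `p`.
#' @export
welch_t <- function(x, y, pooled = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs >= 2 observations", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero variance in both samples", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = pooled)
  list(T = unname(ht$statistic), df = unname(ht$parameter),
       df_display = floor(unname(ht$parameter)), p = ht$p.value)
}

#' Kruskal--Wallis test across groups
#'
#' Standard tie-corrected H statistic with `length(groups) - 1` degrees of
#' freedom and a chi-square p-value.
#'
#' @param groups list of >= 2 nonempty numeric samples.
#' @return List: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("need >= 2 nonempty groups", call. = FALSE)
  if (length(unique(unlist(groups))) == 1)  # no rank variation at all
    return(list(H = 0, df = length(groups) - 1, p = 1))
  ht <- stats::kruskal.test(groups)
  list(H = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Sequential Bonferroni (Holm step-down) correction
#'
#' P-values are ranked in order of significance and compared in turn to
#' increasingly stringent critical values `alpha / (k - i + 1)`; once a
#' comparison fails, all larger p-values are declared non-significant.
#' Thresholds are compared at full precision but also reported truncated to
#' three decimals for display (for alpha = 0.05 and k = 4: 0.050, 0.025,
#' 0.016, 0.012).
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param alpha familywise significance level in (0, 1).
#' @return data.frame in the input order: `p`, `rank`, `critical`,
#'   `critical_display`, `significant`.
#' @export
sequential_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  k <- length(p_values)
  ord <- order(p_values)
  crit <- alpha / (k - seq_len(k) + 1)
  sig_sorted <- logical(k)
  ok <- TRUE
  for (i in seq_len(k)) {
    ok <- ok && (p_values[ord[i]] <= crit[i])
    sig_sorted[i] <- ok
  }
  out <- data.frame(p = p_values, rank = NA_integer_, critical = NA_real_,
                    critical_display = NA_real_, significant = NA)
  out$rank[ord] <- seq_len(k)
  out$critical[ord] <- crit
  out$critical_display <- trunc(out$critical * 1000) / 1000
  out$significant[ord] <- sig_sorted
  out
}

#' Planned between-background comparisons per time point
#'
#' The pre-specified test battery for one appearance metric: at every time
#' point, a two-sided between-background comparison (Wilcoxon rank-sum for
#' saturation, luminance and the JND metrics, which are typically
#' non-normal; Welch t for hue), with the time points' p-values jointly
#' corrected by sequential Bonferroni.
#'
#' @param records data.frame of per-fish records with columns `background`,
#'   `time_min` and the metric column.
#' @param metric column name: one of saturation, hue, luminance,
#'   chromatic_jnd, achromatic_jnd.
#' @param alpha familywise level.
#' @param first_background which background forms the first (x) sample;
#'   default the first level encountered in the records.
#' @return data.frame, one row per time point: test used, statistic, df
#'   (t only), p, critical threshold (display-truncated), significance.
#' @export
planned_comparisons <- function(records, metric, alpha = 0.05,
                                first_background = NULL) {
  stopifnot(metric %in% names(records))
  bgs <- unique(records$background)
  if (length(bgs) != 2)
    stop("records must contain exactly two backgrounds", call. = FALSE)
  if (is.null(first_background)) first_background <- bgs[1]
  second <- setdiff(bgs, first_background)
  times <- sort(unique(records$time_min))
  use_t <- metric == "hue"
  rows <- lapply(times, function(tp) {
    x <- records[records$background == first_background &
                   records$time_min == tp, metric]
    y <- records[records$background == second &
                   records$time_min == tp, metric]
    if (length(x) == 0 || length(y) == 0)
      stop(sprintf("missing records at time %s", tp), call. = FALSE)
    if (use_t) {
      r <- welch_t(x, y)
      data.frame(metric = metric, time_min = tp, test = "welch_t",
                 statistic = r$T, df = r$df_display, p = r$p)
    } else {
      r <- wilcoxon_rank_sum(x, y)
      data.frame(metric = metric, time_min = tp, test = "wilcoxon",
                 statistic = r$W, df = NA_real_, p = r$p)
    }
  })
  out <- do.call(rbind, rows)
  adj <- sequential_bonferroni(out$p, alpha)
  out$critical_threshold <- adj$critical_display
  out$significant <- adj$significant
  out
}

#' Camouflage change over time (Kruskal--Wallis)
#'
#' Tests whether the level of background match (chromatic or achromatic
#' JND) of the fish on one background differs across the time points.
#'
#' @param records per-fish records with `background`, `time_min` and the
#'   JND columns.
#' @param background background label to test.
#' @param jnd_kind "chromatic" or "achromatic".
#' @return data.frame row: H, df, p.
#' @export
camouflage_trend <- function(records, background,
                             jnd_kind = c("chromatic", "achromatic")) {
  jnd_kind <- match.arg(jnd_kind)
  col <- paste0(jnd_kind, "_jnd")
  stopifnot(col %in% names(records))
  sub <- records[records$background == background, ]
  times <- sort(unique(records$time_min))
  groups <- lapply(times, function(tp) sub[sub$time_min == tp, col])
  if (any(lengths(groups) == 0))
    stop(sprintf("missing time-point group for background %s", background),
         call. = FALSE)
  r <- kruskal_wallis(groups)
  data.frame(background = background, jnd = jnd_kind,
             H = r$H, df = r$df, p = r$p,
             significant = r$p <= 0.05)
}
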