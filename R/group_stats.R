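#' Paired Student's t-test between two support conditions
#'
#' Two-sided paired t-test on index-paired samples, the comparison used for
#' every no-support versus maximal-support contrast. The statistic is
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences `d = x - y`,
#' referred to Student's t distribution with `n - 1` degrees of freedom.
#' Zero-variance differences are flagged degenerate: p is reported as 1 when
#' the mean difference is also zero and as 0 (the limiting bound) otherwise.
#'
#' @param x,y Equal-length numeric vectors (n >= 2), paired by index.
#' @param metric_name Optional label carried into the result.
#' @return A `paired_htest` object; use [tidy()] or [glance()] for a tibble
#'   with `metric_name`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t_stat`, `df`,
#'   `p_two_sided`, `n`, `degenerate`.
#' @export
paired_ttest <- function(x, y, metric_name = "metric") {
  if (length(x) != length(y)) {
    abort(sprintf("x and y must have equal length (got %d and %d)",
                  length(x), length(y)),
          class = "corohemo_param_error")
  }
  n <- length(x)
  if (n < 2L) abort("need at least 2 pairs", class = "corohemo_param_error")
  if (anyNA(x) || anyNA(y)) {
    abort("missing values are not allowed", class = "corohemo_param_error")
  }
  d <- x - y
  degenerate <- sd(d) == 0
  if (degenerate) {
    if (mean(d) == 0) {
      t_stat <- 0
      p <- 1
    } else {
      t_stat <- sign(mean(d)) * Inf
      p <- 0
    }
  } else {
    ht <- stats::t.test(x, y, paired = TRUE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(
    list(metric_name = metric_name,
         mean_a = mean(x), sd_a = sd(x), mean_b = mean(y), sd_b = sd(y),
         t_stat = t_stat, df = n - 1L, p_two_sided = p, n = n,
         degenerate = degenerate),
    class = "paired_htest"
  )
}

#' @export
print.paired_htest <- function(x, ...) {
  cat(sprintf("Paired t-test [%s]: %.4g +/- %.4g vs %.4g +/- %.4g (n = %d)\n",
              x$metric_name, x$mean_a, x$sd_a, x$mean_b, x$sd_b, x$n))
  cat(sprintf("  t = %.4g, df = %d, two-sided p = %.4g%s\n", x$t_stat, x$df,
              x$p_two_sided, if (x$degenerate) " (degenerate: zero-variance differences)" else ""))
  invisible(x)
}

#' @rdname paired_ttest
#' @param x A `paired_htest`.
#' @param ... Unused.
#' @method tidy paired_htest
#' @export
tidy.paired_htest <- function(x, ...) {
  tibble::tibble(metric_name = x$metric_name,
                 mean_a = x$mean_a, sd_a = x$sd_a,
                 mean_b = x$mean_b, sd_b = x$sd_b,
                 t_stat = x$t_stat, df = x$df,
                 p_two_sided = x$p_two_sided, n = x$n,
                 degenerate = x$degenerate)
}

#' @rdname paired_ttest
#' @method glance paired_htest
#' @export
glance.paired_htest <- function(x, ...) tidy.paired_htest(x)

#' Mean and sample standard deviation
#'
#' Continuous variables are summarized as mean plus/minus SD with the
#' sample (n - 1 denominator) standard deviation.
#'
#' @param values Numeric vector, n >= 2.
#' @return A one-row tibble: `mean`, `sd`, `n`.
#' @export
msd_summary <- function(values) {
  if (length(values) < 2L) {
    abort("need at least 2 values for a mean +/- SD summary",
          class = "corohemo_param_error")
  }
  tibble::tibble(mean = mean(values), sd = sd(values), n = length(values))
}

#' Paired comparison of per-subject metrics across two conditions
#'
#' Takes a long tibble of per-subject metric values under two protocol
#' conditions and produces, per metric, a mean-SD summary of each condition
#' and the paired t-test between them — the layout of the study's
#' LV-parameter table (condition A = no support, condition B = maximal
#' support).
#'
#' @param metrics A tibble with columns `subject`, `condition`, `metric`,
#'   `value` (long format; use [tidyr::pivot_longer()] on a wide metric
#'   table).
#' @param conditions Length-2 character vector naming the reference and
#'   comparison condition (default `c("P0", "P8")`).
#' @return A tibble with one row per metric: `metric`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `t_stat`, `df`, `p_value`, `n`, `degenerate`, where
#'   `a`/`b` are `conditions[1]`/`conditions[2]`.
#' @export
compare_conditions <- function(metrics, conditions = c("P0", "P8")) {
  req <- c("subject", "condition", "metric", "value")
  if (!all(req %in% names(metrics))) {
    abort(sprintf("metrics must have columns %s", paste(req, collapse = ", ")),
          class = "corohemo_param_error")
  }
  if (length(conditions) != 2L) {
    abort("conditions must name exactly two conditions",
          class = "corohemo_param_error")
  }
  a <- dplyr::filter(metrics, .data$condition == conditions[1L])
  b <- dplyr::filter(metrics, .data$condition == conditions[2L])
  purrr::map_dfr(sort(unique(metrics$metric)), function(m) {
    ma <- dplyr::arrange(dplyr::filter(a, .data$metric == m), .data$subject)
    mb <- dplyr::arrange(dplyr::filter(b, .data$metric == m), .data$subject)
    missing_b <- setdiff(ma$subject, mb$subject)
    missing_a <- setdiff(mb$subject, ma$subject)
    if (length(missing_a) || length(missing_b)) {
      abort(sprintf(
        "subject mismatch for metric '%s': missing in %s: %s", m,
        paste0(c(rep(conditions[1L], length(missing_a) > 0),
                 rep(conditions[2L], length(missing_b) > 0)), collapse = "/"),
        paste(c(missing_a, missing_b), collapse = ", ")),
        class = "corohemo_param_error")
    }
    if (anyDuplicated(ma$subject) || anyDuplicated(mb$subject)) {
      abort(sprintf("duplicate subject rows for metric '%s'", m),
            class = "corohemo_param_error")
    }
    ht <- paired_ttest(ma$value, mb$value, metric_name = m)
    tibble::tibble(metric = m, mean_a = ht$mean_a, sd_a = ht$sd_a,
                   mean_b = ht$mean_b, sd_b = ht$sd_b, t_stat = ht$t_stat,
                   df = ht$df, p_value = ht$p_two_sided, n = ht$n,
                   degenerate = ht$degenerate)
  })
}

#' Write a condition-comparison table as TSV
#'
#' @param comparison Output of [compare_conditions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(comparison, path) {
  readr::write_tsv(comparison, path)
  invisible(path)
}
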