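#' Two-sample t test (Welch by default)
#'
#' Thin wrapper around [stats::t.test()] returning a flat result record.
#' Welch's unequal-variance form is the default; the pooled Student form is
#' available via `var_equal = TRUE`. When both samples are constant with
#' equal means the test is vacuous and `p = 1` (`t = 0`) by convention;
#' constant samples with different means give `p = 0`.
#'
#' @param x,y numeric samples, each of length >= 2, finite.
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return List of class `t_test_result`: `t`, `df`, `p_two_sided`,
#'   `mean_x`, `mean_y`, `sd_x`, `sd_y`, `n_x`, `n_y`, `method`.
#' @export
welch_t_test <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("samples must be finite", call. = FALSE)
  base <- list(mean_x = mean(x), mean_y = mean(y),
               sd_x = stats::sd(x), sd_y = stats::sd(y),
               n_x = length(x), n_y = length(y),
               method = if (var_equal) "student" else "welch")
  res <- if (base$sd_x == 0 && base$sd_y == 0) {
    if (base$mean_x == base$mean_y) list(t = 0, df = length(x) + length(y) - 2,
                                         p_two_sided = 1)
    else list(t = sign(base$mean_x - base$mean_y) * Inf,
              df = length(x) + length(y) - 2, p_two_sided = 0)
  } else {
    tt <- stats::t.test(x, y, var.equal = var_equal)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p_two_sided = tt$p.value)
  }
  structure(c(res, base), class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t test: t = %.4f, df = %.2f, two-sided P = %.4g\n",
              if (x$method == "welch") "Welch" else "Student",
              x$t, x$df, x$p_two_sided))
  cat(sprintf("  group x: mean %.4g (sd %.4g, n %d); group y: mean %.4g (sd %.4g, n %d)\n",
              x$mean_x, x$sd_x, x$n_x, x$mean_y, x$sd_y, x$n_y))
  invisible(x)
}

#' Significance code for a P value
#'
#' `***` for P < 0.001, `**` for P < 0.01, `*` for P < 0.05, else `ns`.
#'
#' @param p P value(s) in \[0, 1\].
#' @return Character vector of codes.
#' @export
signif_code <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Compare a phenotype between two groups
#'
#' Summarises two cohorts (e.g. symbiotic vs. aposymbiotic redness indices,
#' or dry body weights) with a two-sample t test and a significance code.
#'
#' @param group_a,group_b numeric vectors, or lists of `redness_result`
#'   objects (their `index` fields are used).
#' @param label phenotype name for the report row.
#' @param var_equal passed to [welch_t_test()].
#' @return One-row data.frame: label, per-group n / mean / sd, `t`, `df`,
#'   `p`, `code`.
#' @export
compare_phenotypes <- function(group_a, group_b, label = "phenotype",
                               var_equal = FALSE) {
  as_values <- function(g) {
    if (is.numeric(g)) return(g)
    vapply(g, function(el) {
      if (inherits(el, "redness_result")) el$index
      else stop("groups must be numeric or lists of redness_result",
                call. = FALSE)
    }, numeric(1))
  }
  a <- as_values(group_a); b <- as_values(group_b)
  tt <- welch_t_test(a, b, var_equal = var_equal)
  data.frame(
    label = label,
    n_a = tt$n_x, mean_a = tt$mean_x, sd_a = tt$sd_x,
    n_b = tt$n_y, mean_b = tt$mean_y, sd_b = tt$sd_y,
    t = tt$t, df = tt$df, p = tt$p_two_sided,
    code = signif_code(tt$p_two_sided)
  )
}
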