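#' Compare a composition metric between two groups of animals
#'
#' Unpaired, two-tailed Student t-test with pooled (equal) variance on any
#' per-animal composition column, the conventional test for two-group
#' contrasts of per-animal percentages. Degenerate inputs are handled explicitly: zero pooled
#' variance with equal means gives t = 0, p = 1; zero pooled variance with
#' unequal means is flagged degenerate with p at the smallest positive
#' double.
#'
#' @param data Stacked per-animal composition tibble (rows = animals) with a
#'   grouping column.
#' @param metric Composition column to compare (tidy-eval, e.g.
#'   `mononuclear_pct`).
#' @param group Grouping column with exactly two levels (e.g. `strain`).
#' @return An object of class `ploidy_ttest`; see [tidy.ploidy_ttest()].
#' @examples
#' comps <- dplyr::bind_rows(
#'   tibble::tibble(strain = "A", mononuclear_pct = c(4, 5, 6)),
#'   tibble::tibble(strain = "B", mononuclear_pct = c(1, 2, 3)))
#' compare_groups(comps, mononuclear_pct, strain)
#' @export
compare_groups <- function(data, metric, group) {
  metric <- rlang::enquo(metric)
  group <- rlang::enquo(group)
  x <- rlang::eval_tidy(metric, data)
  g <- rlang::eval_tidy(group, data)
  lev <- unique(g)
  if (length(lev) != 2) abort("`group` must have exactly two levels")
  a <- x[g == lev[1]]
  b <- x[g == lev[2]]
  if (length(a) < 2 || length(b) < 2) abort("need n >= 2 animals per group")
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  degenerate <- FALSE
  if (sp2 == 0) {
    if (mean(a) == mean(b)) {
      tstat <- 0; p <- 1
    } else {
      tstat <- sign(mean(a) - mean(b)) * Inf
      p <- .Machine$double.xmin
      degenerate <- TRUE
      warn("zero pooled variance with unequal means; p-value degenerate")
    }
  } else {
    tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tstat), df)
    p <- max(p, .Machine$double.xmin)
  }
  structure(
    list(metric = rlang::as_label(metric), groups = as.character(lev),
         mean = c(mean(a), mean(b)), sd = c(sd(a), sd(b)), n = c(n1, n2),
         statistic = tstat, df = df, p.value = p, degenerate = degenerate),
    class = "ploidy_ttest"
  )
}

#' @export
print.ploidy_ttest <- function(x, ...) {
  cat("Two-group comparison of", x$metric, "(Student t, pooled variance)\n")
  for (i in 1:2) {
    cat(sprintf("  %s: mean %.2f, sd %.2f, n %d\n",
                x$groups[i], x$mean[i], x$sd[i], x$n[i]))
  }
  cat(sprintf("  t = %.3f, df = %d, two-tailed p = %.3g%s\n",
              x$statistic, x$df, x$p.value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Tidy a two-group ploidy comparison
#'
#' @param x A `ploidy_ttest` from [compare_groups()].
#' @param ... Unused.
#' @return A one-row tibble with group means/SDs/n, `estimate` (difference
#'   of means), `statistic`, `df` and `p.value`.
#' @method tidy ploidy_ttest
#' @export
tidy.ploidy_ttest <- function(x, ...) {
  tibble(metric = x$metric,
         group1 = x$groups[1], group2 = x$groups[2],
         mean1 = x$mean[1], mean2 = x$mean[2],
         sd1 = x$sd[1], sd2 = x$sd[2], n1 = x$n[1], n2 = x$n[2],
         estimate = x$mean[1] - x$mean[2],
         statistic = x$statistic, df = x$df, p.value = x$p.value,
         degenerate = x$degenerate)
}

#' @rdname tidy.ploidy_ttest
#' @method glance ploidy_ttest
#' @export
glance.ploidy_ttest <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         degenerate = x$degenerate)
}
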