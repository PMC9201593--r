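#' Bonferroni-corrected pairwise group comparisons
#'
#' Welch (unequal-variance) two-sample t-tests between two groups,
#' computed separately within each level of a splitting factor (e.g.
#' frequency band or layer pair), with Bonferroni correction over the
#' comparison family.
#'
#' @param data long data.frame.
#' @param value name of the numeric value column.
#' @param group name of the two-level grouping column.
#' @param split name of the factor column defining the comparisons
#'   (one test per level).
#' @param m size of the Bonferroni family; defaults to the number of
#'   comparisons actually made, but can be set to match a wider family
#'   (e.g. 7 bands, 9 layer pairs).
#' @return data.frame of class `"group_comparisons"`: one row per level
#'   with group means and SDs, `t`, `df`, `p_raw`,
#'   `p_adjusted = min(1, p_raw * m)`, and `m`.
#' @export
pairwise_band_tests <- function(data, value = "value", group = "group",
                                split = "band", m = NULL) {
  stopifnot(is.data.frame(data),
            all(c(value, group, split) %in% names(data)))
  g <- factor(data[[group]])
  stop_if(nlevels(g) != 2L, "grouping column must have exactly 2 levels (got %d)",
          nlevels(g))
  lv <- unique(data[[split]])
  m <- m %||% length(lv)
  rows <- lapply(lv, function(l) {
    sel <- data[[split]] == l
    x <- data[[value]][sel & g == levels(g)[1]]
    y <- data[[value]][sel & g == levels(g)[2]]
    stop_if(length(x) < 2L || length(y) < 2L,
            "need >= 2 observations per group in '%s'", l)
    stop_if(stats::sd(x) == 0 && stats::sd(y) == 0,
            "degenerate (zero) variance in both groups in '%s'", l)
    tt <- stats::t.test(x, y)
    data.frame(level = as.character(l),
               mean_1 = mean(x), sd_1 = stats::sd(x),
               mean_2 = mean(y), sd_2 = stats::sd(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_adjusted = min(1, tt$p.value * m), m = m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- levels(g)
  class(out) <- c("group_comparisons", "data.frame")
  out
}

#' @export
print.group_comparisons <- function(x, ...) {
  gr <- attr(x, "groups")
  cat(sprintf("Welch t-tests, %s vs %s, Bonferroni m = %d\n",
              gr[1], gr[2], x$m[1]))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
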