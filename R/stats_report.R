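#' Significance stars for a p value
#'
#' `*` for p < 0.05, `**` for p < 0.01, `***` for p < 0.001 and `****`
#' for p < 0.0001; `"ns"` otherwise.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return Character vector of star annotations.
#' @export
p_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Percent change between two group means
#'
#' `100 * (x - ref) / ref`; negative values are reductions. The
#' estimator is invariant to rescaling both groups.
#'
#' @param ref reference (e.g. WT) mean.
#' @param x comparison (e.g. Tau35) mean.
#' @return Percent change.
#' @export
percent_change <- function(ref, x) {
  if (ref == 0) stop("reference mean is zero; percent change undefined")
  100 * (x - ref) / ref
}

#' Unpaired two-tailed Student t test with SEM summary
#'
#' Classic pooled-variance two-sample t test (two-sided). When both
#' groups are constant and equal, `p = 1` by convention.
#'
#' @param a,b numeric vectors (each with at least 2 values).
#' @param label optional metric label carried into the result.
#' @return An object of class `tauhcn_test`: `statistic`, `df`, `p`,
#'   `means`, `sems`, `ns` and `stars`.
#' @export
group_t_test <- function(a, b, label = NULL) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 finite values")
  df_tot <- length(a) + length(b) - 2L
  if (isTRUE(all.equal(stats::var(a), 0)) &&
      isTRUE(all.equal(stats::var(b), 0))) {
    # degenerate: both groups (essentially) constant
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    tt <- list(statistic = c(t = if (eq) 0 else Inf),
               parameter = c(df = df_tot),
               p.value = if (eq) 1 else 0)
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 means = c(mean(a), mean(b)), sems = c(sem(a), sem(b)),
                 ns = c(length(a), length(b)),
                 stars = p_stars(tt$p.value), label = label),
            class = "tauhcn_test")
}

#' @export
print.tauhcn_test <- function(x, ...) {
  cat(sprintf("<t test%s> t(%0.4g) = %.3f, p = %.3g %s\n",
              if (is.null(x$label)) "" else paste0(": ", x$label),
              x$df, x$statistic, x$p, x$stars))
  cat(sprintf("  means +/- SEM: %.4g +/- %.3g (n=%d) vs %.4g +/- %.3g (n=%d)\n",
              x$means[1L], x$sems[1L], x$ns[1L],
              x$means[2L], x$sems[2L], x$ns[2L]))
  invisible(x)
}

#' Two-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Fits `metric ~ f1 * f2`, reports Type II sums-of-squares F tests for
#' both main effects and the interaction (robust to unbalanced designs),
#' and Tukey HSD pairwise comparisons across the factor-combination cell
#' means.
#'
#' @param table data.frame holding the metric and the two factors.
#' @param factors character vector of the two factor column names.
#' @param metric name of the numeric metric column.
#' @return A list with `anova` (data.frame: `term`, `F`, `df`, `p`,
#'   `stars`) and `tukey` (data.frame of pairwise cell comparisons:
#'   `contrast`, `diff`, `lwr`, `upr`, `p_adj`, `stars`).
#' @export
anova2_tukey <- function(table, factors, metric) {
  stopifnot(length(factors) == 2L, all(factors %in% names(table)),
            metric %in% names(table))
  df <- data.frame(y = table[[metric]],
                   f1 = factor(table[[factors[1L]]]),
                   f2 = factor(table[[factors[2L]]]))
  df <- df[is.finite(df$y), , drop = FALSE]
  if (nlevels(droplevels(df$f1)) < 2L || nlevels(droplevels(df$f2)) < 2L)
    stop("each factor needs at least 2 observed levels")
  cells <- table(df$f1, df$f2)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s",
                 factors[1L], rownames(cells)[bad[1L]],
                 factors[2L], colnames(cells)[bad[2L]]))
  }
  fit <- stats::lm(y ~ f1 * f2, data = df)
  a2 <- car::Anova(fit, type = 2)
  terms <- rownames(a2)
  keep <- terms != "Residuals"
  res_df <- a2[terms == "Residuals", "Df"]
  out <- data.frame(term = c(factors, paste(factors, collapse = ":")),
                    F = a2[keep, "F value"],
                    df1 = a2[keep, "Df"], df2 = res_df,
                    p = a2[keep, "Pr(>F)"])
  out$stars <- p_stars(out$p)

  # Tukey HSD on the cell means of the crossed design
  tk <- stats::TukeyHSD(stats::aov(y ~ interaction(f1, f2), data = df))[[1L]]
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  tukey$stars <- p_stars(tukey$p_adj)
  list(anova = out, tukey = tukey)
}
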