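#' Compare metric values across conditions
#'
#' One-way or two-way ANOVA with all pairwise Tukey HSD comparisons on the
#' condition factor. The two-way design crosses condition with a second
#' factor (e.g. actin state for state-fraction data), including the
#' interaction.
#'
#' @param data Data frame.
#' @param value Name of the numeric response column.
#' @param group Name of the condition column.
#' @param group2 Name of the second factor column (two-way design only).
#' @param design `"oneway"` or `"twoway"`.
#' @return List with `design`, `anova` (tibble: `term`, `df`, `statistic`,
#'   `p_value`) and `tukey` (tibble of pairwise condition contrasts with
#'   Tukey-adjusted p values).
#' @export
compare_groups <- function(data, value, group, group2 = NULL,
                           design = c("oneway", "twoway")) {
  design <- match.arg(design)
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  g <- factor(data[[group]])
  y <- data[[value]]
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2))
    stop("degenerate input: group(s) with n < 2: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  df <- data.frame(y = y, g = g)
  if (design == "twoway") {
    if (is.null(group2) || !group2 %in% names(data))
      stop("twoway design needs group2", call. = FALSE)
    df$g2 <- factor(data[[group2]])
    fit <- stats::aov(y ~ g * g2, data = df)
  } else {
    fit <- stats::aov(y ~ g, data = df)
  }
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  keep <- terms != "Residuals"
  label <- c(g = group, g2 = group2 %||% "g2")
  pretty <- vapply(terms[keep], function(t) {
    for (k in names(label)) t <- gsub(paste0("\\b", k, "\\b"), label[[k]], t)
    t
  }, character(1))
  anova_tbl <- tibble::tibble(
    term = unname(pretty),
    df = an$Df[keep],
    statistic = an$`F value`[keep],
    p_value = an$`Pr(>F)`[keep]
  )
  tk <- stats::TukeyHSD(fit, which = "g")$g
  tukey_tbl <- tibble::tibble(
    contrast = rownames(tk),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  list(design = design, anova = anova_tbl, tukey = tukey_tbl)
}

#' Ordinary least-squares regression with r-squared
#'
#' @param x,y Numeric vectors (`n >= 3`); `x` must not be constant.
#' @return List of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided slope t test), `n`.
#' @export
regress <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0)
    stop("x is constant; slope undefined", call. = FALSE)
  if (stats::var(y) == 0) {
    return(structure(list(slope = 0, intercept = y[1], r_squared = 0,
                          p_value = NA_real_, n = length(x)),
                     class = "regression_result"))
  }
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = s$r.squared,
    p_value = s$coefficients[2, 4],
    n = length(x)
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression> slope %.4g, intercept %.4g, r^2 = %.4f, p = %.3g, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Group mean and SEM summaries
#'
#' @param data Data frame.
#' @param value,group Column names of the response and grouping variable.
#' @param metric Label stored in the `metric` column.
#' @return Tibble with `condition`, `metric`, `mean`, `sem`, `n`.
#' @export
group_summary <- function(data, value, group, metric = value) {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  sp <- split(data[[value]], data[[group]])
  tibble::tibble(
    condition = names(sp),
    metric = metric,
    mean = unname(vapply(sp, mean, numeric(1))),
    sem = unname(vapply(sp, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1))),
    n = unname(vapply(sp, length, integer(1)))
  )
}
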