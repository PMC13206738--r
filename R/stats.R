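#' Significance tiers
#'
#' Maps p-values to the conventional three-star annotation: `*` for p < 0.05,
#' `**` for p < 0.01, `***` for p < 0.001, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    is.na(p) ~ NA_character_,
    TRUE ~ "ns"
  )
}

#' Two-group t-test on a tidy table
#'
#' Two-tailed t-test between the two groups of `group`, pooled-variance
#' ("student") by default with Welch available by flag.
#'
#' @param data A data frame with one measurement per row.
#' @param value Measurement column (tidy-eval).
#' @param group Grouping column with exactly two levels (tidy-eval).
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return A one-row tibble: `contrast`, `statistic`, `df`, `p_value`,
#'   `p_adjusted` (`NA`; no multiplicity here), `tier`, `variant`.
#' @export
t_test_groups <- function(data, value, group, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  lv <- unique(g)
  if (length(lv) != 2L) stop("t_test_groups needs exactly two groups", call. = FALSE)
  a <- v[g == lv[1]]
  b <- v[g == lv[2]]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(c(a, b)))) stop("values must be finite", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = variant == "student")
  tibble::tibble(
    contrast = paste(lv[1], "-", lv[2]),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    p_adjusted = NA_real_,
    tier = significance_tier(ht$p.value),
    variant = variant
  )
}

#' One-way ANOVA with post hoc Tukey HSD
#'
#' Fits a one-way ANOVA across all groups and follows it with Tukey's honest
#' significant difference comparison of every pair, using the studentized
#' range distribution with the pooled within-group variance. A warning is
#' logged (not an error) when the largest-to-smallest group variance ratio
#' exceeds 10.
#'
#' @inheritParams t_test_groups
#' @return An object of class `anova_tukey` with [tidy.anova_tukey()] and
#'   [glance.anova_tukey()] methods; printing shows the ANOVA row and the
#'   pairwise table.
#' @export
anova_tukey <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(as.character(dplyr::pull(data, {{ group }})))
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  ns <- table(g)
  if (any(ns < 2L)) stop("each group needs at least 2 values", call. = FALSE)
  if (any(!is.finite(v))) stop("values must be finite", call. = FALSE)
  vars <- tapply(v, g, stats::var)
  if (max(vars) / max(min(vars), .Machine$double.eps) > 10) {
    warning("group variance ratio exceeds 10; ANOVA homogeneity assumption ",
            "is doubtful", call. = FALSE)
  }
  fit <- stats::aov(v ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  sig2 <- an["Residuals", "Mean Sq"]
  df_resid <- an["Residuals", "Df"]
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  n_by <- as.numeric(ns)
  names(n_by) <- levels(g)
  se <- sqrt(sig2 / 2 *
               (1 / n_by[vapply(pairs, `[`, "", 1)] +
                1 / n_by[vapply(pairs, `[`, "", 2)]))
  contrasts <- tibble::tibble(
    group1 = vapply(pairs, `[`, "", 1),
    group2 = vapply(pairs, `[`, "", 2),
    contrast = rownames(tk),
    diff = unname(tk[, "diff"]),
    statistic = unname(tk[, "diff"] / (se * sqrt(2))),  # q/sqrt(2), t-scale
    df = df_resid,
    p_adjusted = unname(tk[, "p adj"]),
    tier = significance_tier(unname(tk[, "p adj"]))
  )
  structure(
    list(
      anova = tibble::tibble(
        statistic = an["g", "F value"], df1 = an["g", "Df"], df2 = df_resid,
        p_value = an["g", "Pr(>F)"], n_groups = nlevels(g), n_total = length(v)
      ),
      contrasts = contrasts,
      fit = fit
    ),
    class = "anova_tukey"
  )
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$statistic, x$anova$p_value))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$contrasts, ...)
  invisible(x)
}

#' Tidy the pairwise Tukey table
#'
#' @param x An `anova_tukey` object.
#' @param ... Unused.
#' @return The pairwise contrast tibble.
#' @export
tidy.anova_tukey <- function(x, ...) x$contrasts

#' One-row ANOVA summary
#'
#' @param x An `anova_tukey` object.
#' @param ... Unused.
#' @return A one-row tibble with the F statistic, degrees of freedom and p.
#' @export
glance.anova_tukey <- function(x, ...) x$anova

#' Generic tidy/glance (broom-compatible)
#'
#' Thin generics so `tidy()`/`glance()` work without attaching broom; if broom
#' is attached its generics are used instead.
#' @param x Object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Cohort-level comparison report
#'
#' Summarizes a per-eye measurement table (from [quantify_cohort()] or a
#' QuantResult CSV) by dye x time group — n, mean, SD and SEM are all
#' reported because a bare "±" is ambiguous — and runs the group comparisons:
#' a one-way ANOVA + Tukey HSD across dyes within each time point, and a
#' pooled-variance t-test between time points within each dye.
#'
#' @param data Per-eye tibble with `dye_label`, `time_h` and the response.
#' @param response Response column (tidy-eval), default `area_percent`.
#' @param t_variant Passed to [t_test_groups()].
#' @return A `cohort_report`: list with `summary` (per-group tibble),
#'   `dye_contrasts` (Tukey tibble with a `time_h` column), `time_contrasts`
#'   (t-test tibble with a `dye_label` column) and `anova` (per-time ANOVA
#'   rows). Single-group inputs yield empty contrast tables, not errors.
#' @export
cohort_report <- function(data, response = area_percent,
                          t_variant = c("student", "welch")) {
  t_variant <- match.arg(t_variant)
  need <- c("dye_label", "time_h")
  if (!all(need %in% names(data))) {
    stop("data must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- dplyr::mutate(data, .resp = {{ response }})
  df <- dplyr::filter(df, is.finite(.data$.resp))
  summary_tbl <- df |>
    dplyr::group_by(.data$dye_label, .data$time_h) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$.resp),
      sd = stats::sd(.data$.resp),
      sem = stats::sd(.data$.resp) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  dye_contrasts <- list()
  anova_rows <- list()
  for (t_h in sort(unique(df$time_h))) {
    sub <- dplyr::filter(df, .data$time_h == t_h)
    ok <- sub |> dplyr::count(.data$dye_label) |> dplyr::filter(.data$n >= 2)
    sub <- dplyr::filter(sub, .data$dye_label %in% ok$dye_label)
    if (dplyr::n_distinct(sub$dye_label) >= 2) {
      at <- anova_tukey(sub, .data$.resp, .data$dye_label)
      dye_contrasts[[as.character(t_h)]] <-
        dplyr::mutate(tidy(at), time_h = t_h, .before = 1)
      anova_rows[[as.character(t_h)]] <-
        dplyr::mutate(glance(at), time_h = t_h, .before = 1)
    }
  }
  time_contrasts <- list()
  if (dplyr::n_distinct(df$time_h) == 2) {
    for (dl in unique(df$dye_label)) {
      sub <- dplyr::filter(df, .data$dye_label == dl)
      if (dplyr::n_distinct(sub$time_h) == 2 &&
          all(table(sub$time_h) >= 2)) {
        time_contrasts[[dl]] <- dplyr::mutate(
          t_test_groups(sub, .data$.resp, .data$time_h, variant = t_variant),
          dye_label = dl, .before = 1
        )
      }
    }
  }
  structure(
    list(summary = summary_tbl,
         dye_contrasts = dplyr::bind_rows(dye_contrasts),
         time_contrasts = dplyr::bind_rows(time_contrasts),
         anova = dplyr::bind_rows(anova_rows)),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Group summary (mean, SD, SEM per dye x time):\n")
  print(x$summary, ...)
  if (nrow(x$dye_contrasts)) {
    cat("\nCross-dye Tukey HSD contrasts (per time point):\n")
    print(x$dye_contrasts, ...)
  }
  if (nrow(x$time_contrasts)) {
    cat("\nWithin-dye time contrasts (t-test):\n")
    print(x$time_contrasts, ...)
  }
  invisible(x)
}
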