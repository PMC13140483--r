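#' Normality gate with log transform
#'
#' Shapiro-Wilk tests of the within-cell residuals (values minus their
#' group-by-time cell mean) for one outcome. If any cell rejects at `alpha`,
#' the outcome is natural-log transformed (requiring strictly positive
#' values) and re-tested; the decision is recorded. Constant cells are
#' flagged as untestable, not transformed.
#'
#' @param table Long study table with columns `subject`, `group`, `time`,
#'   `outcome`, `value`.
#' @param outcome Outcome name to gate.
#' @param alpha Rejection level for the per-cell Shapiro-Wilk tests.
#' @return A list: `table` (the input with `value` transformed when needed),
#'   `transform_applied` (`"none"` or `"log"`), and `shapiro`, a tibble of
#'   per-cell p values before (and, when transformed, after) the transform.
#' @export
normality_gate <- function(table, outcome, alpha = 0.05) {
  dat <- dplyr::filter(table, .data$outcome == !!outcome)
  if (!nrow(dat)) stop("outcome not found: ", outcome, call. = FALSE)
  cell_p <- function(d) {
    d |>
      dplyr::group_by(.data$group, .data$time) |>
      dplyr::summarise(
        n = dplyr::n(),
        p = {
          r <- .data$value - mean(.data$value)
          if (dplyr::n() < 3 || stats::sd(r) == 0) NA_real_
          else stats::shapiro.test(r)$p.value
        },
        .groups = "drop"
      )
  }
  before <- cell_p(dat) |> dplyr::mutate(stage = "raw")
  testable <- !is.na(before$p)
  if (!any(testable)) {
    warning("normality untestable in every cell (constant or tiny cells); no transform applied",
            call. = FALSE)
    return(list(table = table, transform_applied = "none", shapiro = before))
  }
  if (all(before$p[testable] >= alpha)) {
    return(list(table = table, transform_applied = "none", shapiro = before))
  }
  bad <- dat$value <= 0
  if (any(bad)) {
    stop("transform error: log transform needs positive values; offending rows: ",
         paste(utils::head(which(bad), 10), collapse = ", "), call. = FALSE)
  }
  dat_t <- dplyr::mutate(dat, value = log(.data$value))
  after <- cell_p(dat_t) |> dplyr::mutate(stage = "log")
  new_table <- table |>
    dplyr::mutate(value = ifelse(.data$outcome == !!outcome,
                                 log(.data$value), .data$value))
  list(table = new_table, transform_applied = "log",
       shapiro = dplyr::bind_rows(before, after))
}

# complete cases for one outcome: subjects observed at all three times
complete_cases <- function(table, outcome) {
  dat <- table |>
    dplyr::filter(.data$outcome == !!outcome) |>
    dplyr::mutate(time = factor(as.character(.data$time),
                                levels = c("baseline", "30", "60")),
                  group = factor(.data$group),
                  subject = as.character(.data$subject))
  if (anyNA(dat$time)) {
    stop("time labels must be baseline, 30, 60", call. = FALSE)
  }
  keep <- dat |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::count(.data$subject) |>
    dplyr::filter(.data$n == 3) |>
    dplyr::pull(.data$subject)
  dat |>
    dplyr::filter(.data$subject %in% keep, !is.na(.data$value)) |>
    dplyr::mutate(subject = factor(.data$subject))
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# repeated measures
gg_epsilon <- function(wide, group) {
  mats <- split(as.data.frame(wide), group)
  S <- Reduce(`+`, lapply(mats, function(m) {
    stats::cov(as.matrix(m)) * (nrow(m) - 1)
  })) / (nrow(wide) - length(mats))
  k <- ncol(S)
  Cmat <- diag(k) - 1 / k
  Sc <- Cmat %*% S %*% Cmat
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' Two-group by three-time mixed repeated-measures ANOVA
#'
#' The mixed-design partition for one outcome of a long study table:
#' the between-subject effect (group) is tested against the subject-within-
#' group stratum, the within-subject effects (time and group-by-time) against
#' the subject-by-time residual. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error_for_that_stratum)` per effect.
#' Sphericity is not assumed away: the Greenhouse-Geisser epsilon is
#' estimated from the pooled within-group covariance and a corrected p value
#' is reported alongside the uncorrected one for the within-subject effects.
#'
#' Only complete cases (subjects observed at all three times) enter the
#' model, applied per outcome.
#'
#' @param table Long study table (`subject`, `group`, `time`, `outcome`,
#'   `value`); `time` must be `baseline`, `30`, `60`.
#' @param outcome Outcome name to analyse.
#' @return An object of class `rm_anova`; see [tidy.rm_anova()] and
#'   [glance.rm_anova()].
#' @export
#' @examples
#' cm <- tidyr::crossing(group = c("YA", "MA"), time = c("baseline", "30", "60")) |>
#'   dplyr::mutate(outcome = "y", mean = ifelse(group == "YA" & time != "baseline", 1, 0),
#'                 sd = 1)
#' tab <- simulate_cohort(cm, n_per_group = 12, seed = 7)
#' tidy(rm_anova(tab, "y"))
rm_anova <- function(table, outcome) {
  dat <- complete_cases(table, outcome)
  n_by_group <- dat |>
    dplyr::distinct(.data$subject, .data$group) |>
    dplyr::count(.data$group)
  if (nrow(n_by_group) != 2) {
    stop("exactly 2 groups required, got ", nrow(n_by_group), call. = FALSE)
  }
  if (any(n_by_group$n < 2)) {
    stop("insufficient data: each group needs at least 2 complete subjects",
         call. = FALSE)
  }
  fit <- stats::aov(value ~ group * time + Error(subject), data = dat)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  rn <- function(df) trimws(rownames(df))
  ss <- function(df, term) df[rn(df) == term, "Sum Sq"]
  dfree <- function(df, term) df[rn(df) == term, "Df"]

  ss_group <- ss(between, "group"); df_group <- dfree(between, "group")
  ss_subj <- ss(between, "Residuals"); df_subj <- dfree(between, "Residuals")
  ss_time <- ss(within, "time"); df_time <- dfree(within, "time")
  ss_gxt <- ss(within, "group:time"); df_gxt <- dfree(within, "group:time")
  ss_res <- ss(within, "Residuals"); df_res <- dfree(within, "Residuals")

  wide <- dat |>
    dplyr::select("subject", "group", "time", "value") |>
    tidyr::pivot_wider(names_from = "time", values_from = "value")
  eps <- gg_epsilon(as.matrix(wide[, c("baseline", "30", "60")]), wide$group)

  eff <- tibble::tibble(
    effect = c("group", "time", "group:time"),
    df = c(df_group, df_time, df_gxt),
    df_error = c(df_subj, df_res, df_res),
    ss = c(ss_group, ss_time, ss_gxt),
    ss_error = c(ss_subj, ss_res, ss_res)
  ) |>
    dplyr::mutate(
      statistic = (.data$ss / .data$df) / (.data$ss_error / .data$df_error),
      p.value = stats::pf(.data$statistic, .data$df, .data$df_error,
                          lower.tail = FALSE),
      partial_eta_sq = .data$ss / (.data$ss + .data$ss_error),
      gg_epsilon = c(NA, eps, eps),
      p_gg = dplyr::if_else(
        .data$effect == "group", .data$p.value,
        stats::pf(.data$statistic, .data$df * eps, .data$df_error * eps,
                  lower.tail = FALSE))
    )
  structure(
    list(effects = eff, data = dat, outcome = outcome,
         n_per_group = stats::setNames(n_by_group$n,
                                       as.character(n_by_group$group)),
         gg_epsilon = eps, fit = fit),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("<rm_anova>", x$outcome, "| n =",
      paste(names(x$n_per_group), x$n_per_group, collapse = ", "), "\n")
  print(x$effects)
  invisible(x)
}

#' Tidy a repeated-measures ANOVA fit
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per effect (`group`, `time`, `group:time`):
#'   degrees of freedom, sums of squares, F `statistic`, `p.value`,
#'   `partial_eta_sq`, Greenhouse-Geisser `gg_epsilon` and `p_gg`.
#' @export
tidy.rm_anova <- function(x, ...) x$effects

#' One-row summary of a repeated-measures ANOVA fit
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return A one-row tibble: outcome, per-group complete-case counts,
#'   interaction p, Greenhouse-Geisser epsilon.
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    n_group1 = x$n_per_group[[1]],
    n_group2 = x$n_per_group[[2]],
    p_interaction = x$effects$p.value[x$effects$effect == "group:time"],
    gg_epsilon = x$gg_epsilon
  )
}

#' Bonferroni-corrected post hoc pairwise tests
#'
#' Families follow the 2x3 design: `time_within_group` runs the three paired
#' time contrasts separately within each group (m = 3 per group),
#' `group_within_time` runs the between-group Welch test at each time
#' (m = 3), and `time_overall` runs the three paired time contrasts pooling
#' both groups (m = 3). Adjusted p values are `min(1, m * p_raw)`.
#'
#' @param table Long study table.
#' @param outcome Outcome to test.
#' @param which Family definition.
#' @return Tibble: `family`, `stratum`, `contrast`, `mean_diff`, `p_raw`,
#'   `m`, `p_adjusted`, `note` (zero-variance contrasts are flagged with an
#'   `NA` p value).
#' @export
bonferroni_posthoc <- function(table, outcome,
                               which = c("time_within_group",
                                         "group_within_time",
                                         "time_overall")) {
  which <- match.arg(which)
  dat <- complete_cases(table, outcome)
  times <- levels(dat$time)
  pairs <- utils::combn(times, 2, simplify = FALSE)

  paired_contrast <- function(d, t1, t2) {
    w <- d |>
      dplyr::select("subject", "time", "value") |>
      tidyr::pivot_wider(names_from = "time", values_from = "value")
    diffs <- w[[t2]] - w[[t1]]
    if (stats::sd(diffs) == 0) {
      return(tibble::tibble(mean_diff = mean(diffs), p_raw = NA_real_,
                            note = "zero-variance contrast"))
    }
    tt <- stats::t.test(w[[t2]], w[[t1]], paired = TRUE)
    tibble::tibble(mean_diff = unname(tt$estimate), p_raw = tt$p.value,
                   note = NA_character_)
  }

  rows <- switch(
    which,
    time_within_group = purrr::map_dfr(levels(dat$group), function(g) {
      d <- dat[dat$group == g, ]
      purrr::map_dfr(pairs, function(pr) {
        paired_contrast(d, pr[1], pr[2]) |>
          dplyr::mutate(stratum = g,
                        contrast = paste(pr[2], "-", pr[1]), m = 3L)
      })
    }),
    group_within_time = purrr::map_dfr(times, function(tt) {
      d <- dat[dat$time == tt, ]
      g <- levels(dat$group)
      x <- d$value[d$group == g[1]]
      y <- d$value[d$group == g[2]]
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        tibble::tibble(mean_diff = mean(x) - mean(y), p_raw = NA_real_,
                       note = "zero-variance contrast", stratum = tt,
                       contrast = paste(g[1], "-", g[2]), m = 3L)
      } else {
        ht <- stats::t.test(x, y) # Welch
        tibble::tibble(mean_diff = unname(diff(rev(ht$estimate))),
                       p_raw = ht$p.value, note = NA_character_, stratum = tt,
                       contrast = paste(g[1], "-", g[2]), m = 3L)
      }
    }),
    time_overall = purrr::map_dfr(pairs, function(pr) {
      paired_contrast(dat, pr[1], pr[2]) |>
        dplyr::mutate(stratum = "all",
                      contrast = paste(pr[2], "-", pr[1]), m = 3L)
    })
  )
  rows |>
    dplyr::mutate(family = which,
                  p_adjusted = pmin(1, .data$m * .data$p_raw)) |>
    dplyr::select("family", "stratum", "contrast", "mean_diff", "p_raw", "m",
                  "p_adjusted", "note")
}

#' Baseline group comparisons
#'
#' Welch two-sample t tests for continuous variables and chi-squared tests
#' (without continuity correction) for categorical variables, one row per
#' variable.
#'
#' @param data Data frame with one row per subject, a grouping column and any
#'   number of descriptive variables (numeric = continuous, anything else =
#'   categorical).
#' @param group Name of the grouping column (two groups).
#' @return Tibble: `variable`, `type`, `statistic` (t or X-squared), `df`,
#'   `p.value`, `note`.
#' @export
describe_groups <- function(data, group = "group") {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  vars <- setdiff(names(data), group)
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      if (stats::sd(x[g == levels(g)[1]]) == 0 &&
          stats::sd(x[g == levels(g)[2]]) == 0 &&
          mean(x[g == levels(g)[1]]) == mean(x[g == levels(g)[2]])) {
        return(tibble::tibble(variable = v, type = "continuous", statistic = 0,
                              df = NA_real_, p.value = 1, note = "identical groups"))
      }
      ht <- stats::t.test(x ~ g)
      tibble::tibble(variable = v, type = "continuous",
                     statistic = unname(ht$statistic),
                     df = unname(ht$parameter), p.value = ht$p.value,
                     note = NA_character_)
    } else {
      tab <- table(g, x)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected == 0)) {
        return(tibble::tibble(variable = v, type = "categorical",
                              statistic = NA_real_, df = NA_real_,
                              p.value = NA_real_,
                              note = "chi-squared undefined: expected cell count 0"))
      }
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      tibble::tibble(variable = v, type = "categorical",
                     statistic = unname(ht$statistic),
                     df = unname(ht$parameter), p.value = ht$p.value,
                     note = NA_character_)
    }
  })
}
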