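test_that("normality gate leaves normal data untransformed most of the time", {
  hits <- sapply(1:40, function(i) {
    tab <- simulate_cohort(cohort_grid(rep(10, 6), rep(1, 6)), 20, 0.3,
                           seed = 1000 + i)
    suppressWarnings(normality_gate(tab, "y")$transform_applied)
  })
  # per-replicate false-transform probability is 1 - 0.95^6 (6 cells); even
  # doubling it, fewer than half of 40 replicates should transform
  expect_gte(sum(hits == "none"), 20)
})

test_that("log-normal data are detected and transformed successfully", {
  tab <- simulate_cohort(cohort_grid(rep(1, 6), rep(0.8, 6)), 25, 0.3,
                         seed = 17) |>
    dplyr::mutate(value = exp(value))
  res <- normality_gate(tab, "y")
  expect_equal(res$transform_applied, "log")
  post <- res$shapiro[res$shapiro$stage == "log", ]
  # exactly normal after the transform: most cells should clear the gate
  expect_gte(sum(post$p > 0.05), 4)
  expect_true(all(post$p > 1e-3))
  expect_equal(res$table$value, log(tab$value))
})

test_that("constant cells are flagged untestable, not transformed", {
  tab <- simulate_cohort(cohort_grid(rep(5, 6), rep(0, 6)), 10, seed = 2)
  expect_warning(res <- normality_gate(tab, "y"), "untestable")
  expect_equal(res$transform_applied, "none")
})

test_that("non-positive values block the log transform with row numbers", {
  tab <- simulate_cohort(cohort_grid(rep(0, 6), rep(1, 6)), 15, seed = 4) |>
    dplyr::mutate(value = value^3) # heavy-tailed, non-normal, signed
  expect_error(normality_gate(tab, "y"), "transform error")
})

test_that("rm-ANOVA matches the brute-force sums-of-squares oracle", {
  for (seed in 1:20) {
    tab <- random_study_table(seed, n_ya = sample(3:6, 1), n_ma = sample(3:6, 1))
    fit <- rm_anova(tab, "y")
    orc <- ss_oracle(tab)
    eff <- tidy(fit)
    expect_equal(eff$statistic, unname(orc$F), tolerance = 1e-8)
    expect_equal(eff$p.value, unname(orc$p), tolerance = 1e-8)
    expect_equal(eff$partial_eta_sq, unname(orc$eta), tolerance = 1e-8)
  }
})

test_that("sums of squares partition the total exactly", {
  tab <- random_study_table(77, n_ya = 5, n_ma = 4)
  fit <- rm_anova(tab, "y")
  eff <- tidy(fit)
  ss_parts <- sum(eff$ss) + # group, time, gxt
    eff$ss_error[eff$effect == "group"] + # subject(group)
    eff$ss_error[eff$effect == "time"] # within residual
  y <- fit$data$value
  expect_equal(ss_parts, sum((y - mean(y))^2), tolerance = 1e-8)
})

test_that("identical group means with subject offsets give F_group = 0", {
  base <- tidyr::crossing(subject = sprintf("s%02d", 1:8),
                          time = c("baseline", "30", "60"))
  # subject offsets only, same offset pattern in both groups, no time structure
  tab <- base |>
    dplyr::mutate(group = ifelse(subject %in% sprintf("s%02d", 1:4), "YA", "MA"),
                  outcome = "y",
                  value = 10 + rep(c(-1, 0, 1, 2), 2)[match(
                    subject, sprintf("s%02d", 1:8))])
  fit <- rm_anova(tab, "y")
  eff <- tidy(fit)
  expect_equal(eff$statistic[eff$effect == "group"], 0, tolerance = 1e-12)
  expect_equal(eff$ss[eff$effect == "time"], 0, tolerance = 1e-12)
})

test_that("partial eta squared stays in [0, 1] and is 0 iff SS is 0", {
  for (seed in c(5, 6)) {
    fit <- rm_anova(random_study_table(seed), "y")
    eff <- tidy(fit)
    expect_true(all(eff$partial_eta_sq >= 0 & eff$partial_eta_sq <= 1))
    expect_equal(eff$partial_eta_sq == 0, eff$ss == 0)
  }
})

test_that("Greenhouse-Geisser epsilon lies in its theoretical range", {
  for (seed in c(9, 10, 11)) {
    fit <- rm_anova(random_study_table(seed, 6, 6), "y")
    expect_gte(fit$gg_epsilon, 0.5) # lower bound 1/(k-1) for k = 3
    expect_lte(fit$gg_epsilon, 1 + 1e-12)
  }
})

test_that("complete-case filtering drops subjects with missing times", {
  tab <- random_study_table(13, 5, 5)
  tab$value[tab$subject == "ya1" & tab$time == "30"] <- NA
  fit <- rm_anova(tab, "y")
  expect_equal(unname(fit$n_per_group["YA"]), 4)
  tiny <- tab[tab$subject %in% c("ya1", "ya2", "ma1", "ma2"), ]
  expect_error(rm_anova(tiny, "y"), "insufficient data")
})

test_that("Bonferroni adjustment multiplies and caps", {
  tab <- random_study_table(19, 5, 5)
  ph <- bonferroni_posthoc(tab, "y", "time_within_group")
  expect_equal(nrow(ph), 6) # 3 contrasts x 2 groups
  expect_equal(ph$p_adjusted, pmin(1, 3 * ph$p_raw))
  ph2 <- bonferroni_posthoc(tab, "y", "group_within_time")
  expect_equal(nrow(ph2), 3)
  expect_equal(ph2$p_adjusted, pmin(1, 3 * ph2$p_raw))
})

test_that("zero-variance contrasts are flagged with undefined p", {
  tab <- tidyr::crossing(subject = sprintf("s%d", 1:6),
                         time = c("baseline", "30", "60")) |>
    dplyr::mutate(group = ifelse(subject %in% sprintf("s%d", 1:3), "YA", "MA"),
                  outcome = "y", value = 5)
  ph <- bonferroni_posthoc(tab, "y", "time_within_group")
  expect_true(all(is.na(ph$p_raw)))
  expect_true(all(ph$note == "zero-variance contrast"))
})

test_that("a young-only time effect is flagged within YA by the post hocs", {
  hits <- sapply(1:10, function(i) {
    cm <- cohort_grid(means = c(0, 0, 0, 0, 0, 0), sds = rep(1, 6))
    cm$mean[cm$group == "YA" & cm$time != "baseline"] <- 1.5
    tab <- simulate_cohort(cm, n_per_group = 20,
                           within_subject_correlation = 0.6, seed = 400 + i)
    ya <- bonferroni_posthoc(tab, "y", "time_within_group") |>
      dplyr::filter(stratum == "YA", grepl("baseline", contrast))
    all(ya$p_adjusted < 0.05)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("group descriptives use Welch t and the classical chi-square", {
  d <- tibble::tibble(group = rep(c("YA", "MA"), each = 10),
                      age = c(rnorm(10, 24, 3), rnorm(10, 55, 3)),
                      sex = rep(c("F", "M"), 10))
  res <- describe_groups(d)
  expect_equal(res$type, c("continuous", "categorical"))

  # identical groups -> t = 0, p = 1
  same <- tibble::tibble(group = rep(c("A", "B"), each = 5), x = rep(1:5, 2))
  rs <- describe_groups(same)
  expect_equal(rs$statistic, 0)
  expect_equal(rs$p.value, 1)

  # 2x2 sex-by-group table (12, 9 / 13, 7) against the closed form
  counts <- tibble::tibble(
    group = c(rep("YA", 21), rep("MA", 20)),
    sex = c(rep("F", 12), rep("M", 9), rep("F", 13), rep("M", 7))
  )
  res2 <- describe_groups(counts)
  tab <- table(factor(counts$group), counts$sex)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2_hand <- sum((tab - expected)^2 / expected)
  expect_equal(res2$statistic, x2_hand, tolerance = 1e-8)
})

test_that("the Welch t p value agrees with a permutation test", {
  withr::with_seed(50, {
    x <- rnorm(12, 0, 1)
    y <- rnorm(10, 1, 1)
    d <- tibble::tibble(group = rep(c("A", "B"), c(12, 10)), v = c(x, y))
    obs <- abs(t.test(v ~ group, data = d)$statistic)
    perms <- replicate(2000, {
      g <- sample(d$group)
      abs(t.test(d$v[g == "A"], d$v[g == "B"])$statistic)
    })
  })
  p_perm <- mean(perms >= obs)
  p_welch <- describe_groups(d, "group")$p.value
  expect_equal(p_welch, p_perm, tolerance = 0.05)
})
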