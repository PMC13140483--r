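# shared fixtures built in code

# default Windkessel fixture (aortic-scale parameters)
wk_fixture <- function(zc = 0.1, hr = 60, fs = 1000, n_beats = 3,
                       noise_sd = 0, seed = NULL) {
  simulate_windkessel(zc = zc, r_peripheral = 1.0, compliance = 1.5,
                      heart_rate = hr, stroke_volume = 70,
                      sampling_rate = fs, n_beats = n_beats,
                      noise_sd = noise_sd, seed = seed)
}

# one noise-free pressure ensemble beat
wk_beat <- function(...) wk_fixture(n_beats = 1, ...)$pressure

# cell-mean grid for simulate_cohort with a single outcome
cohort_grid <- function(means, sds, outcome = "y") {
  tidyr::crossing(group = c("YA", "MA"), time = c("baseline", "30", "60")) |>
    dplyr::arrange(group != "YA", time) |>
    dplyr::mutate(outcome = outcome,
                  mean = as.numeric(means),
                  sd = as.numeric(sds))
}

# brute-force mixed-design sums of squares via sequential projections:
# RSS drops of nested least-squares fits, independent of aov()'s strata
ss_oracle <- function(dat) {
  dat$subject <- factor(dat$subject)
  dat$group <- factor(dat$group)
  dat$time <- factor(as.character(dat$time), levels = c("baseline", "30", "60"))
  rss <- function(f) sum(stats::resid(stats::lm(f, data = dat))^2)
  r0 <- rss(value ~ 1)
  r1 <- rss(value ~ group)
  r2 <- rss(value ~ group + subject)
  r3 <- rss(value ~ group + subject + time)
  r4 <- rss(value ~ group + subject + time + group:time)
  ss <- list(group = r0 - r1, subject = r1 - r2, time = r2 - r3,
             gxt = r3 - r4, resid = r4, total = r0)
  n_sub <- length(unique(dat$subject))
  n_grp <- length(levels(dat$group))
  df <- list(group = n_grp - 1, subject = n_sub - n_grp, time = 2,
             gxt = 2 * (n_grp - 1),
             resid = 2 * n_sub - 2 - 2 * (n_grp - 1))
  f_group <- (ss$group / df$group) / (ss$subject / df$subject)
  f_time <- (ss$time / df$time) / (ss$resid / df$resid)
  f_gxt <- (ss$gxt / df$gxt) / (ss$resid / df$resid)
  list(
    ss = ss, df = df,
    F = c(group = f_group, time = f_time, gxt = f_gxt),
    p = c(group = stats::pf(f_group, df$group, df$subject, lower.tail = FALSE),
          time = stats::pf(f_time, df$time, df$resid, lower.tail = FALSE),
          gxt = stats::pf(f_gxt, df$gxt, df$resid, lower.tail = FALSE)),
    eta = c(group = ss$group / (ss$group + ss$subject),
            time = ss$time / (ss$time + ss$resid),
            gxt = ss$gxt / (ss$gxt + ss$resid))
  )
}

# random small complete study table
random_study_table <- function(seed, n_ya = 4, n_ma = 3) {
  withr::with_seed(seed, {
    tidyr::crossing(
      subject = c(sprintf("ya%d", seq_len(n_ya)), sprintf("ma%d", seq_len(n_ma))),
      time = c("baseline", "30", "60")
    ) |>
      dplyr::mutate(group = ifelse(grepl("^ya", subject), "YA", "MA"),
                    outcome = "y",
                    value = round(stats::rnorm(dplyr::n(), 10, 3), 3))
  })
}
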