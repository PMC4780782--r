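test_that("mixed ANOVA reproduces a stratum-wise least-squares oracle", {
  d <- make_anova_table(3, seed = 2, group_shift = 0.6, vot_effect = 1)
  r <- mixed_anova(d)
  o <- anova_lm_oracle(d)
  m <- merge(r, o, by = "effect", suffixes = c("", "_oracle"))
  expect_equal(nrow(m), 7L)
  expect_equal(m$F, m$F_oracle, tolerance = 1e-8)
  expect_equal(m$df_num, m$df_num_oracle)
  expect_equal(m$df_den, m$df_den_oracle)
  # uncorrected p follows from (F, df)
  expect_equal(m$p_uncorrected,
               pf(m$F, m$df_num, m$df_den, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("GG epsilon matches the multivariate-model machinery and its bounds", {
  d <- make_anova_table(8, seed = 3, group_shift = 0.5, vot_effect = 1)
  r <- mixed_anova(d)
  # two-level within factor: epsilon exactly 1
  expect_equal(r$gg_epsilon[r$effect == "task"], 1)
  expect_true(is.na(r$gg_epsilon[r$effect == "group"]))

  # independent route: car's mlm repeated-measures machinery
  d$cell <- paste(d$task, d$vot, sep = "_")
  wide <- reshape(d[, c("participant", "group", "cell", "dprime")],
                  direction = "wide", idvar = c("participant", "group"),
                  timevar = "cell", v.names = "dprime")
  Y <- as.matrix(wide[, -(1:2)])
  cells <- sub("dprime[.]", "", colnames(Y))
  idata <- data.frame(task = factor(sub("_.*", "", cells)),
                      vot = factor(sub(".*_", "", cells)))
  A <- car::Anova(lm(Y ~ group, data = wide), idata = idata,
                  idesign = ~ task * vot, type = 3)
  s <- suppressWarnings(summary(A, multivariate = FALSE))
  eps_car <- s$pval.adjustments[, "GG eps"]
  for (e in rownames(s$pval.adjustments))
    expect_equal(r$gg_epsilon[r$effect == e], unname(eps_car[e]),
                 tolerance = 1e-10)

  # epsilon within [1/(k-1), 1]; the correction can only raise the p-value
  # of an effect worth correcting (F >= 1; for F < 1 shrinking both df can
  # lower p slightly, a property of the F distribution itself)
  k <- 3
  eps_vot <- r$gg_epsilon[r$effect == "vot"]
  expect_gte(eps_vot, 1 / (k - 1))
  expect_lte(eps_vot, 1)
  big <- !is.na(r$gg_epsilon) & r$F >= 1
  expect_true(all(r$p_gg[big] >= r$p_uncorrected[big] - 1e-12))
})

test_that("partial eta-squared is consistent with its F-based identity", {
  d <- make_anova_table(5, seed = 9, group_shift = 0.4, vot_effect = 0.8)
  r <- mixed_anova(d)
  expect_equal(r$partial_eta2,
               r$F * r$df_num / (r$F * r$df_num + r$df_den),
               tolerance = 1e-10)
  expect_true(all(r$partial_eta2 >= 0 & r$partial_eta2 <= 1))
})

test_that("mixed ANOVA rejects unbalanced designs and flags constant responses", {
  d <- make_anova_table(3, seed = 1)
  expect_error(mixed_anova(d[-1, ]), "unbalanced")
  d0 <- d; d0$dprime <- 1
  r0 <- mixed_anova(d0)
  expect_true(attr(r0, "degenerate"))
  d1 <- d[d$participant %in% c("s01", "s04"), ]  # one participant per group
  expect_error(mixed_anova(d1), "2 participants")
})

test_that("a planted between-group shift is detected with high power", {
  hits <- vapply(1:60, function(i) {
    d <- make_anova_table(63, seed = 100 + i, group_shift = 0.5)
    r <- mixed_anova(d)
    r$p_uncorrected[r$effect == "group"] < 0.05
  }, NA)
  expect_gt(mean(hits), 0.8)
})

test_that("peak ANCOVA agrees with explicit nested least squares", {
  withr::with_seed(31, {
    d <- data.frame(group = rep(c("A", "B"), each = 4),
                    peak_location = c(-30, 0, 0, 30, -30, 0, 0, 30),
                    peak_amplitude = rnorm(8, mean = rep(c(1, 2), each = 4)))
  })
  r <- ancova_peak(d)
  # type-II SS by nested model comparison on the same data
  g <- factor(d$group); loc <- d$peak_location; y <- d$peak_amplitude
  rss <- function(X) sum(lm.fit(X, y)$residuals^2)
  X_full <- model.matrix(~ g * loc)
  X_main <- model.matrix(~ g + loc)
  ss_group <- rss(model.matrix(~ loc)) - rss(X_main)
  ss_loc <- rss(model.matrix(~ g)) - rss(X_main)
  ss_int <- rss(X_main) - rss(X_full)
  ss_err <- rss(X_full)
  expect_equal(r$ss[r$effect == "group"], ss_group, tolerance = 1e-8)
  expect_equal(r$ss[r$effect == "peak_location"], ss_loc, tolerance = 1e-8)
  expect_equal(r$ss[r$effect == "group:peak_location"], ss_int, tolerance = 1e-8)
  expect_equal(r$F[r$effect == "group"], (ss_group / 1) / (ss_err / 4),
               tolerance = 1e-8)
})

test_that("ANCOVA reduces to the plain group contrast when the covariate is inert", {
  # location orthogonal to group, amplitude exactly unrelated to location
  d <- data.frame(group = rep(c("A", "B"), each = 4),
                  peak_location = rep(c(-1, 1, -1, 1), 2),
                  peak_amplitude = c(1, 1, -1, -1, 3, 3, 1, 1))
  r <- ancova_peak(d)
  ss_oneway <- anova(lm(peak_amplitude ~ group, data = d))[["Sum Sq"]][1]
  expect_equal(r$ss[r$effect == "group"], ss_oneway, tolerance = 1e-6)
  expect_equal(r$ss[r$effect == "peak_location"], 0, tolerance = 1e-10)

  # identical amplitudes across groups: group F ~ 0
  d2 <- d; d2$peak_amplitude <- rep(c(1, 1, -1, -1), 2)
  expect_lt(ancova_peak(d2)$F[1], 1e-10)

  d3 <- d; d3$peak_location <- 1
  expect_error(ancova_peak(d3), "zero variance")
  expect_error(ancova_peak(d[c(1, 2, 5, 6, 7), ]), "3 participants")
})

test_that("partial correlation matches the closed-form identity", {
  withr::with_seed(17, {
    age <- rnorm(10)
    x <- 0.5 * age + rnorm(10)
    y <- -0.3 * age + rnorm(10)
  })
  pc <- partial_correlation(x, y, age)
  rxy <- cor(x, y); rxz <- cor(x, age); ryz <- cor(y, age)
  expect_equal(pc$r, (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
               tolerance = 1e-10)
  expect_equal(pc$df, 7L)
  t_stat <- pc$r * sqrt(7) / sqrt(1 - pc$r^2)
  expect_equal(pc$p, 2 * pt(-abs(t_stat), 7), tolerance = 1e-12)

  # a covariate unrelated to x and y leaves the plain correlation intact
  withr::with_seed(18, {
    x2 <- rnorm(200); y2 <- 0.4 * x2 + rnorm(200); z2 <- rnorm(200)
  })
  expect_equal(partial_correlation(x2, y2, z2)$r, cor(x2, y2),
               tolerance = 0.02)
  expect_equal(partial_correlation(x2, x2, z2)$r, 1, tolerance = 1e-10)
  expect_error(partial_correlation(1:3, 1:3, 1:3), "n >= 4")
  # x perfectly collinear with the covariate leaves no residual variance
  expect_error(partial_correlation(1:10, rnorm(10), 1:10), "zero residual")
})

test_that("partial correlation table covers all pairs with pairwise deletion", {
  withr::with_seed(2, {
    d <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30),
                    age_months = rnorm(30))
  })
  d$a[1:3] <- NA
  tab <- partial_correlation_table(d, c("a", "b", "c"))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$n[tab$var1 == "a" & tab$var2 == "b"], 27L)
  expect_equal(tab$n[tab$var1 == "b" & tab$var2 == "c"], 30L)
})
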