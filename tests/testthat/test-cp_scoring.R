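test_that("identification tabulation counts /t/ responses per level", {
  des <- identification_design(seed = 1L)
  tr <- data.frame(vot_ms = des$vot_ms,
                   response = ifelse(des$vot_ms > 0, "t", "d"))
  cv <- tabulate_identification(tr)
  expect_equal(cv$p_t, c(0, 0, 0, 1, 1, 1))
  expect_true(all(cv$n_total == 10L))

  # half /t/ at one level
  tr2 <- tr
  sel <- which(tr2$vot_ms == -15)[1:5]
  tr2$response[sel] <- "t"
  expect_equal(tabulate_identification(tr2)$p_t[3], 0.5)

  # order invariance
  shuf <- tr[sample.int(nrow(tr)), ]
  expect_equal(tabulate_identification(shuf), cv)

  expect_error(tabulate_identification(tr[tr$vot_ms != -45, ]), "-45")
})

test_that("boundary fit: symmetric step gives mu 0; degenerate curves flagged", {
  bf <- fit_boundary(make_curve(c(0, 0, 0, 1, 1, 1)))
  expect_true(bf$converged)
  expect_equal(bf$mu_ms, 0, tolerance = 1e-6)
  expect_gt(bf$s_ms, 0)

  expect_false(fit_boundary(make_curve(rep(1, 6)))$converged)
  expect_false(fit_boundary(make_curve(rep(0, 6)))$converged)
  expect_true(is.na(fit_boundary(make_curve(rep(0, 6)))$mu_ms))
})

test_that("boundary estimator recovers the generative boundary on average", {
  des <- identification_design()
  prof <- list(boundary_mu_ms = 10, precision_s_ms = 8)
  mus <- vapply(1:500, function(i) {
    bf <- fit_boundary(tabulate_identification(
      simulate_identification(prof, des, seed = i)))
    if (bf$converged) bf$mu_ms else NA_real_
  }, 0)
  expect_gt(mean(!is.na(mus)), 0.98)
  expect_lt(abs(mean(mus, na.rm = TRUE) - 10), 1)
})

test_that("observed pair rates pool orders and average flanking identical pairs", {
  mk <- function(a, b, n_diff, n_tot) {
    data.frame(vot_a_ms = a, vot_b_ms = b,
               response = rep(c("different", "same"), c(n_diff, n_tot - n_diff)))
  }
  tr <- rbind(mk(-15, 15, 4, 5), mk(15, -15, 4, 5),   # 8/10 different
              mk(-15, -15, 1, 5), mk(15, 15, 3, 5))
  r <- observed_pair_rates(tr, -15, 15)
  expect_equal(r$hit_rate, 0.8)
  expect_equal(r$fa_rate, 0.4)
  expect_equal(r$n_hit_trials, 10L)
  expect_equal(r$n_fa_trials, 10L)
  expect_error(observed_pair_rates(tr, -45, -15), "no trials")
})

test_that("d-prime applies the log-linear correction to every rate", {
  expect_equal(dprime(0.7, 0.7, 1000L, 1000L), 0, tolerance = 1e-12)
  # large counts: corrected rates converge to the raw rates
  expect_equal(dprime(0.84, 0.16, 1e6, 1e6),
               qnorm(0.84) - qnorm(0.16), tolerance = 1e-3)
  # perfect 25/25 vs 0/25 stays finite via the corrected counts
  expect_equal(dprime(1, 0, 25L, 25L),
               qnorm(25.5 / 26) - qnorm(0.5 / 26), tolerance = 1e-12)
  expect_error(dprime(1.2, 0, 10L, 10L), "rates")
  expect_error(dprime(0.5, 0.5, 0L, 10L), "counts")
})

test_that("predicted different-label probability matches covert-label enumeration", {
  expect_equal(predicted_different_prob(0.5, 0.5), 0.5)
  expect_equal(predicted_different_prob(0, 1), 1)
  expect_equal(predicted_different_prob(0.2, 0.9), 0.74)
  expect_error(predicted_different_prob(-0.1, 0.5), "probabilities")

  # exhaustive enumeration of the four covert-label outcomes on a 0.1 grid
  grid <- seq(0, 1, by = 0.1)
  for (p_i in grid) for (p_j in grid) {
    outcomes <- expand.grid(li = c("t", "d"), lj = c("t", "d"))
    pr <- ifelse(outcomes$li == "t", p_i, 1 - p_i) *
      ifelse(outcomes$lj == "t", p_j, 1 - p_j)
    expect_equal(predicted_different_prob(p_i, p_j),
                 sum(pr[outcomes$li != outcomes$lj]), tolerance = 1e-12)
    # symmetry and bounds
    expect_equal(predicted_different_prob(p_i, p_j),
                 predicted_different_prob(p_j, p_i), tolerance = 1e-15)
  }
})

test_that("predicted profiles: step and flat curves behave as ideal cases", {
  step <- predicted_profile(make_curve(c(0, 0, 0, 1, 1, 1)))
  expect_equal(step$scores$hit_rate, c(0, 0, 1, 0, 0))
  expect_equal(step$peak_center_ms, 0)

  flat <- predicted_profile(make_curve(rep(0.5, 6)))
  expect_equal(flat$scores$dprime, rep(0, 5), tolerance = 1e-12)
  expect_equal(flat$peak_amplitude, 0, tolerance = 1e-12)
  expect_equal(flat$peak_center_ms, 0)  # all-equal tie resolves to center 0
})

test_that("predicted H and F match Monte-Carlo covert labeling of a logistic curve", {
  p <- plogis(c(-75, -45, -15, 15, 45, 75) / 8)
  prof <- predicted_profile(make_curve(round(p * 1e6) / 1e6, n_total = 1e6))
  withr::with_seed(101, {
    n_mc <- 1e6
    for (k in 1:5) {
      li <- rbinom(n_mc, 1L, p[k]); lj <- rbinom(n_mc, 1L, p[k + 1])
      expect_equal(prof$scores$hit_rate[k], mean(li != lj), tolerance = 0.01)
      li2 <- rbinom(n_mc, 1L, p[k]); lj2 <- rbinom(n_mc, 1L, p[k])
      ki2 <- rbinom(n_mc, 1L, p[k + 1]); kj2 <- rbinom(n_mc, 1L, p[k + 1])
      fa_mc <- (mean(li2 != lj2) + mean(ki2 != kj2)) / 2
      expect_equal(prof$scores$fa_rate[k], fa_mc, tolerance = 0.01)
    }
  })
})

test_that("predicted F is bounded by the worst identical pair and 0.5", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      curve <- make_curve(round(runif(6) * 100) / 100, n_total = 100)
      prof <- predicted_profile(curve)
      p <- curve$p_t
      cap <- pmax(2 * p[1:5] * (1 - p[1:5]), 2 * p[2:6] * (1 - p[2:6]))
      expect_true(all(prof$scores$fa_rate <= cap + 1e-12))
      expect_true(all(prof$scores$fa_rate <= 0.5 + 1e-12))
    }
  })
})

test_that("sharpening the curve never lowers predicted d' at the boundary pair", {
  dp_mid <- vapply(c(20, 12, 8, 5, 3, 1.5), function(s) {
    p <- plogis(c(-75, -45, -15, 15, 45, 75) / s)
    predicted_profile(make_curve(round(p * 1e4) / 1e4, n_total = 1e4))$scores$dprime[3]
  }, 0)
  expect_true(all(diff(dp_mid) >= -1e-9))
})

test_that("peak extraction breaks ties toward small then negative centers", {
  centers <- c(-60, -30, 0, 30, 60)
  expect_equal(find_peak(centers, c(0.1, 0.5, 2, 0.5, 0.1)),
               list(peak_center_ms = 0, peak_amplitude = 2))
  expect_equal(find_peak(centers, c(0, 1, 0.5, 1, 0))$peak_center_ms, -30)
  expect_equal(find_peak(centers, rep(1, 5))$peak_center_ms, 0)
})

test_that("observed profile of a sharp categorical responder peaks at the boundary", {
  cfg <- cohort_config(allophonic_weight = 0)
  prof <- list(boundary_mu_ms = 0, precision_s_ms = 8)
  des <- discrimination_design()
  at_zero <- vapply(1:500, function(i) {
    tr <- simulate_discrimination(prof, des, cfg, seed = i)
    observed_profile(tr)$peak_center_ms == 0
  }, NA)
  expect_gt(mean(at_zero), 0.9)
})

test_that("chance and perfect responders score flat and ceiling profiles", {
  des <- discrimination_design()
  perfect <- data.frame(vot_a_ms = des$vot_a_ms, vot_b_ms = des$vot_b_ms,
                        response = ifelse(des$is_identical, "same", "different"))
  pr <- observed_profile(perfect)
  ceiling_d <- dprime(1, 0, 10L, 10L)
  expect_equal(pr$scores$dprime, rep(ceiling_d, 5), tolerance = 1e-12)
  expect_equal(pr$peak_center_ms, 0)  # tie rule

  chance <- perfect
  withr::with_seed(5, chance$response <- sample(c("same", "different"), nrow(chance),
                                                replace = TRUE))
  expect_lt(max(abs(observed_profile(chance)$scores$dprime)), 1.5)
  expect_error(observed_profile(perfect[!des$is_identical, ]), "no trials")
})

test_that("observed d' increases with the generative discriminability", {
  # 300 reps/pair so binomial response noise does not mask the ordering
  cfg <- cohort_config(allophonic_weight = 0, criterion_c = 0.5)
  des <- discrimination_design(reps = 300L, seed = 1L)
  withr::with_seed(21, {
    s_vals <- runif(200, 3, 25)
    d_gen <- numeric(200); d_obs <- numeric(200)
    for (i in 1:200) {
      prof <- list(boundary_mu_ms = 0, precision_s_ms = s_vals[i])
      d_gen[i] <- votcp:::d_true_pair(-15, 15, prof, cfg)
      tr <- simulate_discrimination(prof, des, cfg, seed = 1000 + i)
      d_obs[i] <- observed_profile(tr)$scores$dprime[3]
    }
  })
  expect_gt(cor(d_gen, d_obs, method = "spearman"), 0.95)
})

test_that("boundary distribution statistics match hand-computed skewness", {
  s <- boundary_distribution_stats(c(-1, 0, 1))
  expect_equal(s$skewness, 0)
  expect_equal(s$mean_ms, 0)
  # G1 of {0,0,0,10}: g1 = 1.1547, G1 = g1 * sqrt(12)/2 = 2
  expect_equal(boundary_distribution_stats(c(0, 0, 0, 10))$skewness, 2,
               tolerance = 1e-12)
  a <- boundary_distribution_stats(c(3, 1, 4, 1, 5, 9, 2, 6))
  b <- boundary_distribution_stats(c(3, 1, 4, 1, 5, 9, 2, 6) + 100)
  expect_equal(a$skewness, b$skewness, tolerance = 1e-10)
  expect_error(boundary_distribution_stats(c(1, 2, NA, NA)), "at least 3")
})

test_that("score_participants assembles the per-child derived table", {
  cfg <- cohort_config(n_control = 3L, n_dys_pa = 1L, n_dys_vas = 0L,
                       n_dys_other = 0L, seed = 8L)
  co <- simulate_cohort(cfg)
  tab <- score_participants(co$identification, co$discrimination)
  expect_equal(nrow(tab), 4L)
  expect_true(all(c("boundary_mu_ms", "obs_d_0", "pred_d_m30",
                    "pred_peak_amplitude") %in% names(tab)))
  expect_error(
    score_participants(co$identification,
                       co$discrimination[co$discrimination$participant_id != "P001", ]),
    "P001")
})
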