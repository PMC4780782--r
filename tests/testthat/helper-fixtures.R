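# Shared fixture builders. Everything is generated in code; no stored data.

# An identification curve object from labeling proportions on the default
# grid (10 trials per level unless stated).
make_curve <- function(p_t, n_total = 10L, vot = c(-75, -45, -15, 15, 45, 75)) {
  structure(data.frame(vot_ms = vot, n_t = as.integer(round(p_t * n_total)),
                       n_total = as.integer(n_total),
                       p_t = round(p_t * n_total) / n_total),
            class = c("identification_curve", "data.frame"))
}

# A balanced two-group Task x VOT long table with optional effects.
make_anova_table <- function(n_per_group, seed = 1, group_shift = 0,
                             vot_effect = 0, sd = 1) {
  withr::with_seed(seed, {
    d <- expand.grid(participant = sprintf("s%02d", seq_len(2 * n_per_group)),
                     task = c("observed", "predicted"), vot = c(-30, 0, 30),
                     KEEP.OUT.ATTRS = FALSE)
    idx <- as.integer(sub("s", "", d$participant))
    d$group <- ifelse(idx <= n_per_group, "A", "B")
    d$dprime <- rnorm(nrow(d), sd = sd) +
      (d$group == "A") * group_shift + (d$vot == 0) * vot_effect
    d
  })
}

# Independent stratum-wise SS oracle for the mixed ANOVA: sequential lm with
# explicit subject terms; each within stratum's error is the id:within term.
anova_lm_oracle <- function(d) {
  d$g <- factor(d$group); d$t <- factor(d$task)
  d$v <- factor(d$vot); d$id <- factor(d$participant)
  a <- anova(lm(dprime ~ g + id + t + g:t + id:t + v + g:v + id:v +
                  t:v + g:t:v, data = d))
  ss <- setNames(a[["Sum Sq"]], rownames(a))
  df <- setNames(a[["Df"]], rownames(a))
  err <- list(g = "id", t = "id:t", `g:t` = "id:t", v = "id:v",
              `g:v` = "id:v", `t:v` = "Residuals", `g:t:v` = "Residuals")
  lab <- c(g = "group", t = "task", `g:t` = "group:task", v = "vot",
           `g:v` = "group:vot", `t:v` = "task:vot",
           `g:t:v` = "group:task:vot")
  do.call(rbind, lapply(names(err), function(e) {
    data.frame(effect = unname(lab[e]),
               F = (ss[e] / df[e]) / (ss[err[[e]]] / df[err[[e]]]),
               df_num = unname(df[e]), df_den = unname(df[err[[e]]]),
               row.names = NULL)
  }))
}

# Brute-force OLS via normal equations.
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))

# A mediation-structured data frame on the pipeline's column names.
med_frame <- function(n, a, b, c_prime, d = 0.3, seed = 1) {
  withr::with_seed(seed, {
    age <- rnorm(n, 120, 12)
    x <- rnorm(n)
    m <- a * x + rnorm(n)
    vas <- rnorm(n)
    y <- b * m + c_prime * x + d * vas + rnorm(n)
    data.frame(pred_peak_amplitude = x, pa_composite = m,
               reading_accuracy = y, vas_composite = vas, age_months = age)
  })
}
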