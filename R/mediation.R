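#' Sobel test of an indirect effect
#'
#' Large-sample normal test of the mediated effect `a * b`:
#' `z = a b / sqrt(b^2 se_a^2 + a^2 se_b^2)`. The p-value is one-sided in
#' the direction of the hypothesized positive indirect effect,
#' `p = 1 - Phi(z)`.
#'
#' @param a,se_a coefficient and standard error of the predictor ->
#'   mediator path.
#' @param b,se_b coefficient and standard error of the mediator ->
#'   outcome path (predictor partialled).
#' @return A list `z`, `p_one_sided`.
#' @export
sobel <- function(a, se_a, b, se_b) {
  if (se_a <= 0 || se_b <= 0) stop("standard errors must be > 0")
  z <- a * b / sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  list(z = z, p_one_sided = 1 - pnorm(z))
}

# Coefficient and SE extractor for one term of an lm fit.
coef_se <- function(fit, term) {
  s <- summary(fit)$coefficients
  c(est = s[term, "Estimate"], se = s[term, "Std. Error"],
    p = s[term, "Pr(>|t|)"])
}

#' Causal-steps mediation of CP on reading through phoneme awareness
#'
#' Three ordinary-least-squares regressions, fitted in order, with
#' chronological age in every model and VA span as an additional
#' independent regressor on reading:
#' \enumerate{
#'   \item `M ~ age + X` (path `a`: CP -> phoneme awareness);
#'   \item `Y ~ age + X + VAS` (total effect `c`, VA-span path `d`);
#'   \item `Y ~ age + X + M + VAS` (direct effect `c'`, mediator path `b`,
#'     VA-span path `d'`).
#' }
#' The causal-steps flags hold at two-sided `alpha` on `a`, `c` and `b`;
#' the mediation claim additionally requires `c'` to lose significance.
#' The indirect effect `a * b` is tested with the one-sided [sobel()]
#' test.
#'
#' @param data data frame of complete cases.
#' @param x,m,y,vas,age column names: predictor (predicted peak
#'   amplitude), mediator (PA composite), outcome (reading accuracy),
#'   VA-span composite, age.
#' @param alpha significance level for the step flags.
#' @param vas_in_model1 also include VA span in model 1. The printed
#'   model set omits it; including it makes the decomposition
#'   `c = c' + a b` exact because all three models then share one
#'   regressor set.
#' @return A list of class `"mediation_result"`: the three fitted models'
#'   coefficient tables (`model1`, `model2`, `model3`), named paths
#'   (`a`, `b`, `c`, `c_prime`, `d`, `d_prime` with standard errors and
#'   p-values), `sobel_z`, `sobel_p_one_sided`, `steps` (logical flags),
#'   `mediated` (all flags true), `n`.
#' @export
causal_steps <- function(data, x = "pred_peak_amplitude", m = "pa_composite",
                         y = "reading_accuracy", vas = "vas_composite",
                         age = "age_months", alpha = 0.05,
                         vas_in_model1 = FALSE) {
  cols <- c(x, m, y, vas, age)
  stopifnot(all(cols %in% names(data)))
  d <- data[, cols]
  names(d) <- c("X", "M", "Y", "VAS", "AGE")
  d <- d[complete.cases(d), ]
  n <- nrow(d)
  if (n <= 6L) stop("need more complete cases than regressors + 2")
  qrX <- qr(cbind(1, d$AGE, d$X, d$M, d$VAS))
  if (qrX$rank < 5L) stop("rank-deficient design matrix")

  f1 <- if (vas_in_model1) lm(M ~ AGE + X + VAS, data = d) else
    lm(M ~ AGE + X, data = d)
  f2 <- lm(Y ~ AGE + X + VAS, data = d)
  f3 <- lm(Y ~ AGE + X + M + VAS, data = d)

  a <- coef_se(f1, "X")
  c_tot <- coef_se(f2, "X"); d_path <- coef_se(f2, "VAS")
  c_pr <- coef_se(f3, "X"); b <- coef_se(f3, "M"); d_pr <- coef_se(f3, "VAS")
  sb <- sobel(a["est"], a["se"], b["est"], b["se"])

  steps <- c(a_significant = unname(a["p"] < alpha),
             c_significant = unname(c_tot["p"] < alpha),
             b_significant = unname(b["p"] < alpha),
             c_prime_nonsignificant = unname(c_pr["p"] >= alpha))
  paths <- rbind(a = a, c = c_tot, c_prime = c_pr, b = b, d = d_path,
                 d_prime = d_pr)
  structure(list(
    model1 = summary(f1)$coefficients,
    model2 = summary(f2)$coefficients,
    model3 = summary(f3)$coefficients,
    paths = paths,
    sobel_z = unname(sb$z), sobel_p_one_sided = unname(sb$p_one_sided),
    steps = steps, mediated = all(steps), n = n,
    alpha = alpha, vars = setNames(cols, c("x", "m", "y", "vas", "age"))),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  v <- x$vars
  p3 <- function(p) sub("^0", "", sprintf("%.3f", p))
  star <- function(p) if (p < 0.05) " (*)" else if (p < 0.09) " (~)" else " (ns)"
  pa <- x$paths
  cat("Causal-steps mediation (n = ", x$n, ")\n", sep = "")
  cat("  ", v["x"], " --a--> ", v["m"], ": ",
      sprintf("%.3f (SE %.3f)", pa["a", "est"], pa["a", "se"]),
      star(pa["a", "p"]), "\n", sep = "")
  cat("  ", v["m"], " --b--> ", v["y"], ": ",
      sprintf("%.3f (SE %.3f)", pa["b", "est"], pa["b", "se"]),
      star(pa["b", "p"]), "\n", sep = "")
  cat("  ", v["x"], " --c--> ", v["y"], " (total): ",
      sprintf("%.3f", pa["c", "est"]), star(pa["c", "p"]), "\n", sep = "")
  cat("  ", v["x"], " --c'--> ", v["y"], " (direct): ",
      sprintf("%.3f", pa["c_prime", "est"]), star(pa["c_prime", "p"]),
      "\n", sep = "")
  cat("  ", v["vas"], " --d--> ", v["y"], ": ",
      sprintf("%.3f", pa["d", "est"]), star(pa["d", "p"]), "\n", sep = "")
  cat("  Sobel z = ", sprintf("%.2f", x$sobel_z), ", one-sided p = ",
      p3(x$sobel_p_one_sided), "\n", sep = "")
  cat("  Mediation supported: ", x$mediated, "\n", sep = "")
  invisible(x)
}

#' Scan candidate CP indices for a mediation predictor
#'
#' The CP index entering the mediation model is chosen by an explicit,
#' logged scan: for each candidate column, the age-partialled correlation
#' with the mediator (phoneme awareness) is computed and candidates with
#' `p < alpha` are flagged. The scan records every candidate's r and p so
#' the exploratory selection is visible rather than implicit.
#'
#' @param data data frame.
#' @param candidates candidate CP index columns.
#' @param m mediator column.
#' @param age covariate column.
#' @param alpha selection threshold.
#' @return A data frame `candidate`, `r`, `p`, `selected`, ordered by p.
#' @export
scan_cp_candidates <- function(data, candidates, m = "pa_composite",
                               age = "age_months", alpha = 0.05) {
  rows <- lapply(candidates, function(v) {
    pc <- partial_correlation(data[[v]], data[[m]], data[[age]])
    data.frame(candidate = v, r = pc$r, p = pc$p)
  })
  out <- do.call(rbind, rows)
  out$selected <- out$p < alpha
  out[order(out$p), ]
}
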