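# Orthonormal contrast matrix ((k-1) x k) for a within factor.
orth_contrast <- function(k) {
  C <- stats::contr.helmert(k)
  C <- t(C) / sqrt(colSums(C^2))
  C
}

# Greenhouse-Geisser epsilon of a within effect, from the pooled
# within-group covariance of the participant x cell matrix. `M` is the
# effect's contrast matrix over cells.
gg_epsilon <- function(Y, groups, M) {
  gs <- split(seq_len(nrow(Y)), groups)
  S <- matrix(0, ncol(Y), ncol(Y))
  dfree <- 0
  for (idx in gs) {
    if (length(idx) < 2L) next
    S <- S + stats::cov(Y[idx, , drop = FALSE]) * (length(idx) - 1L)
    dfree <- dfree + length(idx) - 1L
  }
  S <- S / dfree
  E <- M %*% S %*% t(M)
  q <- nrow(M)
  eps <- sum(diag(E))^2 / (q * sum(E^2))
  max(min(eps, 1), 1 / q)
}

#' Mixed repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Univariate mixed ANOVA for a design with one between-subjects factor
#' and one or two fully-crossed within-subjects factors (the d'-score
#' analysis: Group between, Task and VOT within). Sums of squares come
#' from [stats::aov()] with the appropriate error strata; the
#' Greenhouse-Geisser epsilon of every within effect is computed from the
#' pooled within-group covariance matrix and applied to the degrees of
#' freedom of every effect involving a within factor (effects with a
#' single numerator degree of freedom have epsilon 1 exactly). Partial
#' eta-squared is `SS_effect / (SS_effect + SS_error)` within each
#' effect's stratum.
#'
#' @param data long-format data frame.
#' @param dv,id,between,within column names: response, participant
#'   identifier, between factor, within factor(s).
#' @return A data frame of class `"anova_result"`: one row per effect with
#'   `effect`, `df_num`, `df_den`, `ss`, `ss_error`, `F`,
#'   `p_uncorrected`, `gg_epsilon`, `p_gg`, `partial_eta2`. An attribute
#'   `degenerate` is `TRUE` when the response is constant (all F
#'   undefined).
#' @export
mixed_anova <- function(data, dv = "dprime", id = "participant",
                        between = "group", within = c("task", "vot")) {
  stopifnot(all(c(dv, id, between, within) %in% names(data)))
  d <- data.frame(.y = data[[dv]], .id = factor(data[[id]]),
                  .g = factor(data[[between]]))
  for (i in seq_along(within)) d[[paste0(".w", i)]] <- factor(data[[within[i]]])
  wn <- paste0(".w", seq_along(within))
  # balance: every participant must hold each within cell exactly once
  cell <- interaction(d[wn], drop = FALSE)
  tab <- table(d$.id, cell)
  if (any(tab != 1L))
    stop("unbalanced within design: each participant needs every ",
         paste(within, collapse = " x "), " cell exactly once")
  if (any(table(unique(d[, c(".id", ".g")])$.g) < 2L))
    stop("need >= 2 participants per group")
  degenerate <- var(d$.y) == 0

  rhs <- paste(c(".g", wn), collapse = " * ")
  err <- paste0("Error(.id/(", paste(wn, collapse = " * "), "))")
  fml <- stats::as.formula(paste(".y ~", rhs, "+", err))
  fit <- aov(fml, data = d)
  sm <- summary(fit)

  rows <- list()
  for (stratum in sm) {
    tb <- stratum[[1]]
    nm <- trimws(rownames(tb))
    resid_i <- which(nm == "Residuals")
    ss_err <- tb[resid_i, "Sum Sq"]; df_err <- tb[resid_i, "Df"]
    for (i in setdiff(seq_along(nm), resid_i)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = nm[i], df_num = tb[i, "Df"], df_den = df_err,
        ss = tb[i, "Sum Sq"], ss_error = ss_err,
        F = tb[i, "Sum Sq"] / tb[i, "Df"] / (ss_err / df_err))
    }
  }
  out <- do.call(rbind, rows)
  # map internal names back to user-facing ones
  repl <- c(setNames(between, ".g"), setNames(within, wn))
  out$effect <- vapply(strsplit(out$effect, ":"), function(parts)
    paste(repl[parts], collapse = ":"), "")
  out$p_uncorrected <- pf(out$F, out$df_num, out$df_den, lower.tail = FALSE)

  # wide participant x cell matrix for the epsilon computations
  d_ord <- d[order(d$.id, cell), ]
  Y <- matrix(d_ord$.y, nrow = nlevels(d$.id), byrow = TRUE)
  grp_of <- d_ord$.g[!duplicated(d_ord$.id)]
  ks <- vapply(wn, function(w) nlevels(d[[w]]), 0L)
  # interaction() levels vary the first factor fastest; the kronecker is
  # built right-to-left so contrast columns match the cell ordering of Y
  eff_within <- function(which_f) {
    mats <- lapply(rev(seq_along(wn)), function(j) {
      if (j %in% which_f) orth_contrast(ks[j]) else
        matrix(1 / ks[j], 1L, ks[j])
    })
    Reduce(`%x%`, mats)
  }
  out$gg_epsilon <- NA_real_
  out$p_gg <- out$p_uncorrected
  for (i in seq_len(nrow(out))) {
    parts <- strsplit(out$effect[i], ":")[[1]]
    wf <- which(within %in% parts)
    if (length(wf) == 0L) next  # purely between effect
    M <- eff_within(wf)
    eps <- if (nrow(M) == 1L) 1 else gg_epsilon(Y, grp_of, M)
    out$gg_epsilon[i] <- eps
    out$p_gg[i] <- pf(out$F[i], out$df_num[i] * eps, out$df_den[i] * eps,
                      lower.tail = FALSE)
  }
  out$partial_eta2 <- out$ss / (out$ss + out$ss_error)
  rownames(out) <- NULL
  structure(out, class = c("anova_result", "data.frame"),
            degenerate = degenerate)
}

#' ANCOVA on discrimination peak amplitude
#'
#' Linear model `amplitude ~ group + location + group:location` with
#' Type-II tests (via [car::Anova()]): the Group effect on peak amplitude
#' adjusted for peak location, the Location effect, and their
#' interaction.
#'
#' @param data data frame.
#' @param amplitude,group,location column names.
#' @return An `"anova_result"` data frame with `F`, dfs, p and partial
#'   eta-squared per effect.
#' @export
ancova_peak <- function(data, amplitude = "peak_amplitude", group = "group",
                        location = "peak_location") {
  stopifnot(all(c(amplitude, group, location) %in% names(data)))
  d <- data.frame(a = data[[amplitude]], g = factor(data[[group]]),
                  loc = data[[location]])
  d <- d[complete.cases(d), ]
  if (any(table(d$g) < 3L)) stop("need >= 3 participants per group")
  if (var(d$loc) == 0) stop("peak location has zero variance (collinear covariate)")
  fit <- lm(a ~ g * loc, data = d)
  A <- car::Anova(fit, type = 2)
  nm <- trimws(rownames(A))
  resid_i <- which(nm == "Residuals")
  ss_err <- A[resid_i, "Sum Sq"]; df_err <- A[resid_i, "Df"]
  keep <- setdiff(seq_along(nm), resid_i)
  lab <- c(g = group, loc = location,
           `g:loc` = paste0(group, ":", location))
  out <- data.frame(effect = unname(lab[nm[keep]]),
                    df_num = A[keep, "Df"], df_den = df_err,
                    ss = A[keep, "Sum Sq"], ss_error = ss_err,
                    F = A[keep, "F value"],
                    p_uncorrected = A[keep, "Pr(>F)"],
                    gg_epsilon = NA_real_, p_gg = A[keep, "Pr(>F)"])
  out$partial_eta2 <- out$ss / (out$ss + out$ss_error)
  rownames(out) <- NULL
  structure(out, class = c("anova_result", "data.frame"))
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' each on the covariate (chronological age in the study analyses), with
#' a two-sided t test on `n - 3` degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariate numeric vector (same length).
#' @return A list `r`, `df`, `p`, `n`.
#' @export
partial_correlation <- function(x, y, covariate) {
  keep <- complete.cases(x, y, covariate)
  x <- x[keep]; y <- y[keep]; z <- covariate[keep]
  n <- length(x)
  if (n < 4L) stop("need n >= 4 complete cases")
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  tol <- sqrt(.Machine$double.eps)
  if (var(rx) <= tol * max(var(x), tol) || var(ry) <= tol * max(var(y), tol))
    stop("zero residual variance after partialling out the covariate")
  r <- cor(rx, ry)
  df <- n - 3L
  t <- r * sqrt(df) / sqrt(1 - r^2)
  list(r = r, df = df, p = 2 * pt(-abs(t), df), n = n)
}

#' Age-partialled correlation matrix
#'
#' [partial_correlation()] over every pair of the given columns,
#' controlling for age; the analysis behind the study's correlation table
#' (reading age/accuracy/speed, VA span, phoneme awareness, predicted
#' peak amplitude). Pairwise deletion is applied per pair.
#'
#' @param data data frame.
#' @param vars columns to correlate.
#' @param age column name of the covariate.
#' @return A data frame `var1`, `var2`, `r`, `df`, `p`, `n` (long form,
#'   upper triangle).
#' @export
partial_correlation_table <- function(data, vars, age = "age_months") {
  stopifnot(all(c(vars, age) %in% names(data)))
  combos <- utils::combn(vars, 2L)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    v1 <- combos[1, i]; v2 <- combos[2, i]
    pc <- partial_correlation(data[[v1]], data[[v2]], data[[age]])
    data.frame(var1 = v1, var2 = v2, r = pc$r, df = pc$df, p = pc$p, n = pc$n)
  })
  do.call(rbind, rows)
}

#' Format an ANOVA effect in report style
#'
#' `"F(df1,df2) = x.xx, p = .xxx, eta2_p = .xxx"` strings for a rendered
#' text report.
#' @param result an `"anova_result"` row set.
#' @return Character vector, one line per effect.
#' @export
format_anova <- function(result) {
  p <- ifelse(is.na(result$gg_epsilon), result$p_uncorrected, result$p_gg)
  sprintf("%s: F(%g,%g) = %.2f, p = %s, eta2_p = %.3f%s",
          result$effect, result$df_num, result$df_den, result$F,
          sub("^0", "", sprintf("%.3f", p)), result$partial_eta2,
          ifelse(is.na(result$gg_epsilon), "",
                 sprintf(" (Greenhouse-Geisser eps = %.3f)", result$gg_epsilon)))
}
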