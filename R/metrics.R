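## Evaluation statistics: RMSD / mean error / relative mean error between
## estimated and directly measured pressures, and Lin's concordance
## correlation coefficient for repeated measures computed from crossed
## variance components.

#' Agreement measures between estimated and measured pressures
#'
#' \deqn{RMSD = \sqrt{\tfrac1N\sum (P^{est}_i - P^{meas}_i)^2},\quad
#'       ME = \tfrac1N\sum (P^{est}_i - P^{meas}_i),\quad
#'       RME = 100\,\tfrac1N\sum \frac{P^{est}_i - P^{meas}_i}{P^{meas}_i}.}
#'
#' @param P_est estimated pressures, mmHg.
#' @param P_meas measured pressures, mmHg (all nonzero; RME divides by them).
#' @return object of class `performance_measures` with `rmsd` (mmHg), `me`
#'   (mmHg), `rme` (percent) and `n`.
#' @export
#' @examples
#' performance_measures(c(12, 8), c(10, 10))  # RMSD 2, ME 0, RME 0
performance_measures <- function(P_est, P_meas) {
  if (length(P_est) != length(P_meas)) stop_domain("length mismatch")
  if (length(P_est) < 1) stop_domain("need at least one pair")
  zero <- which(P_meas == 0)
  if (length(zero)) {
    stop_domain("zero measured pressure at index ", zero[1],
                ": relative mean error undefined")
  }
  d <- P_est - P_meas
  structure(list(rmsd = sqrt(mean(d^2)), me = mean(d),
                 rme = 100 * mean(d / P_meas), n = length(d)),
            class = "performance_measures")
}

#' @export
print.performance_measures <- function(x, ...) {
  cat(sprintf("RMSD = %.2f mmHg, ME = %.2f mmHg, RME = %.2f%% (n = %d)\n",
              x$rmsd, x$me, x$rme, x$n))
  invisible(x)
}

## ANOVA method-of-moments variance components for the crossed design
## subject x method x repeat with one observation per cell. Expected mean
## squares (method and repeat treated as fixed, interactions random):
##   E[MS_SM] = s2_e + R s2_sm        E[MS_SN] = s2_e + M s2_sn
##   E[MS_MN] = s2_e + S s2_mn
##   E[MS_S]  = s2_e + R s2_sm + M s2_sn + M R s2_s
## with the three-way interaction pooled into the residual.
mom_components <- function(tab) {
  S <- length(unique(tab$subject))
  M <- length(unique(tab$method))
  R <- length(unique(tab$repeat_idx))
  f <- data.frame(s = factor(tab$subject), m = factor(tab$method),
                  n = factor(tab$repeat_idx), y = tab$value)
  if (R > 1) {
    fit <- stats::aov(y ~ s + m + n + s:m + s:n + m:n, data = f)
    ms <- summary(fit)[[1]][, "Mean Sq"]
    names(ms) <- trimws(rownames(summary(fit)[[1]]))
    ms_e <- ms[["Residuals"]]
    raw <- c(
      e  = ms_e,
      sm = (ms[["s:m"]] - ms_e) / R,
      sn = (ms[["s:n"]] - ms_e) / M,
      mn = (ms[["m:n"]] - ms_e) / S,
      s  = (ms[["s"]] - ms[["s:m"]] - ms[["s:n"]] + ms_e) / (M * R))
  } else {
    ## single repeat: sn and mn are not estimable; subject x method is the
    ## residual
    fit <- stats::aov(y ~ s + m, data = f)
    ms <- summary(fit)[[1]][, "Mean Sq"]
    names(ms) <- trimws(rownames(summary(fit)[[1]]))
    ms_e <- ms[["Residuals"]]
    raw <- c(e = ms_e, sm = 0, sn = 0, mn = 0,
             s = (ms[["s"]] - ms_e) / M)
  }
  raw
}

lmer_components <- function(tab) {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    stop_domain("estimator = 'lmer' requires the lme4 package")
  }
  f <- data.frame(s = factor(tab$subject), m = factor(tab$method),
                  n = factor(tab$repeat_idx), y = tab$value)
  fit <- lme4::lmer(
    y ~ m + (1 | s) + (1 | s:m) + (1 | s:n) + (1 | m:n),
    data = f,
    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(g) {
    i <- which(vc$grp == g)
    if (length(i)) vc$vcov[i] else 0
  }
  c(e = pick("Residual"), sm = pick("s:m"), sn = pick("s:n"),
    mn = pick("m:n"), s = pick("s"))
}

ccc_from_components <- function(comp) {
  tot <- sum(comp)
  if (tot <= 0) stop_domain("degenerate data: zero total variance")
  unname((comp[["s"]] + comp[["sn"]]) / tot)
}

#' Lin's concordance correlation coefficient for repeated measures
#'
#' Estimates the crossed variance components (subject, subject x repeat,
#' subject x method, method x repeat, residual) and forms
#' \deqn{CCC = \frac{\sigma^2_s + \sigma^2_{sn}}
#'   {\sigma^2_s + \sigma^2_{sn} + \sigma^2_{sm} + \sigma^2_{mn} +
#'    \sigma^2_e}.}
#' The default estimator is ANOVA method-of-moments on the (near-)balanced
#' crossed design, with negative moment estimates truncated at zero (the
#' pre-truncation values are reported). `estimator = "lmer"` plugs in REML
#' variance components from lme4 instead. The confidence interval is a
#' percentile bootstrap over subjects (the independent units), seeded.
#'
#' @param tab data frame with columns `subject`, `method` (exactly 2 levels),
#'   `repeat_idx`, `value`.
#' @param conf_level confidence level for the bootstrap interval.
#' @param n_boot bootstrap draws (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param estimator `"mom"` (ANOVA method-of-moments, default) or `"lmer"`.
#' @return object of class `concordance_result`: `ccc`, `ci_low`, `ci_high`,
#'   `components` (truncated), `components_raw` (pre-truncation), `n_subjects`,
#'   `estimator`.
#' @export
lin_ccc_repeated <- function(tab, conf_level = 0.95, n_boot = 2000,
                             seed = 1L, estimator = c("mom", "lmer")) {
  estimator <- match.arg(estimator)
  tab <- as.data.frame(tab)
  need <- c("subject", "method", "repeat_idx", "value")
  if (!all(need %in% names(tab))) {
    stop_domain("tab needs columns ", paste(need, collapse = ", "))
  }
  subs <- unique(tab$subject)
  if (length(subs) < 3) stop_domain("need >= 3 subjects")
  if (length(unique(tab$method)) != 2) stop_domain("need exactly 2 methods")
  if (stats::var(tab$value) == 0) {
    stop_domain("degenerate data: zero total variance")
  }
  est_fun <- if (estimator == "mom") mom_components else lmer_components
  raw <- est_fun(tab)
  comp <- pmax(raw, 0)
  ccc <- ccc_from_components(comp)
  boot <- rep(NA_real_, n_boot)
  if (n_boot > 0) {
    set.seed(seed)
    for (b in seq_len(n_boot)) {
      draw <- sample(subs, length(subs), replace = TRUE)
      tab_b <- do.call(rbind, lapply(seq_along(draw), function(i) {
        g <- tab[tab$subject == draw[i], , drop = FALSE]
        g$subject <- i  # relabel so duplicates count as distinct subjects
        g
      }))
      boot[b] <- tryCatch(ccc_from_components(pmax(est_fun(tab_b), 0)),
                          error = function(e) NA_real_)
    }
  }
  qs <- if (all(is.na(boot))) c(NA_real_, NA_real_) else {
    stats::quantile(boot, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                    na.rm = TRUE, names = FALSE)
  }
  structure(list(ccc = ccc, ci_low = qs[1], ci_high = qs[2],
                 components = comp, components_raw = raw,
                 n_subjects = length(subs), estimator = estimator,
                 conf_level = conf_level, n_boot = n_boot),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Lin's CCC (repeated measures, %s): %.3f (%.2f%% CI %.3f-%.3f)\n",
              x$estimator, x$ccc, 100 * x$conf_level, x$ci_low, x$ci_high))
  comp <- x$components
  cat(sprintf("  components: s=%.3g sn=%.3g sm=%.3g mn=%.3g e=%.3g (n=%d subjects)\n",
              comp[["s"]], comp[["sn"]], comp[["sm"]], comp[["mn"]],
              comp[["e"]], x$n_subjects))
  invisible(x)
}

#' Classic bivariate Lin concordance correlation coefficient
#'
#' \eqn{CCC = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)} with
#' denominator-n moments. Provided as the closed-form special case the
#' repeated-measures estimator reduces to when there is one repeat.
#'
#' @param x,y paired measurements from the two methods.
#' @return scalar CCC in [-1, 1].
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop_domain("length mismatch")
  n <- length(x)
  if (n < 2) stop_domain("need >= 2 pairs")
  mx <- mean(x); my <- mean(y)
  sx <- mean((x - mx)^2); sy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx + sy + (mx - my)^2)
}
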