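#' Recognition-memory score
#'
#' Difference between the rate of calling a target item "old" and the rate of
#' calling a foil item "old": `P('old'|target) - P('old'|foil)`.
#'
#' @param p_old_given_target,p_old_given_foil rates in `[0, 1]`.
#' @return RM score in `[-1, 1]`.
#' @export
recognition_memory_score <- function(p_old_given_target, p_old_given_foil) {
  if (any(p_old_given_target < 0 | p_old_given_target > 1) ||
      any(p_old_given_foil < 0 | p_old_given_foil > 1))
    stop("rates must lie in [0, 1]")
  p_old_given_target - p_old_given_foil
}

#' Relative memory decline over the follow-up interval
#'
#' `(rm_baseline - rm_followup) / rm_baseline`; higher values indicate a
#' greater decline. Scale-invariant in the two scores.
#'
#' @param rm_baseline,rm_followup RM scores; baseline must be non-zero.
#' @return decline as a fraction of baseline performance.
#' @export
memory_decline <- function(rm_baseline, rm_followup) {
  if (any(rm_baseline == 0)) stop("zero baseline RM score: decline undefined")
  (rm_baseline - rm_followup) / rm_baseline
}

#' Semi-partial effect size R2-beta-star from an F statistic
#'
#' `R2 = (q F / v) / (1 + q F / v)` with `q` the numerator and `v` the
#' denominator degrees of freedom. Strictly increasing in F, mapping
#' `[0, Inf)` onto `[0, 1)`.
#'
#' @param f F statistic (>= 0).
#' @param df_num numerator degrees of freedom.
#' @param df_den denominator degrees of freedom (may be fractional, e.g.
#'   Kenward-Roger adjusted).
#' @return effect size in `[0, 1)`.
#' @export
semipartial_r2 <- function(f, df_num, df_den) {
  stopifnot(all(f >= 0), all(df_num > 0), all(df_den > 0))
  q <- df_num * f / df_den
  q / (1 + q)
}

#' Fit a Gaussian linear mixed (or fixed-effect) association model
#'
#' Fits the model by REML with a per-subject random intercept when the
#' formula contains a random term; per-effect F tests use small-sample
#' adjusted denominator degrees of freedom (Kenward-Roger where available,
#' else Satterthwaite), and each effect's semi-partial R2-beta-star is
#' attached. If the random effect is singular (variance estimated at zero)
#' or the formula has no random term, an ordinary least-squares fit with
#' type-III F tests is used instead, with a warning in the singular case.
#'
#' @param formula model formula, e.g.
#'   `mean_cos_phase ~ switcher * centiloid + age + sex + tst + sw_duration +
#'   (1 | subject_id)`.
#' @param data model data, one row per subject x condition.
#' @param df_method `"Kenward-Roger"` or `"Satterthwaite"` (mixed fits only;
#'   Satterthwaite is much faster and nearly identical for balanced
#'   random-intercept designs).
#' @return object of class `swc_model_fit`: list with `model` (the lmer/lm
#'   object), `anova` (data.frame: `effect`, `F`, `df_num`, `df_den`, `p`,
#'   `r2_beta_star`), `coef`, `varcomp` (random-intercept and residual
#'   variances), `meta` (fit type, df method, singular fallback flag),
#'   `formula`, `data`.
#' @export
fit_mixed_model <- function(formula, data,
                            df_method = c("Satterthwaite", "Kenward-Roger")) {
  df_method <- match.arg(df_method)
  has_rand <- length(lme4::findbars(formula)) > 0
  singular_fallback <- FALSE
  if (has_rand) {
    fit <- tryCatch(
      lmerTest::lmer(formula, data = data, REML = TRUE),
      error = function(e) stop("mixed model failed to converge: ",
                               conditionMessage(e)))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      warning("singular random effect; falling back to a fixed-effects model")
      singular_fallback <- TRUE
    }
  }
  if (!has_rand || singular_fallback) {
    fixed <- lme4::nobars(formula)
    fit_lm <- stats::lm(fixed, data = data)
    a <- car::Anova(fit_lm, type = 3)
    a <- a[!rownames(a) %in% c("(Intercept)", "Residuals"), , drop = FALSE]
    tab <- data.frame(effect = rownames(a), F = a[["F value"]],
                      df_num = a[["Df"]],
                      df_den = stats::df.residual(fit_lm),
                      p = a[["Pr(>F)"]], stringsAsFactors = FALSE)
    tab$r2_beta_star <- semipartial_r2(tab$F, tab$df_num, tab$df_den)
    varcomp <- c(subject = 0, residual = summary(fit_lm)$sigma^2)
    out <- list(model = fit_lm, anova = tab, coef = stats::coef(fit_lm),
                varcomp = varcomp,
                meta = list(type = "ols", df_method = "residual",
                            singular_fallback = singular_fallback),
                formula = formula, data = data)
  } else {
    a <- stats::anova(fit, type = 3, ddf = df_method)
    tab <- data.frame(effect = rownames(a), F = a[["F value"]],
                      df_num = a[["NumDF"]], df_den = a[["DenDF"]],
                      p = a[["Pr(>F)"]], stringsAsFactors = FALSE)
    tab$r2_beta_star <- semipartial_r2(tab$F, tab$df_num, tab$df_den)
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- stats::setNames(vc$vcov, vc$grp)
    out <- list(model = fit, anova = tab, coef = lme4::fixef(fit),
                varcomp = varcomp,
                meta = list(type = "lmm", df_method = df_method,
                            singular_fallback = FALSE),
                formula = formula, data = data)
  }
  class(out) <- "swc_model_fit"
  out
}

#' @export
print.swc_model_fit <- function(x, ...) {
  cat(sprintf("<swc_model_fit> %s (%s dfs)%s\n", x$meta$type,
              x$meta$df_method,
              if (isTRUE(x$meta$singular_fallback)) " [singular fallback]"
              else ""))
  print(transform(x$anova, F = round(F, 3), df_den = round(df_den, 1),
                  p = signif(p, 3), r2_beta_star = round(r2_beta_star, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Fit the primary coupling-phase association model
#'
#' Dependent variable: per-subject mean cosine of the spindle-onset coupling
#' phase, one row per subject x switcher type. Fixed effects: switcher type,
#' amyloid burden (Centiloid), their interaction, age, sex, total sleep time
#' and the per-type mean slow-wave duration; random intercept per subject.
#' Sex is coded as a factor with `female` as the reference level.
#'
#' @param table long data.frame with columns `subject_id`, `switcher`,
#'   `mean_cos_phase`, `centiloid`, `age`, `sex`, `tst`, `sw_duration`
#'   (>= 20 subjects).
#' @param df_method denominator-df method, see [fit_mixed_model()].
#' @return a [fit_mixed_model()] fit.
#' @export
fit_primary_model <- function(table,
                              df_method = c("Satterthwaite",
                                            "Kenward-Roger")) {
  need <- c("subject_id", "switcher", "mean_cos_phase", "centiloid", "age",
            "sex", "tst", "sw_duration")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (length(unique(table$subject_id)) < 20)
    stop("at least 20 subjects required")
  table$switcher <- factor(table$switcher, levels = c("slow", "fast"))
  table$sex <- factor(table$sex, levels = c("female", "male"))
  fit_mixed_model(
    mean_cos_phase ~ switcher * centiloid + age + sex + tst + sw_duration +
      (1 | subject_id),
    data = table, df_method = match.arg(df_method))
}

#' Per-switcher-type amyloid slopes with family-wise adjustment
#'
#' Post-hoc decomposition of the amyloid-by-type interaction: the slope of
#' the coupling cosine on Centiloid within each switcher type, its t
#' statistic, and a family-adjusted p-value (via estimated marginal trends).
#' The family of per-type slope tests is Sidak-corrected; for the two-level
#' switcher factor this plays the role a Tukey adjustment plays for a single
#' set of pairwise contrasts.
#'
#' @param fit a [fit_primary_model()] fit (must contain the interaction).
#' @param var continuous moderated covariate (default `"centiloid"`).
#' @param by factor defining the groups (default `"switcher"`).
#' @return data.frame: group level, `slope`, `se`, `df`, `t`, `p_adj` (Sidak family correction over the set of per-type
#'   slope tests; with two levels this matches the Tukey-style family
#'   adjustment of a single pairwise set).
#' @export
posthoc_slopes <- function(fit, var = "centiloid", by = "switcher") {
  stopifnot(inherits(fit, "swc_model_fit"))
  terms_ <- attr(stats::terms(lme4::nobars(fit$formula)), "term.labels")
  inter <- grepl(":", terms_) &
    vapply(terms_, function(tl) {
      parts <- strsplit(tl, ":")[[1]]
      var %in% parts && by %in% parts
    }, TRUE)
  if (!any(inter))
    stop("model has no ", by, " x ", var,
         " interaction; per-type slopes are not defined")
  emt <- emmeans::emtrends(fit$model, stats::as.formula(paste("~", by)),
                           var = var)
  tst <- summary(emt, infer = c(FALSE, TRUE), adjust = "sidak")
  data.frame(level = tst[[by]], slope = tst[[paste0(var, ".trend")]],
             se = tst$SE, df = tst$df, t = tst$t.ratio, p_adj = tst$p.value,
             stringsAsFactors = FALSE)
}

#' Leave-one-subject-out Cook's distances on the fixed effects
#'
#' For each subject, refits the model without that subject's rows and
#' computes `D_i = (b - b_i)' V^-1 (b - b_i) / p` where `b` are the full-fit
#' fixed-effect estimates, `V` their covariance and `p` their number.
#' Distances above 1 are flagged as potential outliers.
#'
#' @param fit a [fit_mixed_model()] fit.
#' @param group grouping column name (default `"subject_id"`).
#' @return data.frame: `subject`, `cooks_d`, `flag` (`cooks_d > 1`).
#' @export
cooks_check <- function(fit, group = "subject_id") {
  stopifnot(inherits(fit, "swc_model_fit"))
  data <- fit$data
  subjects <- unique(data[[group]])
  if (length(subjects) < 10)
    warning("fewer than 10 subjects: Cook's distances are unstable")
  if (fit$meta$type == "lmm") {
    b <- lme4::fixef(fit$model)
    V <- as.matrix(stats::vcov(fit$model))
  } else {
    b <- stats::coef(fit$model)
    V <- stats::vcov(fit$model)
  }
  Vinv <- solve(V)
  p <- length(b)
  d <- vapply(subjects, function(s) {
    sub <- data[data[[group]] != s, , drop = FALSE]
    refit <- suppressWarnings(suppressMessages(
      fit_mixed_model(fit$formula, sub,
                      df_method = if (fit$meta$type == "lmm")
                        fit$meta$df_method else "Satterthwaite")))
    bi <- if (refit$meta$type == "lmm") lme4::fixef(refit$model)
          else stats::coef(refit$model)
    db <- b - bi[names(b)]
    as.numeric(t(db) %*% Vinv %*% db) / p
  }, 0)
  data.frame(subject = subjects, cooks_d = d, flag = d > 1,
             stringsAsFactors = FALSE)
}

#' Paired t test on baseline vs follow-up scores
#'
#' @param baseline,followup paired score vectors of equal length (>= 3).
#' @return list with `t`, `df`, `p`, `mean_change` (baseline - follow-up).
#' @export
paired_change_test <- function(baseline, followup) {
  if (length(baseline) != length(followup))
    stop("baseline and follow-up must be paired (equal length)")
  if (length(baseline) < 3) stop("need at least 3 pairs")
  diffs <- baseline - followup
  if (stats::sd(diffs) == 0) {
    return(list(t = 0, df = length(diffs) - 1,
                p = if (all(diffs == 0)) 1 else 0,
                mean_change = mean(diffs)))
  }
  tt <- stats::t.test(baseline, followup, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_change = mean(diffs))
}
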