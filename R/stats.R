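# Group-difference statistics: rank-sum Z tests for skewed performance
# measures, likelihood-ratio contrasts from linear mixed models for the eye
# movement features, phi effect sizes and false-discovery-rate correction.

#' Rank-sum Z test (Mann-Whitney with normal approximation)
#'
#' Two-sided test of a group difference via the Mann-Whitney U statistic and
#' its tie-corrected normal approximation:
#' `Z = |U - n1 n2 / 2| / sqrt(n1 n2 / 12 * ((n + 1) - sum(t^3 - t) / (n (n - 1))))`
#' where `t` are the tie-group sizes. No continuity correction is applied.
#'
#' @param a,b numeric vectors, one per group (each length >= 2).
#' @return list with `statistic` (Z, nonnegative), `statistic_name`, `df`
#'   (`NA`), `p_raw`, and the underlying `U`.
#' @export
ranksum_z <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (n1 < 2L || n2 < 2L) {
    stop_vrgaze("each group needs at least 2 values",
                class = "vrgaze_validation_error")
  }
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(statistic = 0, statistic_name = "Z", df = NA_integer_,
                p_raw = 1, U = U))
  }
  z <- abs(U - n1 * n2 / 2) / sqrt(sigma2)
  list(statistic = z, statistic_name = "Z", df = NA_integer_,
       p_raw = min(1, 2 * pnorm(-z)), U = U)
}

#' Likelihood-ratio group contrast from a linear mixed model
#'
#' Models a scenario-level eye movement feature as a linear function of
#' Group and Task Scenario (fixed effects) with random intercepts for
#' Participant and Task Scenario Order, optionally plus covariates and an
#' invalid-percentage random intercept. The tested term is assessed by a
#' likelihood-ratio chi-square between maximum-likelihood fits with and
#' without that term (fitting delegated to `lme4`).
#'
#' @param features scenario-feature table with columns `participant`,
#'   `group`, `scenario`, `scenario_order` and the response.
#' @param response name of the response column.
#' @param term tested term: `"group"`, `"scenario"` or `"group:scenario"`.
#' @param covariates optional character vector of additional fixed effects.
#' @param random_invalid_pct also include a random intercept of the binned
#'   invalid-sample percentage.
#' @return list with `statistic` (chi-square), `statistic_name`, `df`,
#'   `p_raw`, `effect_phi` (with N = participants in the model), `n`, and a
#'   `singular` flag (result returned with a warning when a fit is singular).
#' @export
lmm_group_contrast <- function(features, response,
                               term = c("group", "scenario", "group:scenario"),
                               covariates = NULL,
                               random_invalid_pct = FALSE) {
  term <- match.arg(term)
  need <- c("participant", "group", "scenario", "scenario_order", response)
  missing <- setdiff(need, names(features))
  if (length(missing)) {
    stop_vrgaze("feature table lacks column(s): %s",
                paste(missing, collapse = ", "),
                class = "vrgaze_validation_error")
  }
  d <- features[stats::complete.cases(features[, need]), need, drop = FALSE]
  names(d)[names(d) == response] <- ".y"
  d$group <- factor(d$group)
  d$scenario <- factor(d$scenario)
  d$scenario_order <- factor(d$scenario_order)
  if (nlevels(d$group) != 2L || min(table(unique(d[, c("participant", "group")])$group)) < 2L) {
    stop_vrgaze("need two groups with >= 2 participants each",
                class = "vrgaze_validation_error")
  }
  n_part <- length(unique(d$participant))

  if (stats::var(d$.y) == 0) {
    return(list(statistic = 0, statistic_name = "chi2",
                df = 0L, p_raw = 1, effect_phi = 0, n = n_part,
                singular = FALSE))
  }

  cov_part <- if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  ran_part <- "(1 | participant) + (1 | scenario_order)"
  if (random_invalid_pct) ran_part <- paste(ran_part, "+ (1 | invalid_bin)")
  if (random_invalid_pct) {
    d$invalid_bin <- factor(cut(features$invalid_pct[match(d$participant,
                                                           features$participant)],
                                breaks = 5))
  }
  fixed_full <- switch(term,
                       "group" = "group + scenario",
                       "scenario" = "group + scenario",
                       "group:scenario" = "group * scenario")
  fixed_red <- switch(term,
                      "group" = "scenario",
                      "scenario" = "group",
                      "group:scenario" = "group + scenario")
  f_full <- as.formula(paste(".y ~", fixed_full, cov_part, "+", ran_part))
  f_red <- as.formula(paste(".y ~", fixed_red, cov_part, "+", ran_part))

  singular <- FALSE
  fit_ml <- function(f) {
    withCallingHandlers(
      suppressMessages(lme4::lmer(f, data = d, REML = FALSE,
                                  control = lme4::lmerControl(calc.derivs = FALSE))),
      warning = function(w) {
        singular <<- TRUE
        invokeRestart("muffleWarning")
      })
  }
  m_full <- fit_ml(f_full)
  m_red <- fit_ml(f_red)
  if (lme4::isSingular(m_full) || lme4::isSingular(m_red)) singular <- TRUE
  a <- anova(m_red, m_full)
  chisq <- max(0, a$Chisq[2])
  df <- as.integer(a$Df[2])
  p <- a$`Pr(>Chisq)`[2]
  if (singular) {
    warning("singular mixed-model fit; likelihood-ratio result returned as-is",
            call. = FALSE)
  }
  list(statistic = chisq, statistic_name = "chi2", df = df, p_raw = p,
       effect_phi = effect_phi(chisq, n_part), n = n_part, singular = singular)
}

#' Phi effect size for a chi-square contrast
#'
#' `phi = sqrt(chi2 / N)` with N the number of participants in the model.
#'
#' @param chi2 chi-square statistic (>= 0).
#' @param n number of participants (> 0).
#' @return phi (nonnegative scalar).
#' @export
effect_phi <- function(chi2, n) {
  assert_scalar_num(chi2, "chi2", 0)
  assert_scalar_num(n, "n", 1)
  sqrt(chi2 / n)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values (monotone, capped at 1, original order
#' restored), applied within one reported family of tests.
#'
#' @param p numeric vector of raw p values in `[0, 1]`.
#' @return adjusted p values.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_vrgaze("p values must lie in [0, 1]", class = "vrgaze_validation_error")
  }
  p.adjust(p, method = "BH")
}
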