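# Statistical stages on an analysis-ready cohort: chi-squared HAC rate
# tables, logistic models for the odds of HAC / in-hospital death /
# 30-day readmission, and Gamma log-link GLMs for cost and length-of-stay
# multipliers. Fits use stats::glm (IRLS); intervals are Wald on the
# exponentiated scale, matching the symmetric intervals conventionally
# printed for such models.

# Paper-style covariate set, as factor columns built by model_frame().
DEFAULT_MODEL_TERMS <- c("sex", "indigenous", "age_band", "seifa",
                         "marital_status", "region_of_birth", "insurance",
                         "acute", "icu", "comorb_cat", "region")

#' Build the regression model frame with reference levels fixed
#'
#' Reference levels: age `<45`, SEIFA `Q1`, marital `divorced_separated`,
#' region of birth `America`, hospital remoteness `major_city`, no
#' comorbidity.
#'
#' @param episodes analysis-ready episode table.
#' @return data.frame of outcome and factor covariate columns.
#' @export
model_frame <- function(episodes) {
  data.frame(
    hac = episodes$hac,
    died_in_hospital = episodes$died_in_hospital,
    readmit30 = episodes$readmit30,
    cost = episodes$cost,
    los = episodes$los,
    sex = factor(episodes$sex, levels = c("female", "male")),
    indigenous = episodes$indigenous,
    age_band = factor(episodes$age_band, levels = AGE_BANDS),
    seifa = factor(paste0("Q", episodes$seifa_quintile),
                   levels = paste0("Q", 1:5)),
    marital_status = factor(episodes$marital_status,
                            levels = MARITAL_LEVELS),
    region_of_birth = factor(episodes$region_of_birth,
                             levels = BIRTH_LEVELS),
    insurance = episodes$insurance,
    acute = episodes$acute,
    icu = episodes$icu,
    comorb_cat = factor(episodes$comorb_cat, levels = COMORB_LEVELS),
    region = factor(episodes$region, levels = REGION_LEVELS),
    stringsAsFactors = FALSE)
}

coef_table <- function(fit, level = 0.95) {
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  data.frame(term = rownames(sm), estimate = est, se = se,
             exp_estimate = exp(est),
             ci_low = exp(est - z * se), ci_high = exp(est + z * se),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' HAC rates by strata with chi-squared tests
#'
#' For each stratifier, the HAC rate per level and a Pearson chi-squared
#' test on the level-by-HAC contingency table (continuity correction
#' off). Stratifiers with a single observed level are reported without a
#' test. Mean outcomes (cost, LOS, death, readmission) by HAC status are
#' appended.
#'
#' @param episodes flagged episode table.
#' @param stratifiers character vector of column names.
#' @return list of class `rate_table`: `rates`, `tests`,
#'   `outcome_means`.
#' @export
rate_table <- function(episodes,
                       stratifiers = c("sex", "indigenous", "age_band",
                                       "seifa_quintile", "marital_status",
                                       "region_of_birth", "insurance",
                                       "acute", "icu", "comorb_cat",
                                       "region")) {
  if (!"hac" %in% names(episodes)) stop("'hac' column missing")
  rates <- list(); tests <- list()
  for (s in stratifiers) {
    if (!s %in% names(episodes)) stop("unknown stratifier: ", s)
    lev <- episodes[[s]]
    tab <- table(lev, factor(episodes$hac, levels = c(FALSE, TRUE)))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    r <- prop.table(tab, 1)[, 2]
    rates[[s]] <- data.frame(stratifier = s, level = rownames(tab),
                             n = as.integer(rowSums(tab)),
                             hac_rate = as.numeric(r),
                             stringsAsFactors = FALSE)
    if (nrow(tab) >= 2 && all(colSums(tab) > 0)) {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      tests[[s]] <- data.frame(stratifier = s,
                               statistic = unname(ct$statistic),
                               df = unname(ct$parameter),
                               p_value = unname(ct$p.value),
                               stringsAsFactors = FALSE)
    } else {
      tests[[s]] <- data.frame(stratifier = s, statistic = NA_real_,
                               df = NA_real_, p_value = NA_real_,
                               stringsAsFactors = FALSE)
    }
  }
  means <- do.call(rbind, lapply(split(episodes, episodes$hac), function(d) {
    data.frame(hac = d$hac[1],
               mean_cost = mean(d$cost),
               mean_los = mean(d$los),
               death_rate = mean(d$died_in_hospital),
               readmit30_rate = if (!is.null(d$readmit30))
                 mean(d$readmit30) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(means) <- NULL
  structure(list(rates = do.call(rbind, c(rates, make.row.names = FALSE)),
                 tests = do.call(rbind, c(tests, make.row.names = FALSE)),
                 outcome_means = means),
            class = "rate_table")
}

#' Fit a logistic regression and report odds ratios
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) with Wald
#' 95% intervals on the odds-ratio scale. Apparent separation (any
#' |coefficient| > 10 on the log-odds scale, or non-convergence within
#' `maxit`) is flagged rather than silently reported.
#'
#' @param data model frame from [model_frame()] (or any data.frame).
#' @param outcome name of a binary outcome column.
#' @param terms covariate names; default is the study covariate set.
#' @param level confidence level.
#' @param maxit IRLS iteration cap.
#' @return list of class `model_fit`: `model`, `family`, `coefficients`
#'   (term, estimate, se, exp_estimate, ci_low, ci_high), `n`,
#'   `converged`.
#' @export
fit_logistic <- function(data, outcome, terms = DEFAULT_MODEL_TERMS,
                         level = 0.95, maxit = 25L) {
  y <- data[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2)
    stop("outcome '", outcome, "' is constant; cannot fit")
  f <- stats::reformulate(terms, response = outcome)
  fit <- suppressWarnings(
    stats::glm(f, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = maxit)))
  converged <- fit$converged && all(abs(stats::coef(fit)) < 10, na.rm = TRUE)
  if (!converged)
    warning("logistic fit for '", outcome,
            "' did not converge cleanly (possible separation)")
  structure(list(model = outcome, family = "logistic",
                 coefficients = coef_table(fit, level),
                 n = stats::nobs(fit), converged = converged, fit = fit),
            class = "model_fit")
}

#' Fit a log-link GLM for a positive outcome (cost or length of stay)
#'
#' Gamma family with log link (default); exponentiated coefficients are
#' multiplicative effects on the mean. Non-positive outcome values are
#' dropped with a reported count; more than 5% non-positive is an error.
#'
#' @inheritParams fit_logistic
#' @param family `"gamma"` (default) or `"quasipoisson"` (a
#'   variance-to-mean alternative sometimes preferred for day counts).
#' @return a `model_fit`; also carries `n_dropped_nonpositive`.
#' @export
fit_glm_log <- function(data, outcome, terms = DEFAULT_MODEL_TERMS,
                        family = c("gamma", "quasipoisson"),
                        level = 0.95, maxit = 25L) {
  family <- match.arg(family)
  y <- data[[outcome]]
  bad <- !is.na(y) & y <= 0
  if (mean(bad) > 0.05)
    stop("more than 5% of '", outcome, "' values are non-positive (",
         sum(bad), "/", length(y), ")")
  use <- data[!bad, , drop = FALSE]
  fam <- if (family == "gamma") stats::Gamma(link = "log")
         else stats::quasipoisson(link = "log")
  f <- stats::reformulate(terms, response = outcome)
  fit <- suppressWarnings(
    stats::glm(f, data = use, family = fam,
               control = stats::glm.control(epsilon = 1e-8, maxit = maxit)))
  if (!fit$converged)
    warning("GLM for '", outcome, "' did not converge")
  structure(list(model = outcome, family = paste0(family, "-log"),
                 coefficients = coef_table(fit, level),
                 n = stats::nobs(fit), converged = fit$converged,
                 n_dropped_nonpositive = sum(bad), fit = fit),
            class = "model_fit")
}

#' Extract one term's exponentiated estimate from a model fit
#'
#' @param fit a `model_fit`.
#' @param term coefficient name (e.g. `"hacTRUE"`).
#' @return named list `estimate`, `ci_low`, `ci_high`.
#' @export
term_effect <- function(fit, term) {
  ct <- fit$coefficients
  i <- match(term, ct$term)
  if (is.na(i)) stop("term '", term, "' not in model '", fit$model, "'")
  list(estimate = ct$exp_estimate[i], ci_low = ct$ci_low[i],
       ci_high = ct$ci_high[i])
}
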