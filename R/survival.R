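#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival estimate, optionally stratified by group. Censored
#' subjects leave the risk set without producing a step.
#'
#' @param time Follow-up times (months), nonnegative.
#' @param event Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param group Optional grouping factor.
#' @return An object of class `"km_curve"`: a data frame with columns
#'   `time`, `survival`, `n_risk`, `n_event` (and `group` when stratified),
#'   plus the underlying `survival::survfit` object in attribute `"fit"`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (length(time) == 0) stop("empty input")
  if (length(time) != length(event)) stop("time and event must have equal length")
  if (any(time < 0, na.rm = TRUE)) stop("times must be nonnegative")
  s <- survival::Surv(time, as.integer(as.logical(event)))
  if (is.null(group)) {
    fit <- survival::survfit(s ~ 1)
    out <- data.frame(time = fit$time, survival = fit$surv,
                      n_risk = fit$n.risk, n_event = fit$n.event)
  } else {
    group <- factor(group)
    fit <- survival::survfit(s ~ group)
    out <- data.frame(time = fit$time, survival = fit$surv,
                      n_risk = fit$n.risk, n_event = fit$n.event,
                      group = factor(rep(sub("^group=", "", names(fit$strata)),
                                         fit$strata), levels = levels(group)))
  }
  attr(out, "fit") <- fit
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve (", nrow(x), " event times)\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Time (months)", ylab = "Survival probability",
                          col = NULL, ...) {
  fit <- attr(x, "fit")
  k <- if ("group" %in% names(x)) nlevels(x$group) else 1
  if (is.null(col)) col <- seq_len(k)
  graphics::plot(fit, xlab = xlab, ylab = ylab, col = col, ...)
  if (k > 1)
    graphics::legend("bottomleft", legend = levels(x$group), col = col,
                     lty = 1, bty = "n")
  invisible(x)
}

#' Log-rank comparison of survival between groups
#'
#' Standard (unweighted) log-rank test across k groups, chi-square reference
#' on k - 1 degrees of freedom.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Grouping factor with at least 2 levels.
#' @return List with `statistic` (chi-square), `df`, `p_value`, and the
#'   per-group observed/expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("at least 2 groups are required")
  ev <- as.integer(as.logical(event))
  if (sum(ev, na.rm = TRUE) == 0) stop("log-rank test requires at least one event")
  sd_ <- survival::survdiff(survival::Surv(time, ev) ~ group)
  df <- length(sd_$n) - 1
  list(statistic = unname(sd_$chisq), df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       observed = sd_$obs, expected = sd_$exp)
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood Cox fit (Efron tie handling) reporting hazard ratios
#' with Wald confidence intervals, for OS or DFS endpoints. In
#' `"multivariate"` mode covariates enter when univariately significant at
#' `entry_p`, mirroring how multivariate prognostic tables are assembled.
#' Monotone-likelihood problems (e.g. a factor level with no events) are
#' flagged via the convergence indicator and a separation flag on extreme
#' coefficients.
#'
#' @param data Data frame with time, event and covariate columns.
#' @param time,event Names of the time and event columns.
#' @param covariates Character vector of covariate names. Ordinal factors
#'   entered as a single per-step term should be supplied as numeric codes
#'   (see [stromal_type_code()]).
#' @param mode `"univariate"` or `"multivariate"`.
#' @param entry_p Univariate entry threshold (default 0.05).
#' @param include Optional explicit multivariate covariate list.
#' @param conf_level Wald CI level (default 0.95).
#' @return Object of class `"cox_fit"`: `table` (term, estimate, hr, ci_low,
#'   ci_high, p_value), `mode`, `covariates`, `n`, `events`, `converged`,
#'   `separation`.
#' @export
cox_fit <- function(data, time, event, covariates,
                    mode = c("univariate", "multivariate"),
                    entry_p = 0.05, include = NULL, conf_level = 0.95) {
  mode <- match.arg(mode)
  data <- as.data.frame(data)
  ev <- as.integer(as.logical(data[[event]]))
  if (sum(ev, na.rm = TRUE) < 1) stop("at least one event is required")
  fit_one <- function(terms) {
    d <- data[, terms, drop = FALSE]
    d$.time <- data[[time]]; d$.event <- ev
    d <- d[stats::complete.cases(d), , drop = FALSE]
    fit <- survival::coxph(
      stats::reformulate(terms, response = "survival::Surv(.time, .event)"),
      data = d, ties = "efron")
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    tab <- .wald_table(cf, se, conf_level)
    names(tab)[names(tab) == "or"] <- "hr"
    list(table = tab, n = fit$n, events = fit$nevent,
         converged = is.null(fit$info) || fit$iter < 100,
         separation = any(abs(cf) > 15))
  }
  if (mode == "univariate") {
    fits <- lapply(covariates, fit_one)
    tab <- do.call(rbind, lapply(fits, `[[`, "table"))
    tab$covariate <- rep(covariates, vapply(fits, function(f) nrow(f$table), 1L))
    res <- list(table = tab, mode = mode, covariates = covariates,
                n = max(vapply(fits, function(f) as.integer(f$n), 1L)),
                events = max(vapply(fits, function(f) as.integer(f$events), 1L)),
                converged = all(vapply(fits, `[[`, TRUE, "converged")),
                separation = any(vapply(fits, `[[`, FALSE, "separation")))
  } else {
    if (is.null(include)) {
      uni <- cox_fit(data, time, event, covariates, mode = "univariate",
                     conf_level = conf_level)
      pmin_by_cov <- tapply(uni$table$p_value, uni$table$covariate, min)
      include <- select_multivariate_covariates(
        data.frame(term = names(pmin_by_cov), p_value = as.numeric(pmin_by_cov)),
        alpha = entry_p)
      include <- covariates[covariates %in% include]
    }
    if (!length(include)) stop("no covariates meet the multivariate entry rule")
    f <- fit_one(include)
    f$table$covariate <- NA_character_
    res <- c(f["table"], list(mode = mode, covariates = include, n = f$n,
                              events = f$events, converged = f$converged,
                              separation = f$separation))
  }
  class(res) <- "cox_fit"
  res
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional hazards (%s, n = %d, events = %d)%s\n",
              x$mode, x$n, x$events,
              if (x$separation) " [monotone likelihood suspected]" else ""))
  tab <- x$table
  for (cl in c("hr", "ci_low", "ci_high", "p_value")) tab[[cl]] <- signif(tab[[cl]], digits)
  print.data.frame(tab[, c("term", "hr", "ci_low", "ci_high", "p_value")],
                   row.names = FALSE)
  invisible(x)
}

#' Select covariates for a multivariate model
#'
#' Returns, in their original order, the covariates whose univariate p-value
#' falls below `alpha`.
#'
#' @param univariate_results Data frame with columns `term` and `p_value`.
#' @param alpha Entry threshold (default 0.05).
#' @return Character vector of selected terms.
#' @export
select_multivariate_covariates <- function(univariate_results, alpha = 0.05) {
  ur <- as.data.frame(univariate_results)
  as.character(ur$term[!is.na(ur$p_value) & ur$p_value < alpha])
}

#' Ordinal coding of stromal type
#'
#' Codes the four stromal types on the prognostic ordering used when the
#' type enters a Cox model as a single per-step term: inflammatory = 0,
#' intermediate = 1, fibrotic = 2, necrotic = 3. Per-level dummy coding is
#' available by passing the factor itself to [cox_fit()].
#'
#' @param stype Factor/character of stromal types.
#' @return Integer codes 0-3.
#' @export
stromal_type_code <- function(stype) {
  map <- c(inflammatory = 0L, intermediate = 1L, fibrotic = 2L, necrotic = 3L)
  s <- as.character(stype)
  bad <- !is.na(s) & !s %in% names(map)
  if (any(bad)) stop("unknown stromal type: ", paste(unique(s[bad]), collapse = ", "))
  unname(map[s])
}
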