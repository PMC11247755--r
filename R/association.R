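#' Round half away from zero
#'
#' Rounds the way clinical tables print percentages (half always up in
#' magnitude), where base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.as_count_table <- function(x) {
  m <- as.matrix(x)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("contingency table must contain nonnegative integer counts")
  storage.mode(m) <- "double"
  m
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's statistic without continuity correction by default: the
#' association p-values reported for this grading system (e.g. lymph-node
#' metastasis vs response) are reproduced only without the Yates correction.
#'
#' @param table An r x c matrix of nonnegative integer counts.
#' @param correct Apply the Yates continuity correction on 2 x 2 tables
#'   (default `FALSE`).
#' @return A list of class `"contingency_result"`: `table`, `statistic`,
#'   `df`, `p_value`, `expected`, `method`.
#' @examples
#' pearson_chi2(matrix(c(20, 17, 114, 34), 2))  # p ~ 0.005
#' @export
pearson_chi2 <- function(table, correct = FALSE) {
  m <- .as_count_table(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square test undefined: a row or column marginal is zero")
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  structure(list(table = m, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 expected = ct$expected, method = "pearson_chi2"),
            class = "contingency_result")
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided p-value by hypergeometric enumeration: with the margins fixed,
#' the probabilities of all tables no more probable than the observed one
#' (up to a relative tolerance of 1e-7 for ties) are summed. Degenerate
#' margins (an empty row or column) leave only one possible table, so p = 1.
#'
#' @param table A 2 x 2 matrix of nonnegative integer counts.
#' @return A `"contingency_result"` list (statistic is the observed
#'   top-left count).
#' @export
fisher_exact <- function(table) {
  m <- .as_count_table(table)
  if (!all(dim(m) == c(2L, 2L))) stop("fisher_exact requires a 2 x 2 table")
  a <- m[1, 1]; r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); k <- sum(m[, 1])
  if (r1 == 0 || r2 == 0 || k == 0 || sum(m[, 2]) == 0) {
    p <- 1
  } else {
    support <- max(0, k - r2):min(k, r1)
    probs <- stats::dhyper(support, r1, r2, k)
    p_obs <- probs[match(a, support)]
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  structure(list(table = m, statistic = a, df = NA_real_, p_value = p,
                 expected = outer(rowSums(m), colSums(m)) / max(sum(m), 1),
                 method = "fisher_exact"),
            class = "contingency_result")
}

#' Choose and run Fisher's exact or the chi-square test
#'
#' Codifies the usual selection rule: Fisher's exact test when any expected
#' cell count is below `threshold` (2 x 2 tables only), Pearson chi-square
#' otherwise. Larger tables with small expected counts fall back to the
#' chi-square test with a warning.
#'
#' @param table An r x c count matrix.
#' @param threshold Expected-count threshold for switching to Fisher
#'   (default 5).
#' @param correct Passed to [pearson_chi2()].
#' @return A `"contingency_result"` with the chosen `method` recorded.
#' @export
select_and_test <- function(table, threshold = 5, correct = FALSE) {
  m <- .as_count_table(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  small <- any(expected < threshold)
  if (small && all(dim(m) == c(2L, 2L))) return(fisher_exact(m))
  if (small)
    warning("expected counts below ", threshold,
            " in an r x c table; using Pearson chi-square")
  pearson_chi2(m, correct = correct)
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("%s: p = %.4g", x$method, x$p_value))
  if (!is.na(x$df)) cat(sprintf(" (statistic %.3f, df %d)", x$statistic, as.integer(x$df)))
  cat("\n")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-distribution approximation. A constant vector has no rank ordering, so
#' `rho` is returned missing with a warning.
#'
#' @param x,y Equal-length numeric vectors (length >= 3 after removing
#'   pairwise missing values).
#' @return List with `rho` and `p_value`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x)[keep]; y <- as.numeric(y)[keep]
  if (length(x) < 3) stop("at least 3 complete pairs are required")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom. When every observation is identical the statistic is defined as
#' 0 with p = 1 (no evidence of any difference).
#'
#' @param values Either a numeric vector (paired with `groups`) or a list of
#'   numeric group vectors.
#' @param groups Grouping factor when `values` is a vector.
#' @return List with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    if (length(values) < 2) stop("at least 2 groups are required")
    if (any(lengths(values) == 0)) stop("every group must be non-empty")
    all_v <- unlist(values, use.names = FALSE)
    k <- length(values)
    if (length(unique(all_v)) == 1)
      return(list(statistic = 0, df = k - 1L, p_value = 1))
    kt <- stats::kruskal.test(values)
  } else {
    groups <- factor(groups)
    if (nlevels(groups) < 2) stop("at least 2 groups are required")
    if (length(unique(values)) == 1)
      return(list(statistic = 0, df = nlevels(groups) - 1L, p_value = 1))
    kt <- stats::kruskal.test(values, groups)
  }
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

# Wald summary table for a fitted glm/coxph: exp(coef) with normal CI.
.wald_table <- function(coefs, ses, conf_level) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = names(coefs),
             estimate = unname(coefs),
             or = exp(unname(coefs)),
             ci_low = exp(unname(coefs) - z * ses),
             ci_high = exp(unname(coefs) + z * ses),
             p_value = 2 * stats::pnorm(-abs(unname(coefs) / ses)),
             row.names = NULL)
}

#' Logistic regression for pathological response
#'
#' Maximum-likelihood logistic regression of good pathological response on
#' clinicopathological covariates, reporting odds ratios with Wald
#' confidence intervals. `mode = "univariate"` fits one model per covariate;
#' `mode = "multivariate"` fits a joint model on the covariates that are
#' univariately significant at `entry_p` (or on an explicit `include` list).
#' Complete or quasi-complete separation is detected and flagged.
#'
#' @param data Data frame holding outcome and covariates.
#' @param outcome Name of the outcome column; a factor/character with the
#'   `positive` level, or a 0/1 numeric (1 = positive).
#' @param covariates Character vector of covariate column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param positive Outcome level modelled as success (default `"good"`).
#' @param entry_p Univariate entry threshold for the multivariate model
#'   (default 0.05).
#' @param include Optional explicit covariate list for the multivariate
#'   model, overriding the entry rule.
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @return An object of class `"logistic_fit"`: `table` (term, estimate, or,
#'   ci_low, ci_high, p_value), `mode`, `covariates`, `n`, `converged`,
#'   `separation`.
#' @export
logistic_fit <- function(data, outcome, covariates,
                         mode = c("univariate", "multivariate"),
                         positive = "good", entry_p = 0.05, include = NULL,
                         conf_level = 0.95) {
  mode <- match.arg(mode)
  data <- as.data.frame(data)
  y_raw <- data[[outcome]]
  y <- if (is.numeric(y_raw)) as.integer(y_raw) else as.integer(as.character(y_raw) == positive)
  if (length(unique(stats::na.omit(y))) < 2)
    stop("outcome must contain both classes")
  fit_one <- function(terms) {
    d <- data[, terms, drop = FALSE]
    d$.y <- y
    d <- d[stats::complete.cases(d), , drop = FALSE]
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(stats::reformulate(terms, response = ".y"), data = d,
                 family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    cf <- stats::coef(fit)[-1]
    se <- sqrt(diag(stats::vcov(fit)))[-1]
    tab <- .wald_table(cf, se, conf_level)
    if (sep || any(abs(cf) > 15)) sep <- TRUE
    list(table = tab, n = nrow(d), converged = fit$converged, separation = sep)
  }
  if (mode == "univariate") {
    fits <- lapply(covariates, fit_one)
    tab <- do.call(rbind, lapply(fits, `[[`, "table"))
    tab$covariate <- rep(covariates, vapply(fits, function(f) nrow(f$table), 1L))
    res <- list(table = tab, mode = mode, covariates = covariates,
                n = max(vapply(fits, function(f) as.integer(f$n), 1L)),
                converged = all(vapply(fits, `[[`, TRUE, "converged")),
                separation = any(vapply(fits, `[[`, FALSE, "separation")))
  } else {
    if (is.null(include)) {
      uni <- logistic_fit(data, outcome, covariates, mode = "univariate",
                          positive = positive, conf_level = conf_level)
      pmin_by_cov <- tapply(uni$table$p_value, uni$table$covariate, min)
      include <- covariates[covariates %in% names(pmin_by_cov)[pmin_by_cov < entry_p]]
    }
    if (!length(include)) stop("no covariates meet the multivariate entry rule")
    f <- fit_one(include)
    f$table$covariate <- NA_character_
    res <- c(f[c("table")], list(mode = mode, covariates = include,
                                 n = f$n, converged = f$converged,
                                 separation = f$separation))
  }
  class(res) <- "logistic_fit"
  res
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic regression (%s, n = %d)%s\n", x$mode, x$n,
              if (x$separation) " [separation detected]" else ""))
  tab <- x$table
  tab$or <- signif(tab$or, digits); tab$ci_low <- signif(tab$ci_low, digits)
  tab$ci_high <- signif(tab$ci_high, digits); tab$p_value <- signif(tab$p_value, digits)
  print.data.frame(tab[, c("term", "or", "ci_low", "ci_high", "p_value")],
                   row.names = FALSE)
  invisible(x)
}

#' Baseline-characteristics summary table stratified by response
#'
#' Builds a "Table 1"-style summary: for each categorical variable, counts
#' and column percentages by good/poor response group, with an association
#' p-value chosen by [select_and_test()]. Missing values appear as an
#' explicit `NA` row and are excluded from the test (complete-case).
#' Percentages are printed rounded half-up to one decimal.
#'
#' @param data Cohort data frame.
#' @param variables Character vector of categorical variable names.
#' @param group Name of the stratifying column (two levels, e.g.
#'   `good`/`poor`).
#' @param threshold Expected-count threshold passed to [select_and_test()].
#' @return Data frame of class `"table1"` with columns `variable`, `level`,
#'   `n_total`, `n_good`, `pct_good`, `n_poor`, `pct_poor`, `method`,
#'   `p_value` (the p-value attached to each variable's first row).
#' @export
build_table1 <- function(data, variables, group, threshold = 5) {
  data <- as.data.frame(data)
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("the stratifier must have exactly 2 levels")
  n_by <- table(g)
  if (any(n_by == 0)) stop("empty stratum: ", names(n_by)[n_by == 0])
  n1 <- n_by[[1]]; n2 <- n_by[[2]]; n <- length(g)
  rows <- list()
  rows[[1]] <- data.frame(variable = "All cases", level = "",
                          n_total = n,
                          n_good = n1, pct_good = round_half_up(100 * n1 / n),
                          n_poor = n2, pct_poor = round_half_up(100 * n2 / n),
                          method = "", p_value = NA_real_)
  for (v in variables) {
    x <- data[[v]]
    if (is.null(x)) stop("unknown variable: ", v)
    x <- factor(x)
    has_na <- anyNA(x)
    tab <- table(x, g)
    test <- if (nrow(tab) >= 2) select_and_test(tab, threshold = threshold) else NULL
    lv <- rownames(tab)
    if (has_na) {
      tab <- rbind(tab, "NA" = table(g[is.na(x)]))
      lv <- c(lv, "NA")
    }
    vr <- data.frame(variable = v, level = lv,
                     n_total = rowSums(tab),
                     n_good = tab[, 1], pct_good = round_half_up(100 * tab[, 1] / n1),
                     n_poor = tab[, 2], pct_poor = round_half_up(100 * tab[, 2] / n2),
                     method = "", p_value = NA_real_, row.names = NULL)
    if (!is.null(test)) {
      vr$method[1] <- test$method
      vr$p_value[1] <- test$p_value
    }
    rows[[length(rows) + 1]] <- vr
  }
  out <- do.call(rbind, rows)
  class(out) <- c("table1", "data.frame")
  out
}

#' @export
print.table1 <- function(x, ...) {
  y <- as.data.frame(x)
  y$p_value <- ifelse(is.na(y$p_value), "", formatC(y$p_value, format = "f", digits = 3))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
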