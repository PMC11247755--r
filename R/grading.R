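#' Four-tier pathological response grading
#'
#' Grades response to neoadjuvant chemotherapy from the percentage of
#' residual viable tumor in the tumor bed: complete pathological response
#' (cPR) when no viable tumor remains; major (mPR) for viable tumor in
#' (0, 10\]; partial (pPR) for (10, 50\]; no response (nPR) above 50.
#'
#' Thresholds are compared with exact arithmetic on the stored value (no
#' epsilon): inputs are rater-estimated percentages, so 10 means 10.
#'
#' @param viable_pct Numeric vector of residual viable tumor percentages in
#'   \[0, 100\]. `NA` propagates.
#' @return An ordered factor with levels `cPR < mPR < pPR < nPR`.
#' @examples
#' classify_pathological_response(c(0, 5, 15, 65))
#' @export
classify_pathological_response <- function(viable_pct) {
  v <- as.numeric(viable_pct)
  if (any(v < 0 | v > 100, na.rm = TRUE))
    stop("viable_pct must lie in [0, 100]")
  g <- ifelse(is.na(v), NA_character_,
       ifelse(v == 0, "cPR",
       ifelse(v <= 10, "mPR",
       ifelse(v <= 50, "pPR", "nPR"))))
  factor(g, levels = c("cPR", "mPR", "pPR", "nPR"), ordered = TRUE)
}

#' Good/poor binarization of the response grade
#'
#' Patients achieving cPR, mPR or pPR are the good-response group; nPR is the
#' poor-response group.
#'
#' @param grade A factor or character vector of grades (`cPR`, `mPR`, `pPR`,
#'   `nPR`), e.g. from [classify_pathological_response()].
#' @return A factor with levels `good`, `poor`.
#' @export
response_group <- function(grade) {
  g <- as.character(grade)
  bad <- !is.na(g) & !g %in% c("cPR", "mPR", "pPR", "nPR")
  if (any(bad)) stop("unknown response grade: ", paste(unique(g[bad]), collapse = ", "))
  factor(ifelse(is.na(g), NA_character_, ifelse(g == "nPR", "poor", "good")),
         levels = c("good", "poor"))
}

#' Post-treatment stromal typing of the tumor bed
#'
#' Types the tumor-bed stroma from the three non-viable components. A
#' component is dominant when its proportion exceeds BOTH others by strictly
#' more than `margin` percentage points (inflammatory, fibrotic or necrotic
#' type accordingly); when all pairwise absolute differences are at most
#' `margin` the bed is intermediate type. Configurations satisfying neither
#' rule (e.g. 45/36/19) have no dominant component and fall back to
#' intermediate; these rows are flagged in the `"fallback"` attribute for
#' audit.
#'
#' By default the three non-viable components are renormalized to sum to 100
#' before comparison, so typing is invariant to the viable fraction;
#' `renormalize = FALSE` compares the raw percentages instead.
#'
#' @param x A composition (length-4 vector, data frame or `"tumor_bed"`).
#' @param margin Dominance margin in percentage points (default 10).
#' @param renormalize Renormalize the non-viable components to 100 before
#'   comparison (default `TRUE`).
#' @return A factor with levels `inflammatory`, `fibrotic`, `necrotic`,
#'   `intermediate`; attribute `"fallback"` is a logical vector marking rows
#'   typed intermediate only by fallback. Rows whose non-viable components
#'   are all zero (viable tumor 100%) return `NA`.
#' @examples
#' classify_stromal_type(c(0, 20, 60, 20))  # inflammatory dominance
#' @export
classify_stromal_type <- function(x, margin = 10, renormalize = TRUE) {
  x <- normalize_composition(x)
  nec <- x$necrosis_pct; inf_ <- x$inflammatory_pct; fib <- x$fibrotic_pct
  tot <- nec + inf_ + fib
  if (renormalize) {
    sc <- ifelse(tot > 0, 100 / tot, NA_real_)
    nec <- nec * sc; inf_ <- inf_ * sc; fib <- fib * sc
  } else {
    none <- tot <= 0
    nec[none] <- NA_real_; inf_[none] <- NA_real_; fib[none] <- NA_real_
  }
  type <- rep(NA_character_, nrow(x))
  fallback <- rep(FALSE, nrow(x))
  dom_inf <- inf_ - pmax(fib, nec) > margin
  dom_fib <- fib - pmax(inf_, nec) > margin
  dom_nec <- nec - pmax(inf_, fib) > margin
  inter <- abs(inf_ - fib) <= margin & abs(inf_ - nec) <= margin &
    abs(fib - nec) <= margin
  ok <- !is.na(nec)
  type[ok & dom_inf] <- "inflammatory"
  type[ok & dom_fib] <- "fibrotic"
  type[ok & dom_nec] <- "necrotic"
  type[ok & inter & is.na(type)] <- "intermediate"
  rest <- ok & is.na(type)
  type[rest] <- "intermediate"
  fallback[rest] <- TRUE
  out <- factor(type, levels = c("inflammatory", "fibrotic", "necrotic",
                                 "intermediate"))
  attr(out, "fallback") <- fallback
  out
}
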