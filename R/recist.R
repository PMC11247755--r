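#' Percent change in the longest tumor diameter
#'
#' Reduction is `100 * (pre - post) / pre`; negative values indicate growth.
#'
#' @param pre,post Longest diameters before / after treatment, in the same
#'   unit; `pre` must be positive.
#' @return Percent reduction (may be negative).
#' @export
percent_diameter_change <- function(pre, post) {
  pre <- as.numeric(pre); post <- as.numeric(post)
  if (any(pre <= 0, na.rm = TRUE)) stop("pre-treatment diameter must be positive")
  if (any(post < 0, na.rm = TRUE)) stop("diameters must be nonnegative")
  100 * (pre - post) / pre
}

#' Three-category radiological response (RECIST-style)
#'
#' Categorizes the radiological response used alongside the pathological
#' grading: complete response (CR) for complete tumor resolution, partial
#' response (PR) for a strictly greater than 30% decrease in the longest
#' diameter, and stable disease (SD) for everything else -- including any
#' increase. This mirrors the three-category scheme used with this cohort;
#' `strict = TRUE` restores the full RECIST v1.1 four-category scheme in
#' which a > 20% increase is progressive disease (PD).
#'
#' @param pre,post Longest diameters (same unit); unit cancels.
#' @param complete_resolution Logical; `TRUE` forces CR (and implies
#'   `post == 0`).
#' @param strict Add a PD category for > 20% increase (default `FALSE`).
#' @return A factor `CR`/`PR`/`SD` (plus `PD` when `strict`), with the
#'   percent reduction in attribute `"reduction_pct"`.
#' @examples
#' classify_recist(50, 30)            # 40% decrease -> PR
#' classify_recist(50, 70)            # 40% increase -> SD
#' @export
classify_recist <- function(pre, post, complete_resolution = NULL,
                            strict = FALSE) {
  pre <- as.numeric(pre); post <- as.numeric(post)
  n <- max(length(pre), length(post))
  pre <- rep_len(pre, n); post <- rep_len(post, n)
  if (is.null(complete_resolution)) complete_resolution <- post == 0
  complete_resolution <- rep_len(as.logical(complete_resolution), n)
  if (any(complete_resolution & post != 0, na.rm = TRUE))
    stop("complete resolution implies a post-treatment diameter of 0")
  red <- percent_diameter_change(pre, post)
  lev <- if (strict) c("CR", "PR", "SD", "PD") else c("CR", "PR", "SD")
  cat_ <- ifelse(is.na(red) & !complete_resolution, NA_character_,
          ifelse(complete_resolution, "CR",
          ifelse(red > 30, "PR",
          ifelse(strict & red < -20, "PD", "SD"))))
  out <- factor(cat_, levels = lev)
  attr(out, "reduction_pct") <- red
  out
}

#' Pathological reduction
#'
#' The pathological analogue of radiological shrinkage, paired with the
#' diameter reduction in correlation analyses. The default definition is
#' `100 - residual viable tumor %`; the alternative `"biopsy_delta"` uses the
#' drop from the pre-treatment biopsy tumor content to the residual viable
#' percentage.
#'
#' @param viable_pct Residual viable tumor percentage(s) from the resection.
#' @param tumor_content_pre Pre-treatment biopsy tumor content, required for
#'   `method = "biopsy_delta"`.
#' @param method `"complement"` (default, `100 - viable`) or
#'   `"biopsy_delta"`.
#' @return Percent pathological reduction; missing inputs propagate.
#' @export
pathological_reduction <- function(viable_pct, tumor_content_pre = NULL,
                                   method = c("complement", "biopsy_delta")) {
  method <- match.arg(method)
  v <- as.numeric(viable_pct)
  if (any(v < 0 | v > 100, na.rm = TRUE)) stop("viable_pct must lie in [0, 100]")
  if (method == "complement") return(100 - v)
  if (is.null(tumor_content_pre))
    stop("tumor_content_pre is required for method = 'biopsy_delta'")
  as.numeric(tumor_content_pre) - v
}
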