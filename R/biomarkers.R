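#' Tumor-infiltrating lymphocyte volume (TILV)
#'
#' TILV combines how much stroma a tumor contains with how densely that
#' stroma is infiltrated: `TILV = stroma in tumor (%) x stromal TILs (%)`,
#' giving a score in \[0, 10000\].
#'
#' @param stroma_pct Percentage of the tumor occupied by stroma, in
#'   \[0, 100\].
#' @param stromal_tils_pct Percentage of the stromal area occupied by
#'   lymphocytes, in \[0, 100\].
#' @return Numeric TILV score(s).
#' @examples
#' compute_tilv(30, 80)  # 2400
#' compute_tilv(50, 5)   # 250
#' @export
compute_tilv <- function(stroma_pct, stromal_tils_pct) {
  s <- as.numeric(stroma_pct); t <- as.numeric(stromal_tils_pct)
  if (any(s < 0 | s > 100, na.rm = TRUE) || any(t < 0 | t > 100, na.rm = TRUE))
    stop("percentages must lie in [0, 100]")
  s * t
}

#' Grade stromal TILs into low / intermediate / high
#'
#' Low when at most 5%, intermediate on (5, 50\], high above 50%.
#'
#' @param stromal_tils_pct Stromal TILs percentage(s) in \[0, 100\].
#' @return Ordered factor `low < intermediate < high`.
#' @export
grade_stromal_tils <- function(stromal_tils_pct) {
  t <- as.numeric(stromal_tils_pct)
  if (any(t < 0 | t > 100, na.rm = TRUE))
    stop("stromal_tils_pct must lie in [0, 100]")
  g <- ifelse(is.na(t), NA_character_,
       ifelse(t <= 5, "low", ifelse(t <= 50, "intermediate", "high")))
  factor(g, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

#' Immune-cell density from high-power-field counts
#'
#' Cell densities are counted in three randomly selected high-power fields
#' (HPFs) in the peritumoral stroma; the density is the mean count divided by
#' the HPF area.
#'
#' @param hpf_counts A numeric vector of exactly 3 counts, or an `n x 3`
#'   matrix/data frame (one row per specimen).
#' @param hpf_area_mm2 Area of one HPF in mm^2; the default 0.2376 is a
#'   common 40x objective field.
#' @return Density in cells/mm^2 (one value per specimen).
#' @examples
#' compute_ihc_density(c(30, 40, 50), 0.24)  # 166.67
#' @export
compute_ihc_density <- function(hpf_counts, hpf_area_mm2 = 0.2376) {
  if (is.null(dim(hpf_counts))) hpf_counts <- matrix(hpf_counts, nrow = 1)
  m <- as.matrix(hpf_counts)
  if (ncol(m) != 3L) stop("exactly 3 HPF counts are required per specimen")
  if (any(m < 0, na.rm = TRUE)) stop("HPF counts must be nonnegative")
  if (any(hpf_area_mm2 <= 0)) stop("hpf_area_mm2 must be positive")
  rowMeans(m) / hpf_area_mm2
}

#' T-cell ratio markers with high/low calls
#'
#' Computes the CD4/CD8 and CD8/FOXP3 density ratios and dichotomizes them at
#' the supplied cutoffs (`high` when the ratio strictly exceeds the cutoff).
#' A zero denominator with a positive numerator yields `Inf`; 0/0 yields
#' `NA`.
#'
#' @param cd8_density,cd4_density,foxp3_density Nonnegative densities
#'   (cells/mm^2).
#' @param cutoffs Named numeric vector with elements `cd4_cd8` and
#'   `cd8_foxp3`; the defaults 2.17 and 5.24 are cohort-derived and always
#'   recomputable from data via [youden_cutoff()].
#' @return Data frame with columns `cd4_cd8_ratio`, `cd8_foxp3_ratio`,
#'   `cd4_cd8_high`, `cd8_foxp3_high` (factors `low`/`high`).
#' @export
compute_ratio_markers <- function(cd8_density, cd4_density, foxp3_density,
                                  cutoffs = c(cd4_cd8 = 2.17, cd8_foxp3 = 5.24)) {
  d <- cbind(cd8 = as.numeric(cd8_density), cd4 = as.numeric(cd4_density),
             foxp3 = as.numeric(foxp3_density))
  if (any(d < 0, na.rm = TRUE)) stop("densities must be nonnegative")
  safe_ratio <- function(num, den) {
    r <- num / den                      # x/0 -> Inf
    r[num == 0 & den == 0] <- NA_real_  # 0/0 -> missing
    r
  }
  r1 <- safe_ratio(d[, "cd4"], d[, "cd8"])
  r2 <- safe_ratio(d[, "cd8"], d[, "foxp3"])
  hl <- function(r, cut) factor(ifelse(is.na(r), NA_character_,
                                       ifelse(r > cut, "high", "low")),
                                levels = c("low", "high"))
  data.frame(cd4_cd8_ratio = r1, cd8_foxp3_ratio = r2,
             cd4_cd8_high = hl(r1, cutoffs[["cd4_cd8"]]),
             cd8_foxp3_high = hl(r2, cutoffs[["cd8_foxp3"]]))
}

#' PD-L1 CPS, TPS and IPS scoring
#'
#' Standard PD-L1 scores from already-dichotomized cell counts:
#' \itemize{
#'   \item CPS = 100 x (positive tumor cells + positive immune cells) /
#'     viable tumor cells, capped at 100;
#'   \item TPS = 100 x positive tumor cells / viable tumor cells;
#'   \item IPS (also written ICS) = 100 x positive immune cells / total
#'     immune cells.
#' }
#' A score is PD-L1 positive when at least 1. Zero denominators yield a
#' missing score, never zero.
#'
#' @param pdl1_pos_tumor,pdl1_pos_immune Counts of PD-L1 positive tumor /
#'   immune cells.
#' @param viable_tumor_cells Total viable tumor cells (CPS/TPS denominator).
#' @param total_immune_cells Total immune cells (IPS denominator).
#' @return Data frame with columns `cps`, `tps`, `ips` and logical
#'   `cps_pos`, `tps_pos`, `ips_pos`.
#' @export
compute_pdl1_scores <- function(pdl1_pos_tumor, pdl1_pos_immune,
                                viable_tumor_cells, total_immune_cells) {
  pt <- as.numeric(pdl1_pos_tumor); pi_ <- as.numeric(pdl1_pos_immune)
  vt <- as.numeric(viable_tumor_cells); ti <- as.numeric(total_immune_cells)
  if (any(c(pt, pi_, vt, ti) < 0, na.rm = TRUE))
    stop("cell counts must be nonnegative")
  den_t <- ifelse(!is.na(vt) & vt >= 1, vt, NA_real_)
  den_i <- ifelse(!is.na(ti) & ti >= 1, ti, NA_real_)
  cps <- pmin(100, 100 * (pt + pi_) / den_t)
  tps <- 100 * pt / den_t
  ips <- 100 * pi_ / den_i
  data.frame(cps = cps, tps = tps, ips = ips,
             cps_pos = cps >= 1, tps_pos = tps >= 1, ips_pos = ips >= 1)
}

#' Youden-index cutpoint for a continuous marker
#'
#' Dichotomizes a marker at the cutoff maximizing sensitivity + specificity
#' on the ROC curve for predicting good pathological response, where values
#' strictly greater than the cutoff call "high" (= predicted good). Candidate
#' cutoffs are the observed unique marker values; ties in the objective are
#' broken toward the smallest cutoff.
#'
#' @param values Numeric marker values.
#' @param labels Response labels, coercible to the levels in `positive` /
#'   its complement (typically `good` / `poor`).
#' @param positive The label treated as the positive (predicted-by-high)
#'   class; default `"good"`.
#' @return A list of class `"cutpoint"`: `cutoff`, `youden`, `sensitivity`,
#'   `specificity`, `direction`.
#' @export
youden_cutoff <- function(values, labels, positive = "good") {
  v <- as.numeric(values); lab <- as.character(labels)
  keep <- !is.na(v) & !is.na(lab)
  v <- v[keep]; lab <- lab[keep]
  if (length(v) != length(lab)) stop("values and labels must have equal length")
  pos <- lab == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  cand <- sort(unique(v))
  n_pos <- sum(pos); n_neg <- sum(!pos)
  sens <- vapply(cand, function(c) sum(v[pos] > c) / n_pos, numeric(1))
  spec <- vapply(cand, function(c) sum(v[!pos] <= c) / n_neg, numeric(1))
  j <- sens + spec - 1
  # ties (within numerical noise; true J values are spaced by at least
  # 1/(n_pos*n_neg)) break toward the smallest cutoff
  best <- which(j >= max(j) - 1e-9)[1]
  structure(list(cutoff = cand[best], youden = j[best],
                 sensitivity = sens[best], specificity = spec[best],
                 direction = "greater_is_high"),
            class = "cutpoint")
}

#' @export
print.cutpoint <- function(x, ...) {
  cat(sprintf("Youden cutpoint: > %.4g calls high (J = %.3f; sens %.3f, spec %.3f)\n",
              x$cutoff, x$youden, x$sensitivity, x$specificity))
  invisible(x)
}

#' Dichotomize a marker at a cutoff
#'
#' `high` when the value strictly exceeds the cutoff, `low` otherwise (the
#' cutoff itself is low); missing values propagate.
#'
#' @param values Numeric marker values.
#' @param cutoff Finite cutoff (e.g. from [youden_cutoff()]).
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize_marker <- function(values, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  v <- as.numeric(values)
  factor(ifelse(is.na(v), NA_character_, ifelse(v > cutoff, "high", "low")),
         levels = c("low", "high"))
}
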