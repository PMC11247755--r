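#' Construct a tumor-bed composition table
#'
#' A tumor bed is the region of a resection specimen where the pre-treatment
#' tumor sat. Its area is partitioned into four components -- viable tumor,
#' necrosis, inflammatory stroma and fibrotic stroma -- whose percentages sum
#' to 100.
#'
#' @param viable_pct,necrosis_pct,inflammatory_pct,fibrotic_pct Numeric
#'   vectors of component percentages, each in \[0, 100\].
#' @param normalize If `TRUE`, rows are rescaled to sum to 100 instead of
#'   being required to already do so.
#' @return A data frame of class `"tumor_bed"` with the four component
#'   columns; every row sums to 100.
#' @examples
#' tumor_bed(10, 20, 30, 40)
#' tumor_bed(1, 1, 1, 1, normalize = TRUE)  # scaled to 25/25/25/25
#' @export
tumor_bed <- function(viable_pct, necrosis_pct, inflammatory_pct, fibrotic_pct,
                      normalize = FALSE) {
  x <- data.frame(viable_pct = as.numeric(viable_pct),
                  necrosis_pct = as.numeric(necrosis_pct),
                  inflammatory_pct = as.numeric(inflammatory_pct),
                  fibrotic_pct = as.numeric(fibrotic_pct))
  if (any(is.na(as.matrix(x))))
    stop("tumor-bed components must be non-missing numerics")
  if (any(as.matrix(x) < 0))
    stop("tumor-bed components must be nonnegative")
  tot <- rowSums(x)
  if (normalize) {
    if (any(tot <= 0))
      stop("empty tumor bed: all four components are zero")
    x[] <- 100 * x / tot
  } else {
    if (any(abs(tot - 100) > 1e-6))
      stop("tumor-bed components must sum to 100 (use normalize = TRUE to rescale)")
    if (any(as.matrix(x) > 100 + 1e-9))
      stop("tumor-bed components must be <= 100")
  }
  class(x) <- c("tumor_bed", "data.frame")
  x
}

# Coerce a data.frame/matrix/length-4 vector into the canonical component
# data frame, without the sum-to-100 requirement (validation happens in the
# caller where appropriate).
.as_composition <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != 4L)
      stop("a bare numeric composition must have exactly 4 components")
    x <- as.data.frame(as.list(stats::setNames(x, COMPONENTS)))
  }
  x <- as.data.frame(x)
  missing_cols <- setdiff(COMPONENTS, names(x))
  if (length(missing_cols))
    stop("composition is missing columns: ", paste(missing_cols, collapse = ", "))
  x[COMPONENTS]
}

#' Normalize raw component values to a 100% composition
#'
#' Rescales four nonnegative component measurements so they sum to exactly
#' 100 while preserving their ratios.
#'
#' @param x A length-4 numeric vector, or a data frame / matrix with columns
#'   `viable_pct`, `necrosis_pct`, `inflammatory_pct`, `fibrotic_pct` (one row
#'   per tumor bed).
#' @return A `"tumor_bed"` data frame whose rows sum to 100.
#' @examples
#' normalize_composition(c(1, 1, 1, 1))
#' @export
normalize_composition <- function(x) {
  x <- .as_composition(x)
  m <- as.matrix(x)
  if (any(is.na(m))) stop("composition contains missing values")
  if (any(m < 0)) stop("composition components must be nonnegative")
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("empty tumor bed: all four components are zero")
  out <- as.data.frame(100 * m / tot)
  class(out) <- c("tumor_bed", "data.frame")
  out
}

#' Average per-slide compositions into one specimen-level composition
#'
#' Every slide on which the tumor bed can be recognized contributes one
#' composition estimate; the specimen-level composition is the component-wise
#' arithmetic mean, renormalized to 100.
#'
#' @param slides A data frame with the four component columns, one row per
#'   slide. May contain a `specimen_id` column.
#' @param by Optional column name to aggregate by (defaults to
#'   `"specimen_id"` when present); when absent all rows are averaged into a
#'   single composition.
#' @return A `"tumor_bed"` data frame, one row per specimen (with a
#'   `specimen_id` attribute column when aggregating), rows summing to 100.
#' @export
average_slide_compositions <- function(slides, by = NULL) {
  slides <- as.data.frame(slides)
  if (nrow(slides) == 0L) stop("no slides to average")
  if (is.null(by) && "specimen_id" %in% names(slides)) by <- "specimen_id"
  comp <- .as_composition(slides)
  if (any(is.na(as.matrix(comp)))) stop("slide compositions contain missing values")
  if (is.null(by)) {
    out <- normalize_composition(as.data.frame(as.list(colMeans(comp))))
    return(out)
  }
  ids <- slides[[by]]
  agg <- stats::aggregate(comp, by = list(id = ids), FUN = mean)
  out <- normalize_composition(agg[COMPONENTS])
  out$specimen_id <- agg$id
  out
}

#' Round a composition to reporting increments
#'
#' Component percentages are reported in 5% increments when the component is
#' at least 10%, and as single-digit (integer) percentages when below 10%.
#' After rounding, any discrepancy from 100 is repaired by a largest-remainder
#' adjustment: the component whose rounding moved it furthest in the needed
#' direction is stepped by its own increment (5 or 1) until the total is 100,
#' with ties broken in the fixed order viable, necrosis, inflammatory,
#' fibrotic.
#'
#' @param x A composition (vector, data frame or `"tumor_bed"`), rows summing
#'   to 100.
#' @return A `"tumor_bed"` data frame on the reporting grid, rows summing to
#'   exactly 100.
#' @examples
#' round_composition_to_increments(c(12, 18, 33, 37))   # -> 10 20 35 35
#' round_composition_to_increments(c(3.4, 6.6, 45, 45)) # -> 3 7 45 45
#' @export
round_composition_to_increments <- function(x) {
  x <- normalize_composition(x)
  m <- as.matrix(x)
  out <- m
  for (i in seq_len(nrow(m))) {
    raw <- m[i, ]
    unit <- ifelse(raw < 10, 1, 5)
    r <- round(raw / unit) * unit
    # Repair in two phases, stepping the component with the largest
    # favorable remainder (which.max takes the first maximum, giving the
    # fixed-order tie-break). Phase 1 clears the non-multiple-of-5 residue
    # with 1-point steps on single-digit components; such components must
    # exist whenever the residue is nonzero, since 5%-grid components can
    # only shift the total by multiples of 5. Phase 2 closes the remaining
    # multiple-of-5 gap with 5-point steps.
    guard <- 0L
    repeat {  # phase 1: 1-point steps, single-digit components kept in [0, 10]
      res <- (100 - sum(r)) %% 5
      if (res == 0 || guard > 50L) break
      can_add <- any(unit == 1 & r < 10)
      can_sub <- any(unit == 1 & r > 0)
      dir <- if ((res <= 5 - res && can_add) || !can_sub) 1 else -1
      ok <- unit == 1 & (if (dir > 0) r < 10 else r > 0)
      resid <- if (dir > 0) raw - r else r - raw
      resid[!ok] <- -Inf
      j <- which.max(resid)
      r[j] <- r[j] + dir
      guard <- guard + 1L
    }
    while (sum(r) != 100 && guard < 100L) {  # phase 2: 5-point steps
      diff <- 100 - sum(r)
      resid <- if (diff > 0) raw - r else r - raw
      ok <- unit == 5 & (r + sign(diff) * 5) >= 0 & (r + sign(diff) * 5) <= 100
      resid[!ok] <- -Inf
      j <- which.max(resid)
      r[j] <- r[j] + sign(diff) * 5
      guard <- guard + 1L
    }
    if (sum(r) != 100) {  # unreachable in practice; conservation is the hard invariant
      j <- which.max(raw)
      r[j] <- r[j] + (100 - sum(r))
    }
    out[i, ] <- r
  }
  out <- as.data.frame(out)
  class(out) <- c("tumor_bed", "data.frame")
  out
}

#' @export
print.tumor_bed <- function(x, ...) {
  cat("Tumor-bed composition (", nrow(x), " specimen",
      if (nrow(x) != 1) "s", ")\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
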