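# Columns that must parse as numerics when present in an input CSV.
.NUMERIC_COLS <- c(COMPONENTS, "stroma_pct", "stromal_tils_pct", "tilv",
                   "ki67_pct", "tumor_content_pre",
                   "cd8_hpf1", "cd8_hpf2", "cd8_hpf3",
                   "cd4_hpf1", "cd4_hpf2", "cd4_hpf3",
                   "foxp3_hpf1", "foxp3_hpf2", "foxp3_hpf3",
                   "pdl1_pos_tumor", "pdl1_pos_immune",
                   "viable_tumor_cells", "total_immune_cells",
                   "pre_diameter_mm", "post_diameter_mm",
                   "os_time", "os_event", "dfs_time", "dfs_event")

.check_numeric <- function(df, what) {
  for (cl in intersect(names(df), .NUMERIC_COLS)) {
    if (is.numeric(df[[cl]]) || is.logical(df[[cl]])) next
    v <- suppressWarnings(as.numeric(as.character(df[[cl]])))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "NA")
    if (length(bad))
      stop(sprintf("malformed numeric in %s column '%s' at row(s) %s",
                   what, cl, paste(utils::head(bad, 5), collapse = ", ")))
    df[[cl]] <- v
  }
  df
}

#' Read and merge a cohort from per-stage CSV files
#'
#' Reads any subset of the canonical input tables -- resection slides
#' (keyed by `specimen_id`), biopsy markers, radiology, clinicopathological
#' covariates and survival outcomes (keyed by `patient_id`) -- validates
#' them, and merges on `patient_id`. Slide tables are carried along
#' unaggregated (attribute `"slides"`); [run_pipeline()] performs the
#' averaging. Missing values use the token `NA`; unmatched ids across files
#' produce a warning, duplicated ids an error.
#'
#' @param slides,biopsy,radiology,covariates,outcomes Optional CSV paths.
#' @param merged Optionally, a single canonical merged cohort CSV (as
#'   written by [write_cohort()]).
#' @return A data frame of class `"cohort"`.
#' @export
read_cohort <- function(slides = NULL, biopsy = NULL, radiology = NULL,
                        covariates = NULL, outcomes = NULL, merged = NULL) {
  rd <- function(path, what) {
    if (!file.exists(path)) stop("file not found: ", path)
    .check_numeric(utils::read.csv(path, na.strings = "NA",
                                   stringsAsFactors = FALSE), what)
  }
  slide_df <- NULL
  if (!is.null(slides)) {
    slide_df <- rd(slides, "slides")
    if (!"specimen_id" %in% names(slide_df))
      stop("slide table requires a specimen_id column")
  }
  parts <- list()
  for (what in c("biopsy", "radiology", "covariates", "outcomes", "merged")) {
    path <- get(what)
    if (is.null(path)) next
    df <- rd(path, what)
    if (!"patient_id" %in% names(df))
      stop(what, " table requires a patient_id column")
    dup <- df$patient_id[duplicated(df$patient_id)]
    if (length(dup))
      stop("duplicated patient_id in ", what, ": ",
           paste(unique(dup), collapse = ", "))
    parts[[what]] <- df
  }
  if (length(parts)) {
    out <- Reduce(function(a, b) {
      miss_a <- setdiff(a$patient_id, b$patient_id)
      miss_b <- setdiff(b$patient_id, a$patient_id)
      if (length(miss_a) || length(miss_b))
        warning("unmatched patient ids across input files: ",
                paste(utils::head(c(miss_a, miss_b), 5), collapse = ", "))
      merge(a, b, by = "patient_id", all = TRUE)
    }, parts)
  } else if (!is.null(slide_df)) {
    out <- data.frame(patient_id = unique(slide_df$specimen_id))
  } else {
    stop("no input files supplied")
  }
  attr(out, "slides") <- slide_df
  attr(out, "provenance") <- list(stage = "read_cohort",
                                  sources = list(slides = slides, biopsy = biopsy,
                                                 radiology = radiology,
                                                 covariates = covariates,
                                                 outcomes = outcomes, merged = merged))
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write a cohort to the canonical merged CSV
#'
#' @param cohort A cohort data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "NA")
  invisible(path)
}

.append_provenance <- function(report, stage, params = list()) {
  report$provenance[[length(report$provenance) + 1]] <-
    c(list(stage = stage), params)
  report
}

#' Run the full pathological-response analysis pipeline
#'
#' Executes, in order and as far as the available columns allow: slide
#' averaging; response grading and good/poor binarization; stromal typing;
#' marker scoring (TILV, TILs grade, IHC densities, ratios, PD-L1);
#' radiological categorization; Youden cutpoint estimation for TILV; the
#' stratified baseline table; univariate/multivariate logistic regression;
#' and Kaplan-Meier / log-rank / Cox survival analysis for OS and DFS by
#' response group and stromal type. Every stage appends to the provenance
#' log.
#'
#' @param cohort A `"cohort"` data frame (from [generate_cohort()] or
#'   [read_cohort()]), or a bare data frame with the canonical columns.
#' @param tilv_cutoff TILV dichotomization cut for the table/regressions
#'   (default 75).
#' @param tils_cutoff Stromal-TILs cut for the high/low table row
#'   (default 5).
#' @param hpf_area_mm2 HPF area for density conversion (default 0.2376).
#' @param entry_p Multivariate entry threshold (default 0.05).
#' @param stromal_margin Dominance margin for stromal typing (default 10).
#' @param renormalize_stroma Renormalize non-viable components before
#'   typing (default `TRUE`).
#' @return An object of class `"pathresp_report"`: the augmented cohort and
#'   every stage result that could be computed, plus the provenance log.
#' @export
run_pipeline <- function(cohort, tilv_cutoff = 75, tils_cutoff = 5,
                         hpf_area_mm2 = 0.2376, entry_p = 0.05,
                         stromal_margin = 10, renormalize_stroma = TRUE) {
  slides <- attr(cohort, "slides")
  d <- as.data.frame(cohort)
  report <- list(provenance = list())
  prov0 <- attr(cohort, "provenance")
  if (!is.null(prov0)) report$provenance[[1]] <- prov0

  # 1. slide averaging
  if (!is.null(slides)) {
    avg <- average_slide_compositions(slides)
    idx <- match(d$patient_id, avg$specimen_id)
    if (anyNA(idx))
      stop("patients without slides: ",
           paste(utils::head(d$patient_id[is.na(idx)], 5), collapse = ", "))
    d[COMPONENTS] <- avg[idx, COMPONENTS]
    report <- .append_provenance(report, "average_slides",
                                 list(n_slides = nrow(slides)))
  }

  # 2. grading and stromal typing
  if (all(COMPONENTS %in% names(d))) {
    d$grade <- classify_pathological_response(d$viable_pct)
    d$response <- response_group(d$grade)
    st <- classify_stromal_type(d[COMPONENTS], margin = stromal_margin,
                                renormalize = renormalize_stroma)
    d$stromal_type <- st
    d$stromal_fallback <- attr(st, "fallback")
    d$stromal_code <- stromal_type_code(d$stromal_type)
    report <- .append_provenance(report, "grade",
                                 list(margin = stromal_margin,
                                      renormalize = renormalize_stroma))
  } else if ("viable_pct" %in% names(d)) {
    d$grade <- classify_pathological_response(d$viable_pct)
    d$response <- response_group(d$grade)
    report <- .append_provenance(report, "grade", list(composition = FALSE))
  }

  # 3. marker scoring
  if (all(c("stroma_pct", "stromal_tils_pct") %in% names(d))) {
    d$tilv <- compute_tilv(d$stroma_pct, d$stromal_tils_pct)
    d$tils_grade <- grade_stromal_tils(d$stromal_tils_pct)
    d$tils_high <- dichotomize_marker(d$stromal_tils_pct, tils_cutoff)
    d$tilv_high <- dichotomize_marker(d$tilv, tilv_cutoff)
    report <- .append_provenance(report, "score_tilv",
                                 list(tilv_cutoff = tilv_cutoff,
                                      tils_cutoff = tils_cutoff))
  }
  if (all(c("cd8_hpf1", "cd8_hpf2", "cd8_hpf3") %in% names(d))) {
    d$cd8_density <- compute_ihc_density(d[, paste0("cd8_hpf", 1:3)], hpf_area_mm2)
    d$cd4_density <- compute_ihc_density(d[, paste0("cd4_hpf", 1:3)], hpf_area_mm2)
    d$foxp3_density <- compute_ihc_density(d[, paste0("foxp3_hpf", 1:3)], hpf_area_mm2)
    d <- cbind(d, compute_ratio_markers(d$cd8_density, d$cd4_density,
                                        d$foxp3_density))
    report <- .append_provenance(report, "score_ihc",
                                 list(hpf_area_mm2 = hpf_area_mm2))
  }
  if (all(c("pdl1_pos_tumor", "pdl1_pos_immune", "viable_tumor_cells",
            "total_immune_cells") %in% names(d))) {
    d <- cbind(d, compute_pdl1_scores(d$pdl1_pos_tumor, d$pdl1_pos_immune,
                                      d$viable_tumor_cells, d$total_immune_cells))
    report <- .append_provenance(report, "score_pdl1")
  }

  # 4. radiological categorization
  if (all(c("pre_diameter_mm", "post_diameter_mm") %in% names(d))) {
    cr <- if ("complete_resolution" %in% names(d))
      as.logical(d$complete_resolution) else NULL
    rec <- classify_recist(d$pre_diameter_mm, d$post_diameter_mm, cr)
    d$recist <- rec
    d$radiological_reduction <- attr(rec, "reduction_pct")
    if ("viable_pct" %in% names(d))
      d$pathological_reduction <- pathological_reduction(d$viable_pct)
    report <- .append_provenance(report, "recist")
  }

  two_groups <- !is.null(d$response) && all(table(d$response) > 0)

  # 5. Youden cutpoint for TILV
  if (!is.null(d$tilv) && two_groups) {
    report$tilv_cutpoint <- youden_cutoff(d$tilv, d$response)
    report <- .append_provenance(report, "youden_cutpoint")
  }

  covs <- intersect(c("lymph_node_metastatic", "vascular_invasion",
                      "parametrium_invasion", "nerve_bundle_invasion",
                      "tils_high", "tilv_high"), names(d))

  # 6. stratified baseline table
  if (two_groups && length(covs)) {
    report$table1 <- build_table1(d, covs, "response")
    report <- .append_provenance(report, "table1", list(variables = covs))
  }

  # 7. logistic regression
  num_covs <- covs[vapply(covs, function(v)
    length(unique(stats::na.omit(as.integer(factor(d[[v]]))))) > 1, TRUE)]
  if (two_groups && length(num_covs)) {
    ld <- d
    for (v in num_covs) ld[[v]] <- as.integer(factor(ld[[v]])) - 1L
    report$logistic_univariate <- logistic_fit(ld, "response", num_covs,
                                               mode = "univariate")
    report$logistic_multivariate <- tryCatch(
      logistic_fit(ld, "response", num_covs, mode = "multivariate",
                   entry_p = entry_p),
      error = function(e) NULL)
    report <- .append_provenance(report, "logistic", list(entry_p = entry_p))
  }

  # 8. survival analysis
  for (ep in c("os", "dfs")) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (!all(c(tcol, ecol) %in% names(d))) next
    if (sum(d[[ecol]], na.rm = TRUE) == 0) next
    surv <- list()
    if (two_groups) {
      surv$km_response <- km_estimate(d[[tcol]], d[[ecol]], d$response)
      surv$logrank_response <- logrank_test(d[[tcol]], d[[ecol]], d$response)
    }
    if (!is.null(d$stromal_type) && nlevels(droplevels(d$stromal_type)) > 1) {
      surv$km_stromal <- km_estimate(d[[tcol]], d[[ecol]], d$stromal_type)
      surv$logrank_stromal <- logrank_test(d[[tcol]], d[[ecol]], d$stromal_type)
    }
    cox_covs <- c(if (!is.null(d$stromal_code)) "stromal_code",
                  if (two_groups) "response_good", num_covs)
    if (two_groups) d$response_good <- as.integer(d$response == "good")
    if (length(cox_covs)) {
      surv$cox_univariate <- cox_fit(d, tcol, ecol, cox_covs,
                                     mode = "univariate")
      surv$cox_multivariate <- tryCatch(
        cox_fit(d, tcol, ecol, cox_covs, mode = "multivariate",
                entry_p = entry_p),
        error = function(e) NULL)
    }
    report[[ep]] <- surv
    report <- .append_provenance(report, paste0("survival_", ep))
  }

  attr(d, "slides") <- slides
  class(d) <- c("cohort", "data.frame")
  report$cohort <- d
  class(report) <- "pathresp_report"
  report
}

#' @export
print.pathresp_report <- function(x, ...) {
  d <- x$cohort
  cat("Pathological-response pipeline report\n")
  cat(sprintf("  patients: %d; stages run: %d\n", nrow(d),
              length(x$provenance)))
  if (!is.null(d$grade)) {
    tg <- table(d$grade)
    cat("  response grades:",
        paste(sprintf("%s %d", names(tg), tg), collapse = ", "), "\n")
    gf <- mean(d$response == "good", na.rm = TRUE)
    cat(sprintf("  good response: %.1f%%\n", 100 * gf))
  }
  if (!is.null(d$stromal_type)) {
    ts <- table(d$stromal_type)
    cat("  stromal types:",
        paste(sprintf("%s %d", names(ts), ts), collapse = ", "), "\n")
  }
  if (!is.null(x$tilv_cutpoint))
    cat(sprintf("  TILV Youden cutoff: %.3g\n", x$tilv_cutpoint$cutoff))
  if (!is.null(x$dfs$cox_multivariate)) {
    tab <- x$dfs$cox_multivariate$table
    i <- match("stromal_code", tab$term)
    if (!is.na(i))
      cat(sprintf("  DFS stromal-type HR/step: %.3f (%.3f-%.3f)\n",
                  tab$hr[i], tab$ci_low[i], tab$ci_high[i]))
  }
  invisible(x)
}

#' @export
summary.pathresp_report <- function(object, ...) {
  print(object)
  if (!is.null(object$table1)) {
    cat("\n")
    print(object$table1)
  }
  invisible(object)
}
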