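# Small deterministic fixtures mirroring the published worked examples and
# printed table marginals. These are in-code so tests and the acceptance
# script need no external files; generate_fixture_suite() writes them out as
# CSVs for use from other tools.

#' Seven-patient chemo-immunotherapy worked-example fixture
#'
#' A resection slide table for the seven-patient neoadjuvant
#' chemo-immunotherapy cohort used as a classification worked example:
#' residual viable tumor of 0, 5, 5, 5, 5, 15 and 65 percent. Grading yields
#' 1 cPR, 4 mPR, 1 pPR and 1 nPR (good-response fraction 6/7). Non-viable
#' components are split deterministically.
#'
#' @return A slide-level data frame (`specimen_id`, `slide_id`, four
#'   component columns).
#' @export
nacit_fixture <- function() {
  viable <- c(0, 5, 5, 5, 5, 15, 65)
  rest <- 100 - viable
  data.frame(specimen_id = sprintf("N%d", seq_along(viable)),
             slide_id = 1L,
             viable_pct = viable,
             necrosis_pct = rest * 0.2,
             inflammatory_pct = rest * 0.5,
             fibrotic_pct = rest * 0.3)
}

#' 185-record response-marginal fixture
#'
#' Deterministic residual-viable-tumor percentages placing 27, 49, 58 and 51
#' records in the cPR (0), mPR ((0,10\]), pPR ((10,50\]) and nPR ((50,100\])
#' intervals respectively, matching the published cohort marginals
#' (good response 134/185 = 72.4%).
#'
#' @return Data frame with `patient_id` and `viable_pct`.
#' @export
response_marginal_fixture <- function() {
  viable <- c(rep(0, 27),
              seq(0.2, 10, length.out = 49),
              seq(10.5, 50, length.out = 58),
              seq(51, 100, length.out = 51))
  data.frame(patient_id = sprintf("M%03d", seq_along(viable)),
             viable_pct = viable)
}

#' Published contingency-table fixtures
#'
#' The good/poor cross-tabulations printed for lymph-node metastasis
#' (20/114 vs 17/34) and vascular invasion (21/113 vs 16/35).
#'
#' @return Named list of 2 x 2 count matrices (rows: yes/no; columns:
#'   good/poor).
#' @export
table1_contingency_fixture <- function() {
  list(
    lymph_node_metastatic = matrix(c(20, 114, 17, 34), nrow = 2,
                                   dimnames = list(c("yes", "no"), c("good", "poor"))),
    vascular_invasion = matrix(c(21, 113, 16, 35), nrow = 2,
                               dimnames = list(c("yes", "no"), c("good", "poor"))))
}

#' Published radiological response counts
#'
#' Cohort-level RECIST category counts (CR 19, PR 149, SD 17; objective
#' response rate 90.8%) and the breakdown within the 27 pathological
#' complete responders (6 CR, 21 PR).
#'
#' @return List with `cohort` (named counts) and `cpr_subgroup` (named
#'   counts).
#' @export
recist_count_fixture <- function() {
  list(cohort = c(CR = 19, PR = 149, SD = 17),
       cpr_subgroup = c(CR = 6, PR = 21))
}

#' Published PD-L1 and ratio-marker counts
#'
#' Group counts for PD-L1 CPS positivity (100/134 good, 41/51 poor) and
#' CD8/FOXP3-high prevalence (99/134 good, 21/51 poor).
#'
#' @return Named list of 2 x 2 count matrices (rows: positive-or-high /
#'   negative-or-low; columns: good/poor).
#' @export
pdl1_count_fixture <- function() {
  list(
    cps = matrix(c(100, 34, 41, 10), nrow = 2,
                 dimnames = list(c("positive", "negative"), c("good", "poor"))),
    cd8_foxp3 = matrix(c(99, 35, 21, 30), nrow = 2,
                       dimnames = list(c("high", "low"), c("good", "poor"))))
}

#' Toy survival fixture
#'
#' A six-subject survival set with mixed censoring whose product-limit
#' estimate is hand-checkable.
#'
#' @return Data frame with `time` (months) and `event`.
#' @export
toy_survival_fixture <- function() {
  data.frame(time = c(1, 2, 3, 4, 5, 6),
             event = c(1, 0, 1, 1, 0, 1))
}

#' Write the fixture suite to a directory
#'
#' Emits every in-code fixture as a plain CSV: the seven-patient slide set,
#' the 185-record response marginals, the contingency tables (long format),
#' the radiological counts and the toy survival set.
#'
#' @param outdir Output directory; created if absent.
#' @return Invisibly, the vector of files written.
#' @export
generate_fixture_suite <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character(0)
  w <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  w(nacit_fixture(), "nacit_slides.csv")
  w(response_marginal_fixture(), "response_marginals.csv")
  ct <- table1_contingency_fixture()
  long <- do.call(rbind, lapply(names(ct), function(v) {
    m <- ct[[v]]
    data.frame(variable = v, level = rownames(m),
               n_good = m[, "good"], n_poor = m[, "poor"], row.names = NULL)
  }))
  w(long, "table1_contingency.csv")
  rc <- recist_count_fixture()
  w(data.frame(scope = rep(c("cohort", "cpr_subgroup"),
                           c(length(rc$cohort), length(rc$cpr_subgroup))),
               category = c(names(rc$cohort), names(rc$cpr_subgroup)),
               count = c(rc$cohort, rc$cpr_subgroup)),
    "recist_counts.csv")
  pd <- pdl1_count_fixture()
  long2 <- do.call(rbind, lapply(names(pd), function(v) {
    m <- pd[[v]]
    data.frame(marker = v, level = rownames(m),
               n_good = m[, "good"], n_poor = m[, "poor"], row.names = NULL)
  }))
  w(long2, "pdl1_counts.csv")
  w(toy_survival_fixture(), "toy_survival.csv")
  invisible(files)
}
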