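#' Configuration for the synthetic cohort generator
#'
#' Bundles every distributional assumption of [generate_cohort()]. Defaults
#' emulate the published structure of a 185-patient neoadjuvant-chemotherapy
#' cohort: the four-category response mixture (27/49/58/51), the stromal-type
#' mixture (53/59/5/67 over 184 typed beds), a TILV-high -> good-response
#' logistic link with odds ratio 2.375 (equivalently, the published
#' conditional prevalences 114/134 and 36/51 at the TILV > 75 cut), immune
#' densities centered on the published group means, and stromal-type
#' proportional-hazards survival links with per-step hazard ratios 3.749
#' (OS) and 4.719 (DFS).
#'
#' @param n Cohort size (>= 4).
#' @param seed Default RNG seed used by [generate_cohort()].
#' @param response_probs Length-4 mixture over grades cPR/mPR/pPR/nPR.
#' @param stromal_type_probs Length-4 mixture over stromal types
#'   inflammatory/fibrotic/necrotic/intermediate.
#' @param slides_per_patient Integer range (min, max) of reviewed slides.
#' @param slide_concentration Dirichlet concentration of per-slide
#'   composition noise around the patient-level composition (larger =
#'   tighter inter-slide agreement).
#' @param tilv_or Odds ratio linking TILV-high to good response.
#' @param tilv_cutoff TILV dichotomization cut (high strictly above).
#' @param p_tilv_high_poor P(TILV high | poor response); together with
#'   `tilv_or` this fixes P(TILV high | good) on the logit scale.
#' @param os_hr_per_step,dfs_hr_per_step Hazard ratio per ordinal stromal
#'   step (inflammatory = 0 ... necrotic = 3).
#' @param baseline_hazard_os,baseline_hazard_dfs Events/month at stromal
#'   step 0.
#' @param censor_rate Target censored fraction of the OS endpoint;
#'   independent exponential censoring is calibrated to it.
#' @param hpf_area_mm2 High-power-field area used to convert the published
#'   mean densities into Poisson count means.
#' @param density_means Named list of per-group mean densities (cells/mm^2)
#'   for cd8/cd4/foxp3, each `c(good = , poor = )`.
#' @param cps_pos_rate P(PD-L1 CPS positive) per group, `c(good=, poor=)`.
#' @param covariate_prevalences Named list of per-group Bernoulli
#'   prevalences, `c(good = , poor = )`, for binary covariates.
#' @param radiology_k,radiology_sd_mm Slope and noise (mm) of the
#'   radiological link `post = pre * (1 - k * pathological_reduction/100)` +
#'   noise; chosen to give a positive pathological-radiological rank
#'   correlation.
#' @param p_cr_given_cpr P(radiological complete resolution | cPR).
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n = 185,
                          seed = 1L,
                          response_probs = c(cPR = 27, mPR = 49, pPR = 58, nPR = 51) / 185,
                          stromal_type_probs = c(inflammatory = 53, fibrotic = 59,
                                                 necrotic = 5, intermediate = 67) / 184,
                          slides_per_patient = c(2L, 4L),
                          slide_concentration = 300,
                          tilv_or = 2.375,
                          tilv_cutoff = 75,
                          p_tilv_high_poor = 36 / 51,
                          os_hr_per_step = 3.749,
                          dfs_hr_per_step = 4.719,
                          baseline_hazard_os = 0.0015,
                          baseline_hazard_dfs = 0.0025,
                          censor_rate = 0.30,
                          hpf_area_mm2 = 0.2376,
                          density_means = list(
                            cd8 = c(good = 450.3, poor = 356.7),
                            cd4 = c(good = 436.9, poor = 374.3),
                            foxp3 = c(good = 47.7, poor = 65.2)),
                          cps_pos_rate = c(good = 100 / 134, poor = 41 / 51),
                          covariate_prevalences = list(
                            lymph_node_metastatic = c(good = 20 / 134, poor = 17 / 51),
                            vascular_invasion = c(good = 21 / 134, poor = 16 / 51),
                            parametrium_invasion = c(good = 5 / 134, poor = 4 / 51),
                            nerve_bundle_invasion = c(good = 5 / 134, poor = 5 / 51)),
                          radiology_k = 0.85,
                          radiology_sd_mm = 4,
                          p_cr_given_cpr = 6 / 27) {
  stopifnot(n >= 4, length(response_probs) == 4, length(stromal_type_probs) == 4)
  if (abs(sum(response_probs) - 1) > 1e-8 || any(response_probs < 0))
    stop("response_probs must be a probability 4-vector summing to 1")
  if (abs(sum(stromal_type_probs) - 1) > 1e-8 || any(stromal_type_probs < 0))
    stop("stromal_type_probs must be a probability 4-vector summing to 1")
  stopifnot(os_hr_per_step > 0, dfs_hr_per_step > 0,
            baseline_hazard_os > 0, baseline_hazard_dfs > 0,
            censor_rate >= 0, censor_rate < 1, tilv_or > 0,
            p_tilv_high_poor > 0, p_tilv_high_poor < 1)
  # recurrence hazard = dfs hazard - os hazard must stay positive at every step
  steps <- 0:3
  if (any(baseline_hazard_dfs * dfs_hr_per_step^steps <=
          baseline_hazard_os * os_hr_per_step^steps))
    stop("DFS hazard must exceed the OS hazard at every stromal step")
  cfg <- as.list(environment())
  cfg$steps <- NULL
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d, seed = %d\n", x$n, as.integer(x$seed)))
  cat("  response mixture:", paste(sprintf("%s %.3f", names(x$response_probs),
                                           x$response_probs), collapse = ", "), "\n")
  cat(sprintf("  TILV link: OR %.3f at cut > %g\n", x$tilv_or, x$tilv_cutoff))
  cat(sprintf("  survival links: OS HR/step %.3f, DFS HR/step %.3f, censoring %.0f%%\n",
              x$os_hr_per_step, x$dfs_hr_per_step, 100 * x$censor_rate))
  invisible(x)
}

# One Dirichlet draw per row via gamma normalization; zero shape gives an
# exact zero component.
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Draw a 3-part (necrosis, inflammatory, fibrotic) stroma composition of the
# requested type by accept-reject against the typing rule itself.
.draw_stroma_of_type <- function(type, margin = 10) {
  base <- switch(type,
    inflammatory = c(nec = 0.18, inf = 0.62, fib = 0.20),
    fibrotic     = c(nec = 0.18, inf = 0.20, fib = 0.62),
    necrotic     = c(nec = 0.62, inf = 0.20, fib = 0.18),
    intermediate = c(nec = 1 / 3, inf = 1 / 3, fib = 1 / 3))
  conc <- if (type == "intermediate") 250 else 40
  for (i in 1:200) {
    p <- 100 * as.vector(.rdirichlet(1, conc * base))
    ok <- switch(type,
      inflammatory = p[2] - max(p[1], p[3]) > margin,
      fibrotic     = p[3] - max(p[1], p[2]) > margin,
      necrotic     = p[1] - max(p[2], p[3]) > margin,
      intermediate = max(abs(diff(p)), abs(p[1] - p[3])) <= margin)
    if (ok) return(p)
  }
  stop("failed to draw a stroma composition of type ", type)  # unreachable in practice
}

#' Generate a synthetic neoadjuvant-chemotherapy cohort
#'
#' Draws a full per-patient cohort carrying the statistical structure the
#' downstream analyses assume, so every pipeline stage can be exercised
#' end to end:
#' \itemize{
#'   \item a response grade from the configured four-category mixture, with
#'     residual viable tumor drawn uniformly within the grade's interval
#'     (0; (0,10\]; (10,50\]; (50,100));
#'   \item per-slide tumor-bed compositions (Dirichlet noise around the
#'     patient-level composition); the patient-level composition, grade and
#'     stromal type recorded in the table are re-derived from the slide
#'     average, so the cohort is internally consistent;
#'   \item pre-treatment markers whose TILV-high indicator follows the
#'     configured logistic link to the realized good/poor group, and immune
#'     densities/PD-L1 counts centered on the configured group means;
#'   \item radiology diameters with a positive pathological-radiological
#'     association;
#'   \item exponential OS/DFS times under proportional hazards in the
#'     realized ordinal stromal type, with DFS embedded as
#'     min(recurrence, death) so `dfs_time <= os_time` holds exactly, and
#'     independent exponential censoring calibrated to the target rate.
#' }
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed; defaults to `config$seed`. Identical config + seed
#'   reproduce the cohort exactly.
#' @return A data frame of class `"cohort"`, one row per patient, with the
#'   slide-level table in attribute `"slides"` and generation metadata in
#'   attribute `"provenance"`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  n <- config$n
  grades <- c("cPR", "mPR", "pPR", "nPR")
  drawn_grade <- sample(grades, n, replace = TRUE, prob = config$response_probs)
  viable <- numeric(n)
  viable[drawn_grade == "mPR"] <- stats::runif(sum(drawn_grade == "mPR"), 0, 10)
  viable[drawn_grade == "pPR"] <- stats::runif(sum(drawn_grade == "pPR"), 10, 50)
  viable[drawn_grade == "nPR"] <- stats::runif(sum(drawn_grade == "nPR"), 50, 100)

  drawn_type <- sample(names(config$stromal_type_probs), n, replace = TRUE,
                       prob = config$stromal_type_probs)
  stroma3 <- t(vapply(drawn_type, .draw_stroma_of_type, numeric(3)))
  patient_comp <- cbind(viable_pct = viable,
                        necrosis_pct = (100 - viable) * stroma3[, 1] / 100,
                        inflammatory_pct = (100 - viable) * stroma3[, 2] / 100,
                        fibrotic_pct = (100 - viable) * stroma3[, 3] / 100)

  # slides: Dirichlet noise around the patient composition
  n_slides <- sample(seq(config$slides_per_patient[1], config$slides_per_patient[2]),
                     n, replace = TRUE)
  slide_rows <- vector("list", n)
  for (i in seq_len(n)) {
    alpha <- config$slide_concentration * patient_comp[i, ] / 100
    s <- 100 * .rdirichlet(n_slides[i], alpha)
    slide_rows[[i]] <- data.frame(specimen_id = sprintf("P%03d", i),
                                  slide_id = seq_len(n_slides[i]),
                                  viable_pct = s[, 1], necrosis_pct = s[, 2],
                                  inflammatory_pct = s[, 3], fibrotic_pct = s[, 4])
  }
  slides <- do.call(rbind, slide_rows)

  # realized patient-level composition and labels, re-derived from slides
  avg <- average_slide_compositions(slides)
  avg <- avg[match(sprintf("P%03d", seq_len(n)), avg$specimen_id), ]
  grade <- classify_pathological_response(avg$viable_pct)
  group <- response_group(grade)
  stype <- classify_stromal_type(avg[COMPONENTS])
  good <- group == "good"

  # TILV: binary link on the realized group, continuous values consistent
  # with the cut
  p_high_poor <- config$p_tilv_high_poor
  p_high_good <- stats::plogis(stats::qlogis(p_high_poor) + log(config$tilv_or))
  tilv_high <- stats::rbinom(n, 1, ifelse(good, p_high_good, p_high_poor)) == 1
  stroma_pct <- stats::runif(n, 30, 70)
  lower <- config$tilv_cutoff / stroma_pct  # TILs % at which TILV crosses the cut
  tils_pct <- ifelse(tilv_high,
                     stats::runif(n, lower, 100),
                     stats::runif(n, 0, lower))
  tilv <- stroma_pct * tils_pct

  # IHC counts: Poisson around the configured group mean densities
  lam <- function(marker) {
    mu <- config$density_means[[marker]]
    ifelse(good, mu[["good"]], mu[["poor"]]) * config$hpf_area_mm2
  }
  hpf <- function(marker) {
    l <- lam(marker)
    matrix(stats::rpois(3 * n, rep(l, each = 3)), ncol = 3, byrow = TRUE)
  }
  cd8 <- hpf("cd8"); cd4 <- hpf("cd4"); foxp3 <- hpf("foxp3")

  # PD-L1 counts: positive-cell totals Poisson with rate matched to the
  # configured CPS positivity per group (P(total >= 1) = 1 - exp(-lambda))
  p_pos <- ifelse(good, config$cps_pos_rate[["good"]], config$cps_pos_rate[["poor"]])
  lam_pdl1 <- -log(1 - p_pos)
  pos_tumor <- stats::rpois(n, 0.75 * lam_pdl1)
  pos_immune <- stats::rpois(n, 0.25 * lam_pdl1)
  viable_cells <- round(stats::runif(n, 50, 100))
  immune_cells <- round(stats::runif(n, 30, 120))

  # radiology: positive link to pathological reduction
  pre_d <- stats::runif(n, 40, 80)
  path_red <- pathological_reduction(avg$viable_pct)
  post_d <- pmax(1, pre_d * (1 - config$radiology_k * path_red / 100) +
                   stats::rnorm(n, 0, config$radiology_sd_mm))
  complete_res <- grade == "cPR" & stats::runif(n) < config$p_cr_given_cpr
  post_d[complete_res] <- 0

  # binary clinicopathological covariates
  covs <- lapply(config$covariate_prevalences, function(p) {
    stats::rbinom(n, 1, ifelse(good, p[["good"]], p[["poor"]]))
  })

  # survival: exponential PH in the realized ordinal stromal type; DFS is
  # min(recurrence, death) so dfs_time <= os_time holds by construction
  code <- stromal_type_code(stype)
  code[is.na(code)] <- 3L  # all-viable beds (no stroma): treat as worst step
  h_os <- config$baseline_hazard_os * config$os_hr_per_step^code
  h_dfs <- config$baseline_hazard_dfs * config$dfs_hr_per_step^code
  t_os <- stats::rexp(n, h_os)
  t_rec <- stats::rexp(n, h_dfs - h_os)
  t_dfs <- pmin(t_rec, t_os)
  if (config$censor_rate > 0) {
    # calibrate the exponential censoring rate so the expected OS censored
    # fraction over the realized hazards equals the target
    f <- function(logc) mean(exp(logc) / (exp(logc) + h_os)) - config$censor_rate
    logc <- stats::uniroot(f, c(-25, 10))$root
    cens <- stats::rexp(n, exp(logc))
  } else {
    cens <- rep(Inf, n)
  }
  os_time <- pmin(t_os, cens); os_event <- as.integer(t_os <= cens)
  dfs_time <- pmin(t_dfs, cens); dfs_event <- as.integer(t_dfs <= cens)

  cohort <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    grade = grade, response = group,
    avg[COMPONENTS],
    stromal_type = stype,
    stroma_pct = stroma_pct, stromal_tils_pct = tils_pct,
    tilv = tilv, tilv_high = as.integer(tilv_high),
    ki67_pct = stats::runif(n, 5, 95),
    tumor_content_pre = stats::runif(n, 50, 95),
    cd8_hpf1 = cd8[, 1], cd8_hpf2 = cd8[, 2], cd8_hpf3 = cd8[, 3],
    cd4_hpf1 = cd4[, 1], cd4_hpf2 = cd4[, 2], cd4_hpf3 = cd4[, 3],
    foxp3_hpf1 = foxp3[, 1], foxp3_hpf2 = foxp3[, 2], foxp3_hpf3 = foxp3[, 3],
    pdl1_pos_tumor = pos_tumor, pdl1_pos_immune = pos_immune,
    viable_tumor_cells = viable_cells, total_immune_cells = immune_cells,
    pre_diameter_mm = pre_d, post_diameter_mm = post_d,
    complete_resolution = as.integer(complete_res),
    os_time = os_time, os_event = os_event,
    dfs_time = dfs_time, dfs_event = dfs_event)
  for (nm in names(covs)) cohort[[nm]] <- covs[[nm]]
  attr(cohort, "slides") <- slides
  attr(cohort, "provenance") <- list(
    stage = "generate_cohort", seed = as.integer(seed), config = config,
    timestamp = NA)  # timestamp deliberately unset: byte-identical reruns
  class(cohort) <- c("cohort", "data.frame")
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients\n", nrow(x)))
  if (!is.null(x$grade)) {
    cat("  response grades: ")
    print(table(x$grade))
  }
  invisible(x)
}
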