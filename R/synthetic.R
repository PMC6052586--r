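# Synthetic paired-eye cohort generator.
#
# Emulates a bilateral-cataract study population: per-patient latent biometry
# shared by the two eyes plus eye-level deviation (variance split chosen so
# the population interocular Pearson correlation hits the target), surgical
# power selection against a mild myopic target with grid rounding, and
# correlated postoperative refraction noise standing in for every error
# source other than the lens power itself.

#' Specify the statistical targets of a synthetic paired-eye cohort
#'
#' Defaults reproduce the bilateral study population the analysis assumes:
#' 40 patients, pooled biometry marginals (keratometry 44.4 (1.36) D,
#' anterior chamber depth 3.15 (0.36) mm, axial length 23.43 (0.70) mm),
#' interocular R-squared targets 0.926 / 0.893 / 0.934 for K / ACD / AL,
#' implanted powers restricted to 15.5-25.0 D, a -0.25 D surgical target,
#' postoperative refraction noise of SD 0.45 D with between-eye correlation
#' 0.6, and one 0.25 D-interval and one 0.50 D-interval lens per patient.
#'
#' @param n_patients Number of patients (two eyes each).
#' @param K_mean,K_sd Keratometry mean / SD, diopters.
#' @param ACD_mean,ACD_sd Anterior chamber depth mean / SD, mm.
#' @param AL_mean,AL_sd Axial length mean / SD, mm.
#' @param interocular_r2 Named vector of interocular R-squared targets for
#'   `K`, `ACD`, `AL` (each in (0, 1]).
#' @param refraction_noise_sd SD of postoperative refraction noise, diopters.
#' @param error_interocular_r Between-eye correlation of the refraction
#'   noise (in \[0, 1)).
#' @param target_refraction Surgical target refraction, diopters.
#' @param power_range Allowed continuous-power range, diopters; patients
#'   whose selected powers fall outside are resampled (rejection, not
#'   clipping).
#' @param implant_formula Formula used for surgical power selection.
#' @param lenses Named list of two [iol_lens()] objects, one implanted per
#'   eye of each patient.
#' @return An object of class `iol_cohort_spec` (a named list).
#' @export
cohort_spec <- function(n_patients = 40,
                        K_mean = 44.4, K_sd = 1.36,
                        ACD_mean = 3.15, ACD_sd = 0.36,
                        AL_mean = 23.43, AL_sd = 0.70,
                        interocular_r2 = c(K = 0.926, ACD = 0.893, AL = 0.934),
                        refraction_noise_sd = 0.45,
                        error_interocular_r = 0.6,
                        target_refraction = -0.25,
                        power_range = c(15.5, 25.0),
                        implant_formula = "haigis",
                        lenses = default_lens_registry()) {
  stopifnot(n_patients >= 1, K_sd > 0, ACD_sd > 0, AL_sd > 0,
            all(interocular_r2 > 0), all(interocular_r2 <= 1),
            refraction_noise_sd >= 0,
            error_interocular_r >= 0, error_interocular_r < 1,
            length(power_range) == 2L, power_range[1] < power_range[2],
            length(lenses) == 2L)
  if (!all(c("K", "ACD", "AL") %in% names(interocular_r2)))
    stop("interocular_r2 must be named with K, ACD, AL", call. = FALSE)
  structure(
    list(n_patients = n_patients, K_mean = K_mean, K_sd = K_sd,
         ACD_mean = ACD_mean, ACD_sd = ACD_sd, AL_mean = AL_mean,
         AL_sd = AL_sd, interocular_r2 = interocular_r2,
         refraction_noise_sd = refraction_noise_sd,
         error_interocular_r = error_interocular_r,
         target_refraction = target_refraction, power_range = power_range,
         implant_formula = match_formula(implant_formula), lenses = lenses),
    class = "iol_cohort_spec")
}

# one paired draw with interocular correlation r: shared patient latent of
# variance r*sd^2 plus independent eye deviations of variance (1-r)*sd^2
paired_draw <- function(mean, sd, r) {
  mean + sqrt(r) * sd * stats::rnorm(1) + sqrt(1 - r) * sd * stats::rnorm(2)
}

#' Generate a synthetic paired-eye cohort
#'
#' Draws `n_patients` patients with two eyes each. Per measure, a shared
#' patient latent plus eye-level deviation gives the target interocular
#' correlation. Each patient receives the spec's two lenses, one per eye
#' (which lens goes to the right eye is randomized). The implanted power is
#' the grid-rounded formula power for the spec's target refraction; patients
#' for whom either eye's continuous power falls outside `power_range` are
#' redrawn (up to 1000 attempts). The observed postoperative spherical
#' equivalent is the formula prediction at the implanted (grid) power plus
#' correlated Gaussian noise.
#'
#' @param spec An [cohort_spec()] object.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A data.frame of class `iol_cohort` with one row per eye and
#'   columns `patient_id`, `eye` (`"OD"`/`"OS"`), `lens_name`, `K_D`,
#'   `ACD_mm`, `AL_mm`, `continuous_power_D`, `implanted_power_D`,
#'   `postop_se_D`, `preop_se_D`. The spec and seed are attached as
#'   attributes `spec` and `seed`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 5), seed = 42)
#' head(cohort)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "iol_cohort_spec"))
  set.seed(as.integer(seed))
  r <- sqrt(spec$interocular_r2)   # correlation targets from R-squared
  lens_names <- vapply(spec$lenses, `[[`, character(1), "name")
  rows <- vector("list", spec$n_patients)
  for (p in seq_len(spec$n_patients)) {
    ok <- FALSE
    for (attempt in seq_len(1000)) {
      K <- paired_draw(spec$K_mean, spec$K_sd, r["K"])
      ACD <- paired_draw(spec$ACD_mean, spec$ACD_sd, r["ACD"])
      AL <- paired_draw(spec$AL_mean, spec$AL_sd, r["AL"])
      if (any(K < 30) || any(K > 60) || any(ACD < 1.5) || any(ACD > 5) ||
          any(AL < 18) || any(AL > 32)) next
      lens_idx <- if (stats::runif(1) < 0.5) c(1L, 2L) else c(2L, 1L)
      eyes <- data.frame(K_D = K, ACD_mm = ACD, AL_mm = AL)
      cont <- vapply(1:2, function(e)
        power_for_target(spec$implant_formula, eyes[e, , drop = FALSE],
                         spec$lenses[[lens_idx[e]]],
                         spec$target_refraction), numeric(1))
      if (all(cont >= spec$power_range[1]) &&
          all(cont <= spec$power_range[2])) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("patient %d: no in-range IOL power after 1000 attempts", p),
           call. = FALSE)
    grid <- vapply(1:2, function(e)
      round_to_grid(cont[e], spec$lenses[[lens_idx[e]]]), numeric(1))
    pred <- vapply(1:2, function(e)
      predict_refraction(spec$implant_formula, eyes[e, , drop = FALSE],
                         spec$lenses[[lens_idx[e]]], grid[e]), numeric(1))
    noise <- spec$refraction_noise_sd *
      (sqrt(spec$error_interocular_r) * stats::rnorm(1) +
         sqrt(1 - spec$error_interocular_r) * stats::rnorm(2))
    preop <- -0.9 + 2.4 * stats::rnorm(2)   # descriptive only
    rows[[p]] <- data.frame(
      patient_id = sprintf("P%03d", p),
      eye = c("OD", "OS"),
      lens_name = lens_names[lens_idx],
      K_D = K, ACD_mm = ACD, AL_mm = AL,
      continuous_power_D = cont,
      implanted_power_D = grid,
      postop_se_D = pred + noise,
      preop_se_D = preop)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("iol_cohort", "data.frame")
  out
}

#' Check a cohort against its distributional targets
#'
#' Compares empirical biometry means, SDs, and interocular correlations
#' against the spec. Mean checks use a 4-standard-error band (of the
#' paired-patient sample), SD checks a 30% relative band, and interocular
#' R-squared an absolute band of 0.05 at `n >= 400` patients, widened to
#' 0.20 below that (at 40 patients the sampling noise of a correlation is
#' substantial).
#'
#' @param cohort An `iol_cohort` (or compatible data.frame).
#' @param spec The [cohort_spec()] the cohort should match.
#' @return A data.frame with columns `metric`, `target`, `observed`,
#'   `tolerance`, `pass`, plus an attribute `all_pass`.
#' @export
validate_cohort <- function(cohort, spec = attr(cohort, "spec")) {
  stopifnot(nrow(cohort) >= 2L, inherits(spec, "iol_cohort_spec"))
  n_pat <- length(unique(cohort$patient_id))
  od <- cohort[cohort$eye == "OD", ]
  os <- cohort[cohort$eye == "OS", ]
  od <- od[order(od$patient_id), ]; os <- os[order(os$patient_id), ]
  meas <- list(K = "K_D", ACD = "ACD_mm", AL = "AL_mm")
  targ_mean <- c(K = spec$K_mean, ACD = spec$ACD_mean, AL = spec$AL_mean)
  targ_sd <- c(K = spec$K_sd, ACD = spec$ACD_sd, AL = spec$AL_sd)
  r2_tol <- if (n_pat >= 400) 0.05 else 0.20
  rows <- list()
  for (m in names(meas)) {
    v <- cohort[[meas[[m]]]]
    se <- targ_sd[m] / sqrt(n_pat)   # patients are the independent unit
    rows[[length(rows) + 1L]] <- data.frame(
      metric = paste0(m, "_mean"), target = unname(targ_mean[m]),
      observed = mean(v), tolerance = unname(4 * se),
      pass = abs(mean(v) - targ_mean[m]) <= 4 * se)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = paste0(m, "_sd"), target = unname(targ_sd[m]),
      observed = stats::sd(v), tolerance = unname(0.3 * targ_sd[m]),
      pass = abs(stats::sd(v) - targ_sd[m]) <= 0.3 * targ_sd[m])
    r2 <- pearson_r2(od[[meas[[m]]]], os[[meas[[m]]]])
    rows[[length(rows) + 1L]] <- data.frame(
      metric = paste0(m, "_interocular_r2"),
      target = unname(spec$interocular_r2[m]), observed = r2,
      tolerance = r2_tol,
      pass = abs(r2 - spec$interocular_r2[m]) <= r2_tol)
  }
  in_range <- all(cohort$continuous_power_D >= spec$power_range[1] &
                    cohort$continuous_power_D <= spec$power_range[2])
  rows[[length(rows) + 1L]] <- data.frame(
    metric = "powers_in_range", target = 1, observed = as.numeric(in_range),
    tolerance = 0, pass = in_range)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "all_pass") <- all(out$pass)
  out
}
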