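# Monte Carlo propagation of IOL manufacturing power error into refractive
# prediction error.  Design: only the IOL power is random; biometry, ELP
# estimation and keratometry are taken as error-free, which the zero-error
# power construction enforces by making every eye's baseline prediction
# error identically zero before perturbation.

#' Zero-prediction-error IOL powers for a cohort
#'
#' For each eye, the continuous IOL power at which the chosen formula's
#' predicted refraction equals the observed postoperative spherical
#' equivalent. At this power the refractive prediction error is exactly
#' zero, so all residual error sources (biometry, ELP estimation) are
#' absorbed and only a subsequent power perturbation can create error.
#'
#' @param cohort Data.frame of eyes with `K_D`, `ACD_mm`, `AL_mm`,
#'   `postop_se_D`.
#' @inheritParams predict_refraction
#' @return Continuous powers in diopters (not grid-rounded), one per eye.
#' @export
zero_error_powers <- function(formula, cohort, lens, vertex = 12,
                              corneal_index = 1.3315) {
  if (any(!is.finite(cohort$postop_se_D)))
    stop("postop_se_D must be present for every eye", call. = FALSE)
  power_for_target(formula, cohort, lens, cohort$postop_se_D,
                   vertex = vertex, corneal_index = corneal_index)
}

#' Draw manufactured IOL powers
#'
#' One Gaussian draw per eye around its zero-error power, with the lens's
#' manufacturing tolerance SD. Drawn powers are deliberately NOT re-rounded
#' to the lens grid: manufacturing error is continuous. With
#' `tolerance_sd = 0` the draws equal the means exactly.
#'
#' @param mean_power Per-eye mean powers, diopters.
#' @param tolerance_sd Power error SD, diopters (>= 0).
#' @return Drawn powers, diopters.
#' @export
draw_powers <- function(mean_power, tolerance_sd) {
  stopifnot(tolerance_sd >= 0, all(is.finite(mean_power)))
  mean_power + stats::rnorm(length(mean_power), 0, 1) * tolerance_sd
}

#' Per-eye refractive prediction errors for one simulation replicate
#'
#' Draws one manufactured power per eye and returns the induced refractive
#' prediction error: the refraction the eye actually attains with the drawn
#' power minus the refraction predicted at the labelled (zero-error) power.
#' Because the prediction at the zero-error power equals the observed
#' postoperative SE by construction, this realizes "postoperative spherical
#' equivalent minus predicted refraction" with the power perturbation as the
#' only error source.
#'
#' @inheritParams zero_error_powers
#' @param zero_powers Per-eye zero-error powers (from [zero_error_powers()]).
#' @param tolerance_sd Power error SD in diopters.
#' @return Signed per-eye errors in diopters.
#' @export
replicate_errors <- function(formula, cohort, lens, zero_powers,
                             tolerance_sd = lens$tolerance_sd, vertex = 12,
                             corneal_index = 1.3315) {
  drawn <- draw_powers(zero_powers, tolerance_sd)
  actual <- predict_refraction(formula, cohort, lens, drawn,
                               vertex = vertex, corneal_index = corneal_index)
  labelled <- predict_refraction(formula, cohort, lens, zero_powers,
                                 vertex = vertex,
                                 corneal_index = corneal_index)
  actual - labelled
}

# deterministic per-replicate substream seed (kept within 32-bit range)
replicate_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 2039L + 7L * as.integer(i)
}

#' Run a Monte Carlo manufacturing-tolerance study
#'
#' The full simulation for one formula and one lens group: computes each
#' eye's zero-error power, then runs `n_replicates` independent replicates,
#' each drawing one Gaussian power per eye (SD = the manufacturing tolerance)
#' and summarizing the induced refractive prediction errors via
#' [summarize_errors()]. Replicates use deterministic seed substreams, so a
#' study is exactly reproducible and replicate order does not change the set
#' of results.
#'
#' @inheritParams zero_error_powers
#' @param tolerance_sd Power error SD in diopters; defaults to the lens's.
#' @param n_replicates Number of replicates (default 10).
#' @param seed Integer seed for the study.
#' @param thresholds Absolute-error thresholds in diopters.
#' @return An object of class `iol_mc_study`: list with `replicates` (a
#'   data.frame: one row per replicate with `medae`, `mae`, `iqr_lo`,
#'   `iqr_hi`, `mean_error`, and `pct_within_*` / `n_within_*` columns),
#'   `errors` (eyes x replicates matrix of signed errors), `zero_powers`,
#'   `aggregate` (min/max/grand-median of MedAE and of each threshold
#'   percentage, plus pooled percentages over all replicate-eyes), and the
#'   call parameters. `summary()` prints the per-replicate table.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n_patients = 10), seed = 1)
#' lens <- default_lens_registry()$akreos_ao
#' st <- run_mc_study("haigis", cohort[cohort$lens_name == "Akreos AO", ],
#'                    lens, seed = 1)
#' st$aggregate$medae["median"]
#' }
#' @export
run_mc_study <- function(formula, cohort, lens,
                         tolerance_sd = lens$tolerance_sd,
                         n_replicates = 10, seed = 1,
                         thresholds = c(0.25, 0.50, 0.75, 1.00),
                         vertex = 12, corneal_index = 1.3315) {
  formula <- match_formula(formula)
  stopifnot(nrow(cohort) >= 2L, n_replicates >= 1L, tolerance_sd >= 0)
  zp <- zero_error_powers(formula, cohort, lens, vertex = vertex,
                          corneal_index = corneal_index)
  n_eyes <- nrow(cohort)
  errs <- matrix(NA_real_, n_eyes, n_replicates)
  summaries <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(replicate_seed(seed, i))
    errs[, i] <- replicate_errors(formula, cohort, lens, zp,
                                  tolerance_sd = tolerance_sd,
                                  vertex = vertex,
                                  corneal_index = corneal_index)
    summaries[[i]] <- summarize_errors(errs[, i], thresholds)
  }
  tl <- sprintf("%.2f", thresholds)
  reps <- data.frame(
    replicate = seq_len(n_replicates),
    medae = vapply(summaries, `[[`, numeric(1), "medae"),
    mae = vapply(summaries, `[[`, numeric(1), "mae"),
    iqr_lo = vapply(summaries, function(s) s$iqr[1], numeric(1)),
    iqr_hi = vapply(summaries, function(s) s$iqr[2], numeric(1)),
    mean_error = vapply(summaries, `[[`, numeric(1), "mean_error"))
  for (j in seq_along(thresholds)) {
    reps[[paste0("n_within_", tl[j])]] <-
      vapply(summaries, function(s) unname(s$counts_within[j]), integer(1))
    reps[[paste0("pct_within_", tl[j])]] <-
      vapply(summaries, function(s) unname(s$pct_within[j]), numeric(1))
  }
  pooled <- summarize_errors(as.vector(errs), thresholds)
  aggregate <- list(
    medae = c(min = min(reps$medae), median = stats::median(reps$medae),
              max = max(reps$medae)),
    pct_within = lapply(stats::setNames(seq_along(thresholds), tl), function(j) {
      p <- reps[[paste0("pct_within_", tl[j])]]
      c(min = min(p), median = stats::median(p), max = max(p),
        pooled = unname(pooled$pct_within[j]))
    }),
    pooled = pooled)
  structure(
    list(replicates = reps, errors = errs, zero_powers = zp,
         aggregate = aggregate, formula = formula, lens = lens$name,
         tolerance_sd = tolerance_sd, n_replicates = n_replicates,
         seed = seed, thresholds = thresholds, n_eyes = n_eyes),
    class = "iol_mc_study")
}

#' @export
print.iol_mc_study <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo tolerance study: %s formula, %s lens, power SD %.2f D\n",
    toupper(x$formula), x$lens, x$tolerance_sd))
  cat(sprintf("  %d replicates x %d eyes (seed %d)\n",
              x$n_replicates, x$n_eyes, x$seed))
  m <- x$aggregate$medae
  cat(sprintf("  MedAE: grand median %.2f D (range %.2f - %.2f)\n",
              m["median"], m["min"], m["max"]))
  p <- x$aggregate$pct_within[["0.25"]]
  cat(sprintf(
    "  within ±0.25 D: %.1f%% pooled (replicate range %.1f - %.1f%%)\n",
    p["pooled"], p["min"], p["max"]))
  invisible(x)
}

#' @export
summary.iol_mc_study <- function(object, ...) {
  print(object)
  cat("\nPer-replicate summaries:\n")
  out <- object$replicates
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, 3)
  print(out, row.names = FALSE)
  invisible(object$replicates)
}

#' @export
plot.iol_mc_study <- function(x, ...) {
  graphics::boxplot(x$errors, xlab = "replicate",
                    ylab = "refractive prediction error (D)",
                    main = sprintf("%s, %s, SD %.2f D", toupper(x$formula),
                                   x$lens, x$tolerance_sd), ...)
  graphics::abline(h = c(-0.25, 0.25), lty = 2, col = "grey40")
  invisible(x)
}
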