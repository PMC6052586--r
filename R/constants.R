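# Lens-constant optimization: data-adjusted constants giving zero mean
# numerical prediction error on a cohort with observed refractive outcomes.

#' Back-solve the effective lens position of an operated eye
#'
#' Given an eye's biometry, the implanted IOL power, and the observed
#' postoperative spherical equivalent, finds the effective lens position `d`
#' (mm) at which the Haigis-style vergence chain reproduces the observed
#' refraction exactly. This per-eye ELP is the response variable of the
#' Haigis constant regression.
#'
#' @param eye Data.frame of eyes with columns `K_D`, `AL_mm` (and
#'   `implanted_power_D`, `postop_se_D` unless given explicitly).
#' @param implanted_power,postop_se Optional overrides (diopters), recycled.
#' @param vertex,corneal_index See [predict_refraction()].
#' @param interval Search interval for `d` in mm (default 0.5-9.0).
#' @return Effective lens position(s) in mm.
#' @examples
#' eye <- data.frame(K_D = 44.4, ACD_mm = 3.15, AL_mm = 23.43)
#' se <- iolmc:::haigis_refraction_elp(21, eye$K_D, eye$AL_mm, d_mm = 5)
#' back_solve_elp(eye, implanted_power = 21, postop_se = se)  # 5 mm
#' @export
back_solve_elp <- function(eye, implanted_power = eye$implanted_power_D,
                           postop_se = eye$postop_se_D, vertex = 12,
                           corneal_index = 1.3315, interval = c(0.5, 9.0)) {
  check_eye(eye)
  n <- nrow(eye)
  P <- rep_len(implanted_power, n)
  se <- rep_len(postop_se, n)
  if (any(!is.finite(P)) || any(!is.finite(se)))
    stop("implanted power and postoperative SE must be present and finite",
         call. = FALSE)
  out <- numeric(n)
  for (i in seq_len(n)) {
    f <- function(d)
      haigis_refraction_elp(P[i], eye$K_D[i], eye$AL_mm[i], d,
                            vertex = vertex, corneal_index = corneal_index) -
        se[i]
    lo <- f(interval[1]); hi <- f(interval[2])
    if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
      stop(sprintf(
        "no ELP in (%.1f, %.1f) mm reproduces the observed refraction (eye row %d)",
        interval[1], interval[2], i), call. = FALSE)
    out[i] <- stats::uniroot(f, interval, tol = 1e-10)$root
  }
  out
}

#' Optimize Haigis constants on a cohort
#'
#' Reproduces the data-adjusted Haigis constant procedure: the effective lens
#' position of each operated eye is back-solved from its observed refraction
#' ([back_solve_elp()]), ordinary least squares of ELP on (ACD, AL) yields
#' the slopes `a1`, `a2` and the intercept `a0`, and `a0` is then shifted so
#' the cohort's mean refractive prediction error under the fitted constants
#' is exactly zero. Both the raw regression intercept and the shifted `a0`
#' are reported.
#'
#' @param cohort Data.frame of eyes with columns `K_D`, `ACD_mm`, `AL_mm`,
#'   `implanted_power_D`, `postop_se_D` (>= 3 rows, non-collinear ACD/AL).
#' @inheritParams back_solve_elp
#' @return An object of class `iol_constant_fit` with elements `constants`
#'   (named vector `a0`, `a1`, `a2`), `a0_regression` (pre-shift intercept),
#'   `mean_error_after`, `per_eye_elp`, `regression` (the `lm` fit), and
#'   `formula = "haigis"`. `coef()` returns the constants.
#' @export
optimize_haigis_constants <- function(cohort, vertex = 12,
                                      corneal_index = 1.3315) {
  check_eye(cohort)
  if (nrow(cohort) < 3L)
    stop("need at least 3 eyes to fit three Haigis constants", call. = FALSE)
  elp <- back_solve_elp(cohort, vertex = vertex, corneal_index = corneal_index)
  fit <- stats::lm(elp ~ ACD_mm + AL_mm, data = cohort)
  if (any(is.na(stats::coef(fit))))
    stop("singular design matrix: ACD and AL are collinear in this cohort",
         call. = FALSE)
  a1 <- unname(stats::coef(fit)["ACD_mm"])
  a2 <- unname(stats::coef(fit)["AL_mm"])
  a0_reg <- unname(stats::coef(fit)["(Intercept)"])

  mean_err <- function(a0) {
    pred <- haigis_refraction(cohort$implanted_power_D, cohort$K_D,
                              cohort$ACD_mm, cohort$AL_mm, a0, a1, a2,
                              vertex = vertex, corneal_index = corneal_index)
    mean(cohort$postop_se_D - pred)
  }
  # deeper ELP -> more hyperopic prediction -> monotone objective; widen the
  # bracket geometrically until it straddles zero
  half <- 0.5
  repeat {
    lo <- mean_err(a0_reg - half); hi <- mean_err(a0_reg + half)
    if (lo * hi <= 0) break
    half <- half * 2
    if (half > 8)
      stop("could not bracket the zero-mean-error a0 shift", call. = FALSE)
  }
  a0 <- stats::uniroot(mean_err, c(a0_reg - half, a0_reg + half),
                       tol = 1e-12)$root
  structure(
    list(constants = c(a0 = a0, a1 = a1, a2 = a2),
         a0_regression = a0_reg,
         mean_error_after = mean_err(a0),
         per_eye_elp = elp,
         regression = fit,
         formula = "haigis"),
    class = "iol_constant_fit")
}

#' Optimize the SRK/T A-constant on a cohort
#'
#' Finds the A-constant at which the cohort's mean refractive prediction
#' error (observed postoperative SE minus SRK/T-predicted refraction at the
#' implanted power) is exactly zero, by bracketed root search over
#' \[100, 130\].
#'
#' @inheritParams optimize_haigis_constants
#' @param initial_a Starting A-constant, used only for reporting.
#' @param vertex Spectacle vertex distance, mm.
#' @return An object of class `iol_constant_fit` with `constants` (named
#'   `a_constant`), `mean_error_after`, `initial_a`, `formula = "srkt"`.
#' @export
optimize_a_constant <- function(cohort, initial_a = 118.5, vertex = 12) {
  check_eye(cohort)
  if (nrow(cohort) < 1L) stop("empty cohort", call. = FALSE)
  if (any(!is.finite(cohort$implanted_power_D)) ||
      any(!is.finite(cohort$postop_se_D)))
    stop("implanted power and postoperative SE must be present for all eyes",
         call. = FALSE)
  mean_err <- function(A) {
    pred <- srkt_refraction(cohort$implanted_power_D, cohort$K_D,
                            cohort$AL_mm, A, vertex = vertex)
    mean(cohort$postop_se_D - pred)
  }
  lo <- mean_err(100); hi <- mean_err(130)
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
    stop("no A-constant in [100, 130] zeroes the mean prediction error",
         call. = FALSE)
  a_star <- stats::uniroot(mean_err, c(100, 130), tol = 1e-8)$root
  structure(
    list(constants = c(a_constant = a_star),
         mean_error_after = mean_err(a_star),
         initial_a = initial_a,
         formula = "srkt"),
    class = "iol_constant_fit")
}

#' @export
coef.iol_constant_fit <- function(object, ...) object$constants

#' @export
print.iol_constant_fit <- function(x, ...) {
  if (x$formula == "haigis") {
    cat("Data-adjusted Haigis constants\n")
    cat(sprintf("  a0 = %.4f  (regression intercept %.4f)\n",
                x$constants["a0"], x$a0_regression))
    cat(sprintf("  a1 = %.4f   a2 = %.4f\n",
                x$constants["a1"], x$constants["a2"]))
    cat(sprintf("  eyes: %d   residual ELP SD: %.3f mm\n",
                length(x$per_eye_elp), stats::sigma(x$regression)))
  } else {
    cat("Data-adjusted SRK/T A-constant\n")
    cat(sprintf("  A = %.4f  (started from %.2f)\n",
                x$constants["a_constant"], x$initial_a))
  }
  cat(sprintf("  mean prediction error after adjustment: %.2e D\n",
              x$mean_error_after))
  invisible(x)
}

#' Export fitted constants as a lens-registry JSON block
#'
#' Writes the fitted constants in the field names [iol_lens()] uses so they
#' can be merged into a lens registry.
#'
#' @param fit An `iol_constant_fit`.
#' @return A named list (`a_constant` or `haigis_a0`/`haigis_a1`/`haigis_a2`).
#' @export
constants_as_registry_block <- function(fit) {
  stopifnot(inherits(fit, "iol_constant_fit"))
  if (fit$formula == "haigis") {
    list(haigis_a0 = unname(fit$constants["a0"]),
         haigis_a1 = unname(fit$constants["a1"]),
         haigis_a2 = unname(fit$constants["a2"]))
  } else {
    list(a_constant = unname(fit$constants["a_constant"]))
  }
}
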