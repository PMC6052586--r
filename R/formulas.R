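# Vergence-formula engines for pseudophakic refraction prediction.
#
# Conventions used throughout:
#   K   mean keratometry, diopters (1.3375 keratometric index convention)
#   ACD preoperative anterior chamber depth, mm (epithelium to lens)
#   AL  axial length, mm
#   all powers and refractions in diopters; refractions are spectacle-plane
#   spherical equivalents at the stated vertex distance (mm).

.NA_AQUEOUS <- 1.336   # aqueous/vitreous refractive index
.NC_SRKT <- 1.333      # SRK/T corneal index
.FORMULAS <- c("srkt", "haigis")

match_formula <- function(formula) {
  match.arg(tolower(formula), .FORMULAS)
}

#' SRK/T geometric intermediates
#'
#' Computes the intermediate quantities of the SRK/T formula from keratometry,
#' axial length, and the lens A-constant: corneal radius `r = 337.5/K`, the
#' corrected axial length `lcor` (quadratic shortening beyond 24.2 mm),
#' computed corneal width `cw`, corneal dome height `h` (square-root argument
#' clamped at zero for very steep small corneas), the estimated postoperative
#' anterior chamber depth `elp` (the effective lens position), and the
#' retina-corrected optical axial length `lopt`.
#'
#' @param K Mean keratometry in diopters (vectorized).
#' @param AL Axial length in mm (vectorized).
#' @param a_constant SRK/T A-constant.
#' @return A data.frame with columns `r`, `lcor`, `cw`, `h`, `acd_const`,
#'   `offset`, `elp`, `lopt` (all mm except the dimensionless `acd_const`).
#' @examples
#' srkt_intermediates(K = 44.41, AL = 23.42, a_constant = 118.24)
#' @export
srkt_intermediates <- function(K, AL, a_constant) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("K must be positive and finite", call. = FALSE)
  if (any(!is.finite(AL)) || any(AL < 18) || any(AL > 32))
    stop("AL outside the supported 18-32 mm range", call. = FALSE)
  r <- 337.5 / K
  lcor <- ifelse(AL <= 24.2, AL, -3.446 + 1.715 * AL - 0.0237 * AL^2)
  cw <- -5.41 + 0.58412 * lcor + 0.098 * K
  h <- r - sqrt(pmax(r^2 - cw^2 / 4, 0))
  acd_const <- 0.62467 * a_constant - 68.747
  offset <- acd_const - 3.336
  elp <- h + offset
  lopt <- AL + (0.65696 - 0.02029 * AL)
  data.frame(r = r, lcor = lcor, cw = cw, h = h, acd_const = acd_const,
             offset = offset, elp = elp, lopt = lopt)
}

# SRK/T predicted spectacle refraction at IOL power P (vectorized).
srkt_refraction <- function(P, K, AL, a_constant, vertex = 12) {
  im <- srkt_intermediates(K, AL, a_constant)
  na <- .NA_AQUEOUS
  ncm1 <- .NC_SRKT - 1
  r <- im$r; L <- im$lopt; C <- im$elp; V <- vertex
  num <- 1000 * na * (na * r - ncm1 * L) -
    P * (L - C) * (na * r - ncm1 * C)
  den <- na * (V * (na * r - ncm1 * L) + L * r) -
    0.001 * P * (L - C) * (V * (na * r - ncm1 * C) + C * r)
  if (any(abs(den) < 1e-9))
    stop("singular vergence denominator in SRK/T refraction", call. = FALSE)
  num / den
}

#' Haigis effective lens position
#'
#' The Haigis formula places the lens at `d = a0 + a1 * ACD + a2 * AL` (mm),
#' a linear predictor of postoperative effective lens position from
#' preoperative anterior chamber depth and axial length.
#'
#' @param ACD Preoperative anterior chamber depth, mm (vectorized).
#' @param AL Axial length, mm (vectorized).
#' @param a0,a1,a2 Lens constants (`a0` mm; `a1`, `a2` dimensionless slopes).
#' @return Effective lens position in mm.
#' @examples
#' haigis_elp(ACD = 3.14, AL = 23.42, a0 = 1.706, a1 = 0.279, a2 = 0.087)
#' @export
haigis_elp <- function(ACD, AL, a0, a1, a2) {
  a0 + a1 * ACD + a2 * AL
}

# Haigis predicted spectacle refraction at IOL power P with an explicit
# effective lens position d_mm (vectorized).  Thin-lens vergence chain:
# corneal power from the measured radius with the chosen corneal index,
# propagation across the ELP, image on the retina, refraction carried back
# to the spectacle plane at the vertex distance.
haigis_refraction_elp <- function(P, K, AL, d_mm, vertex = 12,
                                  corneal_index = 1.3315) {
  r_mm <- 337.5 / K
  DC <- (corneal_index - 1) * 1000 / r_mm
  n <- .NA_AQUEOUS
  L <- AL / 1000
  d <- d_mm / 1000
  dx <- vertex / 1000
  q <- n / (L - d) - P            # vergence entering the IOL plane
  if (any(!is.finite(q)) || any(abs(q) < 1e-9))
    stop("singular vergence denominator in Haigis refraction", call. = FALSE)
  s <- n / q + d                  # reduced distance back to the cornea
  if (any(abs(s) < 1e-12))
    stop("singular vergence denominator in Haigis refraction", call. = FALSE)
  rc <- n / s - DC                # corneal-plane refraction
  den <- 1 + dx * rc
  if (any(abs(den) < 1e-9))
    stop("singular spectacle-plane conversion in Haigis refraction",
         call. = FALSE)
  rc / den
}

haigis_refraction <- function(P, K, ACD, AL, a0, a1, a2, vertex = 12,
                              corneal_index = 1.3315) {
  haigis_refraction_elp(P, K, AL, haigis_elp(ACD, AL, a0, a1, a2),
                        vertex = vertex, corneal_index = corneal_index)
}

check_eye <- function(eye) {
  need <- c("K_D", "ACD_mm", "AL_mm")
  miss <- setdiff(need, names(eye))
  if (length(miss))
    stop("eye data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(eye)
}

#' Predicted postoperative refraction for an implanted IOL power
#'
#' Evaluates the SRK/T or Haigis formula for each eye: the spectacle-plane
#' spherical equivalent the eye is predicted to have if a lens of power
#' `iol_power` is implanted. Predicted refraction is strictly decreasing in
#' IOL power over the clinical range.
#'
#' @param formula `"srkt"` or `"haigis"`.
#' @param eye A data.frame of eyes with columns `K_D`, `ACD_mm`, `AL_mm`
#'   (`ACD_mm` is only used by the Haigis formula).
#' @param lens An [iol_lens()] supplying the formula constants.
#' @param iol_power IOL power(s) in diopters, recycled against the eyes.
#' @param vertex Spectacle vertex distance in mm (default 12).
#' @param corneal_index Corneal refractive index used by the Haigis engine to
#'   convert the measured corneal radius to corneal power. Default 1.3315
#'   (the formula's original physical index); set 1.3375 to reuse the
#'   keratometric reading unchanged.
#' @return Numeric vector of predicted refractions in diopters.
#' @examples
#' lens <- default_lens_registry()$akreos_ao
#' eye <- data.frame(K_D = 44.41, ACD_mm = 3.14, AL_mm = 23.42)
#' predict_refraction("haigis", eye, lens, iol_power = 21.0)
#' @export
predict_refraction <- function(formula, eye, lens, iol_power, vertex = 12,
                               corneal_index = 1.3315) {
  formula <- match_formula(formula)
  check_eye(eye)
  stopifnot(inherits(lens, "iol_lens"), all(is.finite(iol_power)))
  if (formula == "srkt") {
    srkt_refraction(iol_power, eye$K_D, eye$AL_mm, lens$a_constant,
                    vertex = vertex)
  } else {
    haigis_refraction(iol_power, eye$K_D, eye$ACD_mm, eye$AL_mm,
                      lens$haigis_a0, lens$haigis_a1, lens$haigis_a2,
                      vertex = vertex, corneal_index = corneal_index)
  }
}

#' IOL power achieving a target refraction
#'
#' Inverts the chosen vergence formula: finds the continuous (not
#' grid-rounded) IOL power whose predicted refraction equals
#' `target_refraction` for each eye. With the target set to an observed
#' postoperative spherical equivalent this is the zero-prediction-error power;
#' with the target set to the planned refraction it is surgical power
#' selection. A bracketed root search on \[-10, 40\] D is used (the predicted
#' refraction is strictly monotone in power, so the root is unique).
#'
#' @inheritParams predict_refraction
#' @param target_refraction Target spectacle refraction(s), diopters,
#'   recycled against the eyes.
#' @param tol Root-finding tolerance in diopters.
#' @return Numeric vector of continuous IOL powers in diopters.
#' @examples
#' lens <- default_lens_registry()$softec_hd
#' eye <- data.frame(K_D = 44.4, ACD_mm = 3.15, AL_mm = 23.43)
#' p <- power_for_target("srkt", eye, lens, target_refraction = -0.25)
#' predict_refraction("srkt", eye, lens, p)  # -0.25 back
#' @export
power_for_target <- function(formula, eye, lens, target_refraction,
                             vertex = 12, corneal_index = 1.3315,
                             tol = 1e-10) {
  formula <- match_formula(formula)
  check_eye(eye)
  n <- nrow(eye)
  target <- rep_len(target_refraction, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ei <- eye[i, , drop = FALSE]
    f <- function(P)
      predict_refraction(formula, ei, lens, P, vertex = vertex,
                         corneal_index = corneal_index) - target[i]
    lo <- f(-10); hi <- f(40)
    if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
      stop(sprintf(
        "no IOL power in [-10, 40] D reaches refraction %.2f D (eye row %d)",
        target[i], i), call. = FALSE)
    out[i] <- stats::uniroot(f, c(-10, 40), tol = tol)$root
  }
  out
}

#' Snap a continuous power onto a lens's manufacturing grid
#'
#' Rounds to the nearest multiple of the lens's diopter interval; exact
#' half-step ties round toward the lower power (the myopia-favoring surgical
#' convention). The result is clamped to the lens's labelled power range.
#'
#' @param power Continuous power(s) in diopters.
#' @param lens An [iol_lens()].
#' @return Power(s) on the lens grid, in diopters.
#' @examples
#' lens <- default_lens_registry()$akreos_ao
#' round_to_grid(c(20.60, 20.75), lens)  # 20.50, 20.50
#' @export
round_to_grid <- function(power, lens) {
  stopifnot(inherits(lens, "iol_lens"), all(is.finite(power)))
  k <- ceiling(power / lens$interval - 0.5)
  pmin(pmax(k * lens$interval, lens$power_min), lens$power_max)
}
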