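# Independent oracles used across the suite.
#
# The package engines compute refraction-given-power in closed form. The
# oracles here transcribe the published power-given-refraction equations of
# each formula and invert them numerically, so agreement checks exercise two
# genuinely different code paths.

# SRK/T: published target-IOL-power equation, transcribed line by line.
oracle_srkt_power_for_refraction <- function(REF, K, AL, A, vertex = 12) {
  na <- 1.336
  ncm1 <- 1.333 - 1
  r <- 337.5 / K
  lcor <- if (AL <= 24.2) AL else -3.446 + 1.715 * AL - 0.0237 * AL^2
  cw <- -5.41 + 0.58412 * lcor + 0.098 * K
  h <- r - sqrt(max(r^2 - cw^2 / 4, 0))
  acd_est <- h + (0.62467 * A - 68.747) - 3.336
  l <- AL + 0.65696 - 0.02029 * AL
  v <- vertex
  num <- 1000 * na * (na * r - ncm1 * l - 0.001 * REF *
                        (v * (na * r - ncm1 * l) + l * r))
  den <- (l - acd_est) * (na * r - ncm1 * acd_est - 0.001 * REF *
                            (v * (na * r - ncm1 * acd_est) + acd_est * r))
  num / den
}

oracle_srkt_refraction <- function(P, K, AL, A, vertex = 12) {
  uniroot(function(REF)
    oracle_srkt_power_for_refraction(REF, K, AL, A, vertex) - P,
    c(-30, 30), tol = 1e-12, maxiter = 1000)$root
}

# Haigis: published thin-lens IOL-power equation at a desired refraction,
# with ELP d = a0 + a1*ACD + a2*AL, corneal power from r = 337.5/K.
oracle_haigis_power_for_refraction <- function(REF, K, ACD, AL, a0, a1, a2,
                                               vertex = 12,
                                               corneal_index = 1.3315) {
  n <- 1.336
  dc <- (corneal_index - 1) / (337.5 / K / 1000)
  d <- (a0 + a1 * ACD + a2 * AL) / 1000
  l <- AL / 1000
  z <- dc + REF / (1 - REF * vertex / 1000)
  n / (l - d) - n / (n / z - d)
}

oracle_haigis_refraction <- function(P, K, ACD, AL, a0, a1, a2, vertex = 12,
                                     corneal_index = 1.3315) {
  uniroot(function(REF)
    oracle_haigis_power_for_refraction(REF, K, ACD, AL, a0, a1, a2, vertex,
                                       corneal_index) - P,
    c(-30, 30), tol = 1e-12, maxiter = 1000)$root
}

# Brute-force bisection root finder (fixed 200 iterations).
oracle_bisect <- function(f, lo, hi, iter = 200) {
  flo <- f(lo)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

# Exhaustive two-sided Mann-Whitney p by enumerating all group assignments.
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  e <- n1 * n2 / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - e) >= abs(obs - e) - 1e-9)
}

# Random eyes within cohort bounds (biometry only).
random_eyes <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(K_D = runif(n, 40, 48),
             ACD_mm = runif(n, 2.4, 3.9),
             AL_mm = runif(n, 21.5, 25.5))
}

study_lenses <- default_lens_registry()

# Synthetic Haigis cohort with planted constants (optionally noisy ELP).
make_haigis_cohort <- function(n, a0, a1, a2, elp_noise_sd = 0, seed = 1,
                               refr_noise_sd = 0) {
  set.seed(seed)
  eyes <- random_eyes(n)
  lens <- study_lenses$akreos_ao
  elp_true <- haigis_elp(eyes$ACD_mm, eyes$AL_mm, a0, a1, a2) +
    rnorm(n, 0, elp_noise_sd)
  p <- numeric(n)
  for (i in seq_len(n)) {
    p[i] <- oracle_bisect(function(P)
      iolmc:::haigis_refraction_elp(P, eyes$K_D[i], eyes$AL_mm[i],
                                    elp_true[i]) + 0.25, -10, 40)
  }
  p <- round_to_grid(p, lens)
  se <- vapply(seq_len(n), function(i)
    iolmc:::haigis_refraction_elp(p[i], eyes$K_D[i], eyes$AL_mm[i],
                                  elp_true[i]), numeric(1)) +
    rnorm(n, 0, refr_noise_sd)
  cbind(eyes, implanted_power_D = p, postop_se_D = se,
        elp_true = elp_true)
}
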