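# Monte Carlo propagation of manufacturing power error.

small_cohort <- function(n_patients = 10, seed = 2, noise = 0.45) {
  spec <- cohort_spec(n_patients = n_patients, refraction_noise_sd = noise)
  generate_cohort(spec, seed = seed)
}

test_that("zero-error powers invert the observed refraction", {
  cohort <- small_cohort(8)
  akreos <- cohort[cohort$lens_name == "Akreos AO", ]
  lens <- study_lenses$akreos_ao
  for (f in c("haigis", "srkt")) {
    zp <- zero_error_powers(f, akreos, lens)
    resid <- predict_refraction(f, akreos, lens, zp) - akreos$postop_se_D
    expect_true(all(abs(resid) < 1e-8))
    # agreement with brute-force bisection
    for (i in seq_len(nrow(akreos))) {
      ei <- akreos[i, , drop = FALSE]
      pb <- oracle_bisect(function(P)
        predict_refraction(f, ei, lens, P) - ei$postop_se_D, -10, 40)
      expect_equal(zp[i], pb, tolerance = 1e-7)
    }
  }
  # an eye whose refraction was generated at a known power returns it
  eye <- data.frame(K_D = 44.4, ACD_mm = 3.15, AL_mm = 23.43,
                    postop_se_D = NA)
  eye$postop_se_D <- predict_refraction("haigis", eye, lens, 21.37)
  expect_equal(zero_error_powers("haigis", eye, lens), 21.37,
               tolerance = 1e-7)
})

test_that("power draws are Gaussian, reproducible, and exact at SD zero", {
  mu <- rep(20, 10)
  set.seed(5)
  expect_identical(draw_powers(mu, 0), mu)

  set.seed(6); d1 <- draw_powers(rep(20, 1e5), 0.40)
  set.seed(6); d2 <- draw_powers(rep(20, 1e5), 0.40)
  expect_identical(d1, d2)
  expect_lt(abs(sd(d1) - 0.40), 0.004)       # within 1% of the SD
  expect_lt(abs(mean(d1) - 20), 0.005)
})

test_that("a power offset produces a myopic error scaled by spectacle sensitivity", {
  eye <- data.frame(K_D = 44.41, ACD_mm = 3.14, AL_mm = 23.42)
  lens <- study_lenses$akreos_ao
  for (f in c("haigis", "srkt")) {
    p0 <- power_for_target(f, eye, lens, 0)
    err <- predict_refraction(f, eye, lens, p0 + 0.40) -
      predict_refraction(f, eye, lens, p0)
    expect_lt(err, 0)                      # stronger lens -> myopic surprise
    expect_gt(abs(err) / 0.40, 0.55)
    expect_lt(abs(err) / 0.40, 0.75)
  }
})

test_that("replicate errors vanish when the drawn power equals the zero-error power", {
  cohort <- small_cohort(6)
  sub <- cohort[cohort$lens_name == "Softec HD", ]
  lens <- study_lenses$softec_hd
  zp <- zero_error_powers("haigis", sub, lens)
  err <- replicate_errors("haigis", sub, lens, zp, tolerance_sd = 0)
  expect_identical(err, rep(0, nrow(sub)))
})

test_that("zero-tolerance studies give identically zero error and 100% within all thresholds", {
  cohort <- small_cohort(10)
  sub <- cohort[cohort$lens_name == "Akreos AO", ]
  st <- run_mc_study("haigis", sub, study_lenses$akreos_ao,
                     tolerance_sd = 0, seed = 3)
  expect_true(all(st$errors == 0))
  expect_true(all(st$replicates$medae == 0))
  expect_true(all(st$replicates$pct_within_0.25 == 100))
  expect_true(all(st$replicates$pct_within_1.00 == 100))
})

test_that("studies are reproducible and replicate substreams are order-independent", {
  cohort <- small_cohort(10)
  sub <- cohort[cohort$lens_name == "Akreos AO", ]
  lens <- study_lenses$akreos_ao
  s1 <- run_mc_study("haigis", sub, lens, seed = 9)
  s2 <- run_mc_study("haigis", sub, lens, seed = 9)
  expect_identical(s1$errors, s2$errors)
  expect_identical(s1$replicates, s2$replicates)
  # a longer run reproduces the shorter run's replicates exactly: replicate
  # i depends only on (seed, i), not on how many replicates surround it
  s3 <- run_mc_study("haigis", sub, lens, seed = 9, n_replicates = 15)
  expect_identical(s3$errors[, 1:10], s1$errors)
})

test_that("error distribution is symmetric about zero at large n", {
  eye <- data.frame(K_D = 44.4, ACD_mm = 3.15, AL_mm = 23.43)
  lens <- study_lenses$akreos_ao
  eye$postop_se_D <- predict_refraction("haigis", eye, lens, 20.5)
  big <- eye[rep(1, 1e5), , drop = FALSE]
  st <- run_mc_study("haigis", big, lens, n_replicates = 1, seed = 12)
  e <- st$errors[, 1]
  g1 <- mean((e - mean(e))^3) / sd(e)^3
  expect_lt(abs(g1), 0.1)
  expect_lt(abs(mean(e)), 0.005)
})

test_that("MedAE scales linearly with the tolerance SD", {
  cohort <- small_cohort(20, seed = 4)
  sub <- cohort[cohort$lens_name == "Akreos AO", ]
  lens <- study_lenses$akreos_ao
  sds <- c(0.05, 0.1, 0.2, 0.35, 0.5)
  medae <- vapply(sds, function(s)
    unname(run_mc_study("haigis", sub, lens, tolerance_sd = s,
                        seed = 14)$aggregate$medae["median"]),
    numeric(1))
  fit <- lm(medae ~ sds)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_gt(coef(fit)["sds"], 0)
})

test_that("aggregates summarize the per-replicate table", {
  cohort <- small_cohort(10, seed = 8)
  sub <- cohort[cohort$lens_name == "Softec HD", ]
  st <- run_mc_study("srkt", sub, study_lenses$softec_hd, seed = 15)
  expect_equal(unname(st$aggregate$medae["median"]),
               median(st$replicates$medae))
  expect_equal(unname(st$aggregate$medae["min"]), min(st$replicates$medae))
  p25 <- st$aggregate$pct_within[["0.25"]]
  expect_equal(unname(p25["pooled"]),
               100 * mean(abs(as.vector(st$errors)) <= 0.25))
  # pooled summary sees every replicate-eye
  expect_equal(st$aggregate$pooled$n, st$n_eyes * st$n_replicates)
})
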