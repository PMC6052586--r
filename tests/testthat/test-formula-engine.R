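# SRK/T and Haigis engines: intermediates, forward prediction, inversion,
# grid rounding.

test_that("SRK/T intermediates match the published equations on an average eye", {
  im <- srkt_intermediates(K = 44.41, AL = 23.42, a_constant = 118.24)
  # frozen values from an independent line-by-line evaluation of the
  # published equations
  expect_equal(im$r, 337.5 / 44.41, tolerance = 1e-12)
  expect_equal(im$lcor, 23.42)
  expect_equal(im$cw, 12.622270, tolerance = 1e-5)
  expect_equal(im$h, 3.365954, tolerance = 1e-5)
  expect_equal(im$acd_const, 5.113981, tolerance = 1e-5)
  expect_equal(im$offset, 1.777981, tolerance = 1e-5)
  expect_equal(im$elp, 5.143935, tolerance = 1e-5)
  expect_equal(im$lopt, 23.601768, tolerance = 1e-5)
})

test_that("SRK/T corrected length is continuous at the 24.2 mm cutoff and H is clamped", {
  at <- srkt_intermediates(44, 24.2, 118.24)
  expect_equal(at$lcor, 24.2, tolerance = 1e-12)
  just_above <- srkt_intermediates(44, 24.2 + 1e-6, 118.24)
  expect_equal(just_above$lcor, 24.2, tolerance = 1e-3)
  # very steep small cornea: sqrt argument goes negative, H collapses to r
  steep <- srkt_intermediates(K = 58, AL = 27, a_constant = 118.24)
  expect_equal(steep$h, steep$r, tolerance = 1e-12)
  expect_true(all(is.finite(unlist(steep))))
})

test_that("domain errors are raised for invalid biometry", {
  expect_error(srkt_intermediates(-1, 23, 118.24), "K must be positive")
  expect_error(srkt_intermediates(44, 40, 118.24), "18-32")
})

test_that("Haigis effective lens position is the stated linear form", {
  d <- haigis_elp(ACD = 3.14, AL = 23.42, a0 = 1.706, a1 = 0.279, a2 = 0.087)
  expect_equal(d, 4.6196, tolerance = 1e-9)
  # exact linearity in a0
  set.seed(11)
  for (i in 1:20) {
    acd <- runif(1, 2, 4); al <- runif(1, 20, 27); delta <- runif(1, -1, 1)
    expect_equal(haigis_elp(acd, al, 1.2 + delta, 0.3, 0.1) -
                   haigis_elp(acd, al, 1.2, 0.3, 0.1), delta,
                 tolerance = 1e-12)
  }
})

test_that("both engines agree with the published power-form oracles", {
  eyes <- random_eyes(1000, seed = 101)
  powers <- runif(1000, 12, 28)
  lens <- study_lenses$akreos_ao
  ref_srkt <- predict_refraction("srkt", eyes, lens, powers)
  ref_haigis <- predict_refraction("haigis", eyes, lens, powers)
  for (i in seq_len(1000)) {
    expect_equal(ref_srkt[i],
                 oracle_srkt_refraction(powers[i], eyes$K_D[i], eyes$AL_mm[i],
                                        lens$a_constant),
                 tolerance = 1e-9)
    expect_equal(ref_haigis[i],
                 oracle_haigis_refraction(powers[i], eyes$K_D[i],
                                          eyes$ACD_mm[i], eyes$AL_mm[i],
                                          lens$haigis_a0, lens$haigis_a1,
                                          lens$haigis_a2),
                 tolerance = 1e-9)
  }
})

test_that("predicted refraction is strictly decreasing in IOL power", {
  eyes <- random_eyes(25, seed = 7)
  grid <- seq(5, 35, by = 0.5)
  for (f in c("srkt", "haigis")) {
    for (i in seq_len(nrow(eyes))) {
      refs <- predict_refraction(f, eyes[i, , drop = FALSE],
                                 study_lenses$softec_hd, grid)
      expect_true(all(diff(refs) < 0))
    }
  }
})

test_that("spectacle-plane sensitivity to power is between 0.4 and 1.0", {
  eyes <- random_eyes(50, seed = 13)
  for (f in c("srkt", "haigis")) {
    p0 <- power_for_target(f, eyes, study_lenses$akreos_ao, 0)
    sens <- abs(predict_refraction(f, eyes, study_lenses$akreos_ao, p0 + 0.5) -
                  predict_refraction(f, eyes, study_lenses$akreos_ao, p0 - 0.5))
    expect_true(all(sens > 0.4 & sens < 1.0))
  }
})

test_that("a one-diopter power step moves an average eye's refraction by 0.55-0.75 D", {
  eye <- data.frame(K_D = 44.41, ACD_mm = 3.14, AL_mm = 23.42)
  for (f in c("srkt", "haigis")) {
    p0 <- power_for_target(f, eye, study_lenses$akreos_ao, 0)
    dref <- predict_refraction(f, eye, study_lenses$akreos_ao, p0) -
      predict_refraction(f, eye, study_lenses$akreos_ao, p0 + 1)
    expect_gt(dref, 0.55)
    expect_lt(dref, 0.75)
  }
})

test_that("power_for_target inverts predict_refraction", {
  eyes <- random_eyes(100, seed = 23)
  lens <- study_lenses$softec_hd
  for (f in c("srkt", "haigis")) {
    # definitional round trip at a fixed power
    ref <- predict_refraction(f, eyes, lens, 21.0)
    expect_equal(power_for_target(f, eyes, lens, ref), rep(21, 100),
                 tolerance = 1e-8)
    # round trip across the clinical target range
    targets <- runif(100, -3, 1)
    p <- power_for_target(f, eyes, lens, targets)
    expect_equal(predict_refraction(f, eyes, lens, p), targets,
                 tolerance = 1e-7)
    # myopic targets need more power
    p_myopic <- power_for_target(f, eyes, lens, -0.5)
    p_plano <- power_for_target(f, eyes, lens, 0)
    expect_true(all(p_myopic > p_plano))
  }
})

test_that("production root-finder agrees with brute-force bisection", {
  eyes <- random_eyes(100, seed = 31)
  lens <- study_lenses$akreos_ao
  targets <- runif(100, -2, 0.5)
  for (f in c("srkt", "haigis")) {
    p <- power_for_target(f, eyes, lens, targets)
    for (i in seq_len(nrow(eyes))) {
      ei <- eyes[i, , drop = FALSE]
      pb <- oracle_bisect(function(P)
        predict_refraction(f, ei, lens, P) - targets[i], -10, 40)
      expect_equal(p[i], pb, tolerance = 1e-7)
    }
  }
})

test_that("power_for_target reports an unreachable target", {
  eye <- data.frame(K_D = 44, ACD_mm = 3.1, AL_mm = 23.4)
  expect_error(power_for_target("srkt", eye, study_lenses$akreos_ao, -25),
               "no IOL power")
})

test_that("grid rounding snaps to the interval, ties toward lower power", {
  akreos <- study_lenses$akreos_ao   # 0.50 D grid
  softec <- study_lenses$softec_hd   # 0.25 D grid
  expect_equal(round_to_grid(20.60, akreos), 20.50)
  expect_equal(round_to_grid(20.60, softec), 20.50)
  expect_equal(round_to_grid(20.75, akreos), 20.50)  # exact tie, lower wins
  expect_equal(round_to_grid(20.875, softec), 20.75) # tie on the 0.25 grid
  expect_equal(round_to_grid(20.90, akreos), 21.00)
  # clamped to the labelled range
  expect_equal(round_to_grid(c(12, 30), akreos), c(15.5, 25.0))
  # never further than half an interval (within range)
  set.seed(3)
  p <- runif(200, 16, 24.5)
  expect_true(all(abs(round_to_grid(p, akreos) - p) <= 0.25 + 1e-12))
  expect_true(all(abs(round_to_grid(p, softec) - p) <= 0.125 + 1e-12))
})

test_that("lens registry round-trips through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_lens_registry(study_lenses, path)
  back <- read_lens_registry(path)
  expect_equal(back, study_lenses)
  shipped <- read_lens_registry(
    system.file("extdata", "lens_registry.json", package = "iolmc"))
  expect_equal(shipped$akreos_ao$tolerance_sd, 0.40)
  expect_equal(shipped$softec_hd$tolerance_sd, 0.11)
  expect_equal(shipped$softec_hd$a_constant, 118.17)
})
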