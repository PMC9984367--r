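test_that("autocorrelation is normalized, symmetric and offset-invariant", {
  hf <- anisotropic_field(64, c(6, 6), seed = 3)
  am <- autocorrelation(hf)
  expect_equal(am$R[am$center[1], am$center[2]], 1)
  expect_lte(max(abs(am$R)), 1 + 1e-9)
  shifted <- height_field(hf$values + 17.3, hf$pixel_scale)
  expect_equal(autocorrelation(shifted)$R, am$R, tolerance = 1e-10)
  expect_error(autocorrelation(height_field(matrix(1, 8, 8))), "constant")
})

test_that("autocorrelation equals brute-force circular correlation on small fields", {
  set.seed(11)
  for (n in c(8, 16, 31)) {
    z <- matrix(rnorm(n * n), n, n)
    am <- autocorrelation(height_field(z))
    # un-centre the map back to lag (0,0) at [1,1]
    cr <- am$center[1]; cc <- am$center[2]
    R <- am$R[c(cr:n, seq_len(cr - 1)), c(cc:n, seq_len(cc - 1))]
    expect_equal(R, oracle_autocorrelation(z), tolerance = 1e-10)
  }
})

test_that("white-noise autocorrelation is near zero off the origin", {
  set.seed(5)
  n <- 128
  hf <- height_field(matrix(rnorm(n * n), n, n))
  am <- autocorrelation(hf)
  off <- am$R
  off[am$center[1], am$center[2]] <- NA
  expect_lt(stats::quantile(abs(off), 0.99, na.rm = TRUE), 3 / n)
})

test_that("anisotropy ratio recovers prescribed correlation-length ratios", {
  str_of <- function(lens, seeds = 1:5, n = 256) {
    mean(vapply(seeds, function(s)
      anisotropy_ratio(autocorrelation(
        anisotropic_field(n, lens, seed = s)))$Str, numeric(1)))
  }
  expect_gt(str_of(c(8, 8)), 0.9)
  expect_equal(str_of(c(4, 16)), 0.25, tolerance = 0.1)
})

test_that("anisotropy ratio is equivariant under 90-degree rotation", {
  hf <- anisotropic_field(128, c(4, 12), seed = 2)
  s1 <- anisotropy_ratio(autocorrelation(hf))$Str
  rot <- t(hf$values)[, rev(seq_len(ncol(hf$values)))]
  s2 <- anisotropy_ratio(autocorrelation(height_field(rot)))$Str
  expect_equal(s1, s2, tolerance = 0.02 * s1)
})

test_that("anisotropy ratio errors when the threshold is never crossed", {
  # a map whose central lobe never decays to the threshold
  am <- structure(list(R = matrix(0.9, 33, 33), lag_scale = 1,
                       center = c(17, 17)),
                  class = "acf_map")
  am$R[17, 17] <- 1
  expect_error(anisotropy_ratio(am), "insufficient extent")
})

test_that("structure function matches the brute-force pair loop exactly", {
  set.seed(21)
  for (n in c(8, 16, 32)) {
    z <- matrix(rnorm(n * n), n, n)
    sf <- structure_function(height_field(z), max_lag_fraction = 0.5)
    expect_equal(sf$S_tau,
                 oracle_structure_function(z, max(sf$tau_um)),
                 tolerance = 1e-12)
  }
})

test_that("structure function has the closed-form values on a linear ramp", {
  n <- 32
  z <- matrix(seq_len(n), n, n)        # z = row index
  sf <- structure_function(height_field(z), max_lag_fraction = 0.25)
  # row-offset pairs differ by tau, column-offset pairs by 0;
  # equal pair counts per axis on a square field give S = tau^2 / 2
  expect_equal(sf$S_tau, sf$tau_um^2 / 2, tolerance = 1e-12)
})

test_that("white-noise structure function plateaus at twice the variance", {
  set.seed(31)
  z <- matrix(rnorm(128 * 128, sd = 2), 128, 128)
  sf <- structure_function(height_field(z))
  expect_equal(mean(sf$S_tau), 2 * 4, tolerance = 0.05)
  sl <- scale_length(sf)
  expect_true(sl$converged)
  expect_lte(sl$tau_c_um, 2)          # immediate plateau
})

test_that("fractal fit is exact on a noiseless power law", {
  tau <- 1:40
  sf <- make_sf(tau, 4 * tau^1.0, Sq = sqrt(max(4 * tau) )) # plateau above range
  fit <- fit_fractal(sf)
  expect_equal(fit$alpha, 1, tolerance = 1e-10)
  expect_equal(fit$D, 2.5, tolerance = 1e-10)
  expect_equal(fit$K, 4, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  mono <- monofractal_check(sf, fit)
  expect_true(mono$monofractal)
  expect_lt(mono$max_residual, 1e-10)
})

test_that("fractal fit recovers D = 3 - H on synthetic self-affine surfaces", {
  for (h in c(0.3, 0.7)) {
    d <- mean(vapply(1:3, function(s)
      fit_fractal(structure_function(fbm_surface(256, h, seed = s)))$D,
      numeric(1)))
    expect_equal(d, 3 - h, tolerance = 0.1)
  }
})

test_that("metrics respond correctly to affine height transforms", {
  hf <- fbm_surface(128, 0.5, seed = 13)
  sf1 <- structure_function(hf)
  fit1 <- fit_fractal(sf1)
  scaled <- height_field(3 * hf$values + 5, hf$pixel_scale)
  sf2 <- structure_function(scaled)
  fit2 <- fit_fractal(sf2)
  expect_equal(sf2$S_tau, 9 * sf1$S_tau, tolerance = 1e-9)
  expect_equal(fit2$K, 9 * fit1$K, tolerance = 1e-6)
  expect_equal(fit2$D, fit1$D, tolerance = 1e-9)
  expect_equal(attr(sf2, "Sq"), 3 * attr(sf1, "Sq"), tolerance = 1e-9)
  # tau_c unchanged: S and the plateau 2 Sq^2 scale together
  expect_equal(fit2$tau_c_um, fit1$tau_c_um, tolerance = 1e-6)
  s_str1 <- anisotropy_ratio(autocorrelation(hf))$Str
  s_str2 <- anisotropy_ratio(autocorrelation(scaled))$Str
  expect_equal(s_str1, s_str2, tolerance = 1e-9)
})

test_that("corner scale length grows with the Hurst exponent", {
  tc <- function(h) mean(vapply(1:3, function(s) {
    sf <- structure_function(fbm_surface(256, h, seed = s))
    scale_length(sf)$tau_c_um
  }, numeric(1)))
  expect_lt(tc(0.3), tc(0.8))
})

test_that("monofractal check rejects a two-regime structure function", {
  tau <- 1:60
  s <- ifelse(tau <= 20, tau^0.4, 20^0.4 * (tau / 20)^1.6)
  sf <- make_sf(tau, s, Sq = 1e6)  # plateau far above: full range fitted
  fit <- fit_fractal(sf)
  mono <- monofractal_check(sf, fit)
  expect_false(mono$monofractal)
  expect_gt(mono$slope_difference, 0.5)
  expect_gt(mono$max_residual, 0.1)
})

test_that("fbm fields register as monofractal", {
  for (s in 1:3) {
    sf <- structure_function(fbm_surface(256, 0.5, seed = s))
    expect_true(monofractal_check(sf)$monofractal)
  }
})

test_that("fractal fit input validation", {
  sf <- make_sf(1:4, (1:4)^1, Sq = 100)
  expect_error(fit_fractal(sf), "fewer than 6")
  sfn <- make_sf(1:20, c(1, 2, -3, (4:20)^1), Sq = 100)
  expect_error(fit_fractal(sfn), "non-positive")
})
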