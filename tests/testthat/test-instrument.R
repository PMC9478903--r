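test_that("wire transmission follows Beer-Lambert through the chord", {
  # zero optical depth: fully transparent wire
  cfg <- wire_phantom(optical_depth = 0, background = 0.8)
  sc <- make_wire_scene(cfg, c(32, 48), pitch = 0.52)
  expect_equal(unclass(sc), matrix(0.8, 32, 48), tolerance = 1e-12,
               ignore_attr = TRUE)
  # center-chord optical depth ln 2 halves the transmission on the axis
  expect_equal(wire_transmission(0, diameter = 0.4, optical_depth = log(2),
                                 background = 0.9),
               0.45, tolerance = 1e-12)
  # outside the wire the background is untouched
  expect_equal(wire_transmission(0.3, diameter = 0.4, optical_depth = 5,
                                 background = 1), 1)
})

test_that("wire rendering agrees with a supersampled oracle within 1%", {
  cfg <- wire_phantom(diameter = 0.8, orientation = 25, optical_depth = 2,
                      background = 1)
  shape <- c(24, 32); pitch <- 0.52
  sc <- make_wire_scene(cfg, shape, pitch)
  # 10x supersampling oracle: average transmission over a 10x10 subgrid
  th <- cfg$orientation * pi / 180
  nvec <- c(cos(th), -sin(th))
  sub <- (seq_len(10) - 0.5) / 10 - 0.5
  oracle <- matrix(0, shape[1], shape[2])
  for (i in seq_len(shape[1])) {
    for (j in seq_len(shape[2])) {
      px <- (i - 1 + 0.5 - shape[1] / 2) * pitch
      py <- (j - 1 + 0.5 - shape[2] / 2) * pitch
      rho <- abs(outer((px + sub * pitch) * nvec[1],
                       (py + sub * pitch) * nvec[2], "+"))
      oracle[i, j] <- mean(wire_transmission(rho, cfg$diameter,
                                             cfg$optical_depth, cfg$background))
    }
  }
  absorbed_pkg <- sum(cfg$background - sc)
  absorbed_orc <- sum(cfg$background - oracle)
  expect_lt(abs(absorbed_pkg - absorbed_orc) / absorbed_orc, 0.01)
})

test_that("a wire outside the field warns and leaves the background uniform", {
  cfg <- wire_phantom(diameter = 0.4, offset = 100)  # 100 mm off-center
  sc <- NULL
  expect_warning(sc <- make_wire_scene(cfg, c(16, 16), pitch = 0.52),
                 "outside the field")
  expect_equal(unclass(sc), matrix(1, 16, 16), ignore_attr = TRUE)
})

test_that("dilution wells are linear in concentration with 2.0 serial ratio", {
  cfg <- dilution_phantom(radius = 6, gain = 1)
  sc <- make_dilution_scene(cfg, c(96, 128), 0.52)
  centers <- attr(sc, "well_centers")
  conc <- attr(sc, "well_concentrations")
  # blank leftmost, ascending to the right
  expect_equal(conc, c(0, 0.74, 1.48, 2.97, 5.93, 11.86))
  plateau <- vapply(seq_len(nrow(centers)), function(k)
    sc[round(centers[k, 1]), round(centers[k, 2])], numeric(1))
  expect_equal(plateau, conc, tolerance = 1e-12)
  # serial 2x dilution between the top pairs
  expect_equal(plateau[6] / plateau[5], 2.0, tolerance = 1e-12)
  expect_equal(plateau[5] / plateau[4], 5.93 / 2.97, tolerance = 1e-12)
  # all-zero concentrations give a zero scene
  z <- make_dilution_scene(dilution_phantom(concentrations = rep(0, 3),
                                            radius = 4), c(48, 64), 0.52)
  expect_equal(max(z), 0)
  # gain scales the plateau
  g2 <- make_dilution_scene(dilution_phantom(radius = 6, gain = 2.5),
                            c(96, 128), 0.52)
  expect_equal(max(g2), 2.5 * 11.86, tolerance = 1e-9)
})

test_that("overlapping or out-of-field wells are config errors", {
  bad <- dilution_phantom(concentrations = c(1, 2),
                          centers = rbind(c(20, 20), c(20, 25)), radius = 5)
  expect_error(make_dilution_scene(bad, c(48, 48), 0.52), "verlapping")
  out <- dilution_phantom(concentrations = c(1), centers = rbind(c(2, 2)),
                          radius = 5)
  expect_error(make_dilution_scene(out, c(48, 48), 0.52), "fit")
})

test_that("effective attenuation matches the diffusion closed form", {
  # hand calculation: sqrt(3 * 0.03 * (0.03 + 12.3)) = sqrt(1.1097)
  expect_equal(effective_attenuation(0.03, 12.3), 1.05342299196,
               tolerance = 1e-10)
  expect_equal(effective_attenuation(1, 0), sqrt(3), tolerance = 1e-12)
})

test_that("depth phantom attenuates exponentially and monotonically", {
  mk <- function(d, blur = FALSE)
    make_depth_scene(depth_phantom(depth = d, emission = 50, blur = blur),
                     c(96, 128), 0.52)
  expect_equal(attr(mk(0), "attenuation"), 1)
  a <- vapply(c(2, 4, 6, 8), function(d) attr(mk(d), "attenuation"), numeric(1))
  expect_true(all(diff(a) < 0))
  mu <- effective_attenuation(0.03, 12.3)
  expect_equal(a, exp(-mu * c(2, 4, 6, 8) / 10), tolerance = 1e-12)
  # peak emission scales with attenuation when blur is off
  expect_equal(max(mk(4)) / max(mk(0)), exp(-mu * 0.4), tolerance = 1e-9)
  # blur preserves the integrated emission (within border leakage)
  sb <- mk(4, blur = TRUE)
  expect_equal(sum(sb), sum(mk(4)), tolerance = 1e-6)
})

test_that("measure equals the double-loop bucket sum", {
  sc <- random_scene(c(6, 8), 21)
  pat <- fourier_pattern(2, 3, 0, c(6, 8))
  ref <- 0
  for (x in 1:6) for (y in 1:8) ref <- ref + sc[x, y] * pat[x, y]
  expect_equal(measure(sc, pat), ref, tolerance = 1e-12)
  # zero scene
  expect_equal(measure(fsi_scene(matrix(0, 6, 8)), pat), 0)
  # uniform scene: c times the pattern sum
  expect_equal(measure(fsi_scene(matrix(2.5, 6, 8)), pat), 2.5 * sum(pat),
               tolerance = 1e-12)
  expect_error(measure(sc, matrix(1, 4, 4)), "match")
})

test_that("measure is linear in the scene at zero noise", {
  set.seed(31)
  s1 <- matrix(runif(48), 6, 8); s2 <- matrix(runif(48), 6, 8)
  pat <- fourier_pattern(1, 5, 2 * pi / 3, c(6, 8))
  a <- 2.3; b <- -0.7
  mixed <- a * s1 + b * s2
  mixed[mixed < 0] <- 0  # scenes must be nonnegative; clamp the combination
  lhs <- measure(fsi_scene(mixed), pat)
  rhs <- sum(mixed * pat)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_equal(measure(fsi_scene(s1 + s2), pat),
               measure(fsi_scene(s1), pat) + measure(fsi_scene(s2), pat),
               tolerance = 1e-9)
})

test_that("acquire composes measure over the plan and is reproducible", {
  sc <- random_scene(c(16, 16), 41)
  plan <- circular_sampling_plan(c(16, 16), 0.3)
  ms <- acquire(sc, plan, use_binary = FALSE, noise = noise_model())
  expect_equal(nrow(ms), 3 * nrow(plan))
  # zero noise grayscale responses reproduce measure() exactly
  for (i in c(1, 7, nrow(plan))) {
    for (p in 0:2) {
      pat <- fourier_pattern(plan$u[i], plan$v[i], phase_steps()[p + 1], c(16, 16))
      expect_equal(ms$D[ms$index == plan$index[i] & ms$phase_index == p],
                   measure(sc, pat), tolerance = 1e-9)
    }
  }
  # fixed seed: bit-identical rerun
  nz <- noise_model(gaussian_sigma = 2, ambient_offset = 10, poisson = TRUE,
                    seed = 99)
  m1 <- acquire(sc, plan, use_binary = TRUE, noise = nz)
  m2 <- acquire(sc, plan, use_binary = TRUE, noise = nz)
  expect_identical(m1$D, m2$D)
  # different seed differs
  nz2 <- noise_model(gaussian_sigma = 2, seed = 100)
  m3 <- acquire(sc, plan, use_binary = TRUE, noise = nz2)
  expect_false(identical(m1$D, m3$D))
})

test_that("ambient offset shifts every response by the same constant", {
  sc <- random_scene(c(8, 8), 5)
  plan <- circular_sampling_plan(c(8, 8), 0.5)
  m0 <- acquire(sc, plan, use_binary = FALSE)
  m1 <- acquire(sc, plan, use_binary = FALSE,
                noise = noise_model(ambient_offset = 123.4))
  expect_equal(m1$D - m0$D, rep(123.4, nrow(m0)), tolerance = 1e-12)
})

test_that("measurement sets round-trip through CSV plus sidecar", {
  sc <- random_scene(c(8, 12), 6)
  plan <- circular_sampling_plan(c(8, 12), 0.4)
  ms <- acquire(sc, plan, use_binary = TRUE,
                noise = noise_model(gaussian_sigma = 1, seed = 4))
  path <- file.path(tempdir(), "ms.csv")
  write_measurements_csv(ms, path)
  back <- read_measurements_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ms), tolerance = 1e-12)
  expect_equal(attr(back, "meta")$shape, c(8, 12))
  expect_true(attr(back, "meta")$use_binary)
  file.remove(path, paste0(path, ".meta.json"))
})

test_that("scenes round-trip through PGM and TIFF with physical metadata", {
  sc <- make_depth_scene(depth_phantom(depth = 2, emission = 7), c(24, 32), 0.52)
  for (ext in c("pgm", "tif")) {
    path <- file.path(tempdir(), paste0("scene.", ext))
    write_scene(sc, path)
    back <- read_scene(path)
    expect_equal(attr(back, "pitch"), 0.52)
    expect_equal(attr(back, "modality"), "fluorescence")
    expect_equal(unclass(back), unclass(sc), tolerance = max(sc) / 65535 * 1.01,
                 ignore_attr = TRUE)
    file.remove(path, paste0(path, ".meta.json"))
  }
})

test_that("scene constructor rejects invalid intensities", {
  expect_error(fsi_scene(matrix(-1, 2, 2)), "nonnegative")
  expect_error(fsi_scene(matrix(c(1, NA, 1, 1), 2, 2)), "finite|nonnegative")
  expect_error(fsi_scene(matrix(Inf, 2, 2)), "finite")
})
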