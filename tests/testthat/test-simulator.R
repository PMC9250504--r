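test_that("windowed sinusoid matches its analytic form and bounds", {
  sp <- source_spec(center = 0.5, sigma = 0.12, frequency = 19)
  # at the window center the 19 Hz sinusoid crosses zero: sin(19*pi) = 0
  expect_lt(abs(source_timecourse(sp, 0.5)), 1e-12)
  t <- seq(0, 3.5, by = 1 / 200)
  expect_true(all(abs(source_timecourse(sp, t)) <= 1))
  # independent scalar evaluation at one sigma past the center
  sp2 <- source_spec(center = 1, sigma = 0.12, frequency = 10)
  expect_equal(source_timecourse(sp2, 1 + 0.12),
               exp(-0.5) * sin(2 * pi * 10 * 1.12), tolerance = 1e-12)
  expect_error(source_spec(sigma = 0), "sigma")
  expect_error(source_timecourse(sp, numeric(0)), "non-empty")
})

test_that("source energy concentrates inside c +/- 3 sigma", {
  t <- seq(0, 3.5, by = 1 / 200)
  for (sp in default_sim_config()$sources) {
    x2 <- source_timecourse(sp, t)^2
    inside <- t >= sp$center - 3 * sp$sigma & t <= sp$center + 3 * sp$sigma
    expect_gt(sum(x2[inside]) / sum(x2), 0.99)
  }
})

test_that("placement draws uniformly and deterministically from region sets", {
  rs <- fix$regions32
  expect_identical(place_sources(rs, 11), place_sources(rs, 11))
  single <- list(occipital = 5L, sensorimotor = 9L, frontal = 2L)
  expect_identical(unname(place_sources(single, 1)), c(5L, 9L, 2L))
  expect_error(place_sources(list(occipital = integer(0)), 1), "empty")
  # chi-square goodness of fit of 10,000 draws against the uniform law
  draws <- vapply(seq_len(10000),
                  function(i) place_sources(rs["occipital"], i)[[1]],
                  integer(1))
  tab <- table(factor(draws, levels = rs$occipital))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("forward projection is linear and exact in the noiseless limit", {
  lf <- fix$lf_fwd32
  x <- rbind(sin(seq(0, 2, length.out = 50)), cos(seq(0, 4, length.out = 50)))
  v <- c(3L, 10L)
  out <- project_and_add_noise(x, v, lf, snr_db = NULL)
  expect_equal(out$y, lf$matrix[, v] %*% x, tolerance = 1e-15)
  # superposition: two sources projected together = sum of single projections
  y1 <- project_and_add_noise(x[1, , drop = FALSE], v[1], lf, snr_db = NULL)$y
  y2 <- project_and_add_noise(x[2, , drop = FALSE], v[2], lf, snr_db = NULL)$y
  expect_equal(out$y, y1 + y2, tolerance = 1e-12)
  # scaling a source scales its potentials exactly
  expect_equal(project_and_add_noise(2 * x, v, lf, snr_db = NULL)$y, 2 * out$y)
  expect_error(project_and_add_noise(x, c(3L, 9999L), lf, NULL), "out of range")
  expect_error(project_and_add_noise(x, 3L, lf, NULL), "vertices")
})

test_that("added noise realizes the configured SNR exactly and reproducibly", {
  lf <- fix$lf_fwd32
  x <- matrix(sin(seq(0, 20, length.out = 200)), 1)
  for (target in c(0, -5, 10)) {
    out <- project_and_add_noise(x, 4L, lf, snr_db = target, rng_seed = 3)
    realized <- 10 * log10(mean(out$y_clean^2) / mean(out$noise^2))
    expect_equal(realized, target, tolerance = 1e-9)
  }
  a <- project_and_add_noise(x, 4L, lf, snr_db = 0, rng_seed = 3)
  b <- project_and_add_noise(x, 4L, lf, snr_db = 0, rng_seed = 3)
  expect_identical(a$y, b$y)
})

test_that("trial generation honors the default study conditions", {
  cfg <- default_sim_config()
  expect_length(cfg$sources, 6)
  expect_equal(vapply(cfg$sources, `[[`, numeric(1), "center"),
               c(0.5, 1, 1.5, 2, 2.5, 3))
  expect_equal(vapply(cfg$sources, `[[`, numeric(1), "frequency"),
               rep(c(19, 10, 7), 2))
  tr <- fix$trial_noisy
  expect_identical(ncol(tr$y), 700L)            # 3.5 s x 200 Hz
  expect_identical(nrow(tr$x_true), 6L)
  # repeated activations reuse the same vertex as their first occurrence
  v <- vapply(tr$sources, `[[`, integer(1), "vertex_index")
  expect_identical(v[4:6], v[1:3])
  expect_equal(tr$sources[[1]]$position,
               unname(fix$lf_fwd32$source_positions[v[1], ]))
})

test_that("dataset generation is deterministic and fully manifested", {
  lf <- fix$lf_fwd32
  d1 <- generate_dataset(lf, n_trials = 4, master_seed = 9,
                         region_sets = fix$regions32)
  d2 <- generate_dataset(lf, n_trials = 4, master_seed = 9,
                         region_sets = fix$regions32)
  expect_identical(d1$trials[[3]]$y, d2$trials[[3]]$y)
  expect_identical(nrow(d1$manifest$sources), 24L)  # 4 trials x 6 sources
  expect_true(all(c("seed", "vertex", "region", "center", "frequency") %in%
                    names(d1$manifest$sources)))
  bad <- default_sim_config()
  bad$sources <- list()
  expect_error(generate_dataset(lf, 2, bad), "no sources")
})

test_that("datasets round-trip through the plain-text serialization", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(fix$lf_fwd32, n_trials = 2, master_seed = 4,
                         region_sets = fix$regions32)
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_length(back$trials, 2)
  expect_equal(back$trials[[1]]$y, ds$trials[[1]]$y, tolerance = 1e-12)
  expect_equal(back$trials[[2]]$x_true, ds$trials[[2]]$x_true, tolerance = 1e-12)
  expect_identical(
    vapply(back$trials[[1]]$sources, `[[`, integer(1), "vertex_index"),
    vapply(ds$trials[[1]]$sources, `[[`, integer(1), "vertex_index"))
  expect_equal(back$trials[[1]]$sources[[2]]$position,
               unname(ds$trials[[1]]$sources[[2]]$position), tolerance = 1e-12)
})
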