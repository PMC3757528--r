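test_that("impulse responses follow the stated closed forms", {
  a10 <- kernel_spec("alpha", ts = 10)
  r <- impulse_response(a10, 30)
  expect_equal(r[1], 0)                       # r(0) = 0
  expect_equal(r[11], exp(-1))                # peak 1/e at t = ts
  expect_equal(which.max(r), 11L)
  # leaky starts at 1 and decays exponentially
  lk <- impulse_response(kernel_spec("leaky", ts = 5), 10)
  expect_equal(lk, exp(-(0:9) / 5))
  # resonant is a damped sine
  rs <- impulse_response(kernel_spec("resonant", ts = 40, omega = 0.1), 20)
  expect_equal(rs, exp(-(0:19) / 40) * sin(0.1 * (0:19)))
  # delayed families are exactly zero before the delay
  da <- impulse_response(kernel_spec("delayed_alpha", ts = 10, delay = 15), 60)
  expect_true(all(da[1:15] == 0))
  expect_equal(da[16:60], impulse_response(a10, 45))
  dg <- impulse_response(kernel_spec("delayed_gaussian", sigma = 3,
                                     delay = 20), 80)
  expect_true(all(dg[1:20] == 0))
  expect_gt(max(dg), 0.99)
  # custom table is returned verbatim (then zero-extended)
  cu <- impulse_response(kernel_spec("custom",
                                     custom_table = c(0, 2, 1)), 3)
  expect_equal(cu, c(0, 2, 1))
})

test_that("kernel_spec rejects family/parameter mismatches", {
  expect_error(kernel_spec("alpha"), "ts")
  expect_error(kernel_spec("alpha", ts = -1), "ts")
  expect_error(kernel_spec("resonant", ts = 10), "omega")
  expect_error(kernel_spec("delayed_gaussian", sigma = 0, delay = 1), "sigma")
  expect_error(kernel_spec("custom"), "custom_table")
  expect_error(kernel_spec("alpha", ts = 10, delay = 5), "delayed")
  expect_error(kernel_spec("alpha", ts = 10, k = 0), "k")
})

test_that("compression matches the logistic form and its bounds", {
  expect_equal(compress(0, 5), 0)
  expect_equal(compress(1, 5), 1 / (1 + exp(-5)) - 0.5)  # ~0.49331
  expect_equal(compress(1, 5), 0.49331, tolerance = 1e-4)
  expect_equal(compress(1e6, 5), 0.5)                    # asymptote
  expect_equal(compress(2, 3, "tanh"), tanh(6) / 2)
  expect_equal(compress(0.37, 5, "none"), 0.37)
  # odd symmetry, bounds, monotonicity (property over a grid; |k*v| kept
  # below ~18 where doubles can still represent the gap to the asymptote
  # for both logistic and tanh)
  v <- seq(-3.5, 3.5, length.out = 401)
  for (kind in c("logistic", "tanh")) {
    a <- compress(v, 5, kind)
    expect_true(all(abs(a) < 0.5))
    expect_equal(a, -rev(a))
    expect_true(all(diff(a) >= 0))
  }
})

test_that("alpha FWHM matches the half-height values and scales linearly", {
  f10 <- kernel_fwhm(kernel_spec("alpha", ts = 10))
  f20 <- kernel_fwhm(kernel_spec("alpha", ts = 20))
  expect_equal(f10, 24.46, tolerance = 1e-3)
  expect_equal(f20, 48.93, tolerance = 1e-3)
  # FWHM / ts ~ 2.446 ("244% of the time constant") across scales
  for (tau in c(2, 7, 31.5, 80)) {
    expect_equal(kernel_fwhm(kernel_spec("alpha", ts = tau)) / tau,
                 2.4463, tolerance = 1e-2)
  }
})

test_that("Gaussian FWHM has its closed form; peaks sit at preferred delays", {
  for (s in c(2, 4.5, 9)) {
    expect_equal(kernel_fwhm(kernel_spec("delayed_gaussian", sigma = s,
                                         delay = 10)),
                 2 * s * sqrt(2 * log(2)), tolerance = 1e-4)
  }
  expect_equal(preferred_delay(kernel_spec("alpha", ts = 10)), 10,
               tolerance = 1e-4)
  expect_equal(preferred_delay(kernel_spec("delayed_alpha", ts = 10,
                                           delay = 15)), 25,
               tolerance = 1e-4)
  # resonant argmax against a brute-force grid oracle
  spec <- kernel_spec("resonant", ts = 40, omega = 0.1,
                      truncation = 30)  # first lobe only
  tt <- seq(0, 30, by = 1e-4)
  oracle <- tt[which.max(exp(-tt / 40) * sin(0.1 * tt))]
  expect_equal(preferred_delay(spec), oracle, tolerance = 1e-3)
})

test_that("multimodal kernels are refused for FWHM analysis", {
  # damped sine over several periods has many comparable local maxima
  spec <- kernel_spec("resonant", ts = 200, omega = 0.5)
  expect_error(kernel_fwhm(spec), "multimodal")
})

test_that("kernel banks are deterministic with the documented ts range", {
  b1 <- sample_kernel_bank(100, "alpha", t_max = 200, seed = 11)
  b2 <- sample_kernel_bank(100, "alpha", t_max = 200, seed = 11)
  expect_equal(b1, b2)
  tsv <- vapply(b1, function(k) k$ts, 0)
  expect_true(all(tsv > 1 & tsv <= 100))
  # mean ts ~ t_max/4 by the law of large numbers (U(1, 100): mean 50.5)
  big <- sample_kernel_bank(1e4, "alpha", t_max = 200, seed = 12)
  expect_equal(mean(vapply(big, function(k) k$ts, 0)), 50.5,
               tolerance = 0.02)
  # heuristic mode pins ts at t_max/2
  h <- sample_kernel_bank(5, "alpha", t_max = 200, seed = 13,
                          ts_mode = "heuristic")
  expect_true(all(vapply(h, function(k) k$ts, 0) == 100))
  # delayed families draw delays in (0, t_max)
  d <- sample_kernel_bank(200, "delayed_gaussian", t_max = 100, seed = 14)
  dl <- vapply(d, function(k) k$delay, 0)
  expect_true(all(dl >= 0 & dl <= 100))
  expect_error(sample_kernel_bank(5, "nope", 100, 1), "unknown")
})

test_that("default truncation drops a negligible tail", {
  for (spec in list(kernel_spec("alpha", ts = 12),
                    kernel_spec("leaky", ts = 30),
                    kernel_spec("delayed_alpha", ts = 8, delay = 40),
                    kernel_spec("delayed_gaussian", sigma = 5, delay = 25))) {
    f <- skimnet:::kernel_fun(spec)
    tail_t <- seq(spec$truncation, spec$truncation + 2000, by = 0.5)
    peak <- max(abs(impulse_response(spec)))
    expect_lt(max(abs(f(tail_t))), 1e-6 * peak)
    # dropped L1 mass below 1e-4 of the retained mass
    body <- sum(abs(impulse_response(spec)))
    dropped <- sum(abs(f(seq(spec$truncation, spec$truncation + 5000))))
    expect_lt(dropped / body, 1e-4)
  }
})

test_that("custom kernel tables load from CSV", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "kernel.csv")
  utils::write.csv(data.frame(timestep = 0:3, value = c(0, 1, 0.5, 0.1)),
                   f, row.names = FALSE)
  ks <- read_kernel_table(f)
  expect_equal(impulse_response(ks, 4), c(0, 1, 0.5, 0.1))
  utils::write.csv(data.frame(timestep = c(0, 2, 3), value = 1:3), f,
                   row.names = FALSE)
  expect_error(read_kernel_table(f), "0, 1, 2")
})
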