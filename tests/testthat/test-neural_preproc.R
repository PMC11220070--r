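test_that("a single spike smooths to a unit-mass Gaussian bump", {
  events <- data.frame(unit_id = 1L, time_s = 10.0)
  trials <- data.frame(t_stim_on_s = 10.0)
  tens <- events_to_ifr(events, trials, bin_ms = 10, sigma_ms = 100,
                        window = c(-1.5, 3))
  ifr <- tens$rates[1, 1, ]
  dt <- 0.01
  expect_equal(sum(ifr) * dt, 1, tolerance = 1e-6)   # integral = 1 spike
  expect_equal(tens$time_s[which.max(ifr)], 0.005, tolerance = 0.02)
  # empty unit stays all-zero
  events2 <- rbind(events, data.frame(unit_id = 2L, time_s = 200))
  tens2 <- events_to_ifr(events2, trials, units = c(1L, 2L))
  expect_true(all(tens2$rates[1, 2, ] == 0))
})

test_that("homogeneous Poisson spiking recovers its rate", {
  set.seed(31)
  rate <- 20
  trials <- data.frame(t_stim_on_s = seq(10, by = 10, length.out = 12))
  spikes <- sort(cumsum(rexp(3000, rate)))
  spikes <- spikes[spikes < 140]
  events <- data.frame(unit_id = 1L, time_s = spikes)
  tens <- events_to_ifr(events, trials)
  est <- mean(tens$rates[, 1, ])
  se <- sqrt(rate / (12 * 4.5))
  expect_lt(abs(est - rate), 3 * se)
})

test_that("smoothing is linear in the spike trains", {
  trials <- data.frame(t_stim_on_s = 0)
  a <- data.frame(unit_id = 1L, time_s = c(0.1, 0.5, 0.9))
  b <- data.frame(unit_id = 1L, time_s = c(0.3, 1.2))
  both <- rbind(a, b)
  ta <- events_to_ifr(a, trials)$rates[1, 1, ]
  tb <- events_to_ifr(b, trials)$rates[1, 1, ]
  tab <- events_to_ifr(both[order(both$time_s), ], trials)$rates[1, 1, ]
  expect_equal(tab, ta + tb, tolerance = 1e-10)
})

test_that("baseline z-scoring matches closed-form values and flags", {
  # deterministic tensor with known mean/sd structure
  n_tr <- 6; n_t <- 18
  time_s <- seq(-1.5, 3, length.out = n_t)
  rates <- array(0, c(n_tr, 2, n_t))
  rates[, 1, ] <- 2                      # constant neuron -> zero-sd path
  set.seed(8)
  vals <- rnorm(n_tr * n_t, 5, 2)
  rates[, 2, ] <- vals
  tens <- population_tensor(rates, time_s, data.frame(id = 1:n_tr))
  z <- zscore_baseline(tens, baseline = c(-1.5, 0))
  expect_identical(z$meta$zero_sd_units, 1L)
  expect_true(all(z$rates[, 1, ] == 0))
  bidx <- which(time_s >= -1.5 & time_s < 0)
  expected <- (rates[, 2, ] - mean(rates[, 2, bidx])) / sd(rates[, 2, ])
  expect_equal(z$rates[, 2, ], expected)
  # standardized baseline mean is ~0 per neuron
  expect_lt(abs(mean(z$rates[, 2, bidx])), 1e-12)
})
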