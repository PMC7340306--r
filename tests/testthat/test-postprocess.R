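test_that("standard-population weights are normalized and label-checked", {
  std <- us_standard_population_2000()
  expect_equal(sum(std$weight), 1, tolerance = 1e-12)
  w <- standard_weights(c("65-74", "75-84", "85+"))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(unname(w[1]), 66037 / (66037 + 44842 + 15508))
  expect_error(standard_weights(c("65-74", "not-a-band")), "not-a-band")
})

# minimal fit-like object for standardization tests
fake_fit <- function(lambda, groups, years = NULL) {
  d <- dim(lambda)
  list(lambda = lambda, unit_ids = paste0("u", seq_len(d[2])),
       group_labels = groups$group,
       years = years %||% seq(2000, length.out = d[4]),
       chain = rep(1L, d[1]), groups = groups)
}

test_that("direct standardization is the weighted stratum average", {
  groups <- tibble::tibble(group = c("a", "b"),
                           age_band = c("65-74", "75-84"))
  lam <- array(NA_real_, c(2, 1, 2, 1))
  lam[, 1, 1, 1] <- 100e-5  # stratum rates per person-year
  lam[, 1, 2, 1] <- 300e-5

  # explicit toy weights
  std5050 <- tibble::tibble(age_band = c("65-74", "75-84"),
                            weight = c(0.5, 0.5))
  out <- age_standardize(fake_fit(lam, groups), std = std5050,
                         groups = groups)
  expect_equal(unname(out$draws$all[1, 1, 1]) * 1e5, 200)

  std7030 <- tibble::tibble(age_band = c("65-74", "75-84"),
                            weight = c(0.7, 0.3))
  out2 <- age_standardize(fake_fit(lam, groups), std = std7030,
                          groups = groups)
  expect_equal(unname(out2$draws$all[1, 1, 1]) * 1e5, 160)

  # convexity identity: equal stratum rates pass through unchanged
  lam[, 1, 2, 1] <- 100e-5
  out3 <- age_standardize(fake_fit(lam, groups), std = std7030,
                          groups = groups)
  expect_equal(unname(out3$draws$all[, 1, 1]) * 1e5, c(100, 100))

  # unmatched labels are reported
  bad <- tibble::tibble(group = c("a", "zzz"), age_band = c("65-74", "75-84"))
  expect_error(age_standardize(fake_fit(lam, groups), groups = bad), "zzz")
})

test_that("standardization commutes with draw-level mixing", {
  set.seed(1)
  groups <- tibble::tibble(group = c("a", "b"),
                           age_band = c("65-74", "75-84"))
  lam <- array(stats::rlnorm(2 * 3 * 2 * 2, -6, 0.3), c(2, 3, 2, 2))
  out <- age_standardize(fake_fit(lam, groups), groups = groups)
  w <- standard_weights(c("65-74", "75-84"))
  # mean over draws of the standardized rate = standardized mean rate
  expect_equal(apply(out$draws$all, c(2, 3), mean),
               w[1] * apply(lam[, , 1, ], c(2, 3), mean) +
                 w[2] * apply(lam[, , 2, ], c(2, 3), mean))
})

test_that("rate summaries use median and interpolated percentiles", {
  arr <- array(0, c(5, 1, 1)); arr[, 1, 1] <- 1:5
  rd <- fake_rate_draws(list(all = arr))
  s <- summarize_rates(rd, per = 1)
  expect_equal(s$rate_per_100k, 3)
  expect_equal(s$ci_low, 1.1)
  expect_equal(s$ci_high, 4.9)

  # constant draws collapse to a point
  arr[] <- 7
  s2 <- summarize_rates(fake_rate_draws(list(all = arr)), per = 1)
  expect_equal(c(s2$rate_per_100k, s2$ci_low, s2$ci_high), c(7, 7, 7))

  # intervals always bracket the median
  set.seed(2)
  arr3 <- array(stats::rlnorm(200 * 4 * 3, -6, 1), c(200, 4, 3))
  s3 <- summarize_rates(fake_rate_draws(list(all = arr3)))
  expect_true(all(s3$ci_low <= s3$rate_per_100k &
                    s3$rate_per_100k <= s3$ci_high))

  arr3[1, 1, 1] <- NaN
  expect_error(summarize_rates(fake_rate_draws(list(all = arr3))),
               "non-finite")
})

test_that("suppression applies the reliability and population rules", {
  mk <- function(point, lo, hi, pops) {
    T <- length(pops)
    list(
      summary = tibble::tibble(unit_id = "u1", group = "all",
                               year = seq_len(T) + 1999,
                               rate_per_100k = point, ci_low = lo,
                               ci_high = hi),
      pop = tibble::tibble(unit_id = "u1", group = "all",
                           year = seq_len(T) + 1999, population = pops)
    )
  }
  # width 110 < point 200: reliable, kept
  a <- mk(200, 150, 260, c(5000, 5000))
  out <- apply_suppression(a$summary, a$pop)
  expect_true(all(out$reliable) && !any(out$suppressed))

  # width 110 >= point 50: unreliable -> suppressed
  b <- mk(50, 10, 120, c(5000, 5000))
  out_b <- apply_suppression(b$summary, b$pop)
  expect_true(all(!out_b$reliable) && all(out_b$suppressed))

  # population exactly 100 in one year: suppressed (strictly greater than
  # 100 is required), even though estimates are reliable
  c_ <- mk(200, 150, 260, c(5000, 100))
  out_c <- apply_suppression(c_$summary, c_$pop)
  expect_true(all(out_c$reliable))
  expect_true(all(out_c$suppressed))
  # ... and 101 everywhere is not
  d <- mk(200, 150, 260, c(101, 101))
  expect_false(any(apply_suppression(d$summary, d$pop)$suppressed))

  # one bad year suppresses the whole series
  e <- list(
    summary = tibble::tibble(unit_id = "u1", group = "all", year = 2000:2001,
                             rate_per_100k = c(200, 50), ci_low = c(150, 10),
                             ci_high = c(260, 120)),
    pop = tibble::tibble(unit_id = "u1", group = "all", year = 2000:2001,
                         population = 5000))
  out_e <- apply_suppression(e$summary, e$pop)
  expect_true(all(out_e$suppressed))

  # masking blanks values but keeps rows
  masked <- mask_suppressed(out_e)
  expect_equal(nrow(masked), 2)
  expect_true(all(is.na(masked$rate_per_100k)))
})

test_that("the set of unsuppressed units is constant across years", {
  set.seed(3)
  scen <- make_scenario("tiny", seed = 3)
  fit <- fit_mstcar(scen$data, scen$graph, groups = scen$groups,
                    control = mstcar_control(n_chains = 2, n_iter = 200,
                                             n_burnin = 100, thin = 1,
                                             seed = 3))
  rs <- apply_suppression(summarize_rates(age_standardize(fit)),
                          scen$data, groups = scen$groups)
  per_year <- tapply(!rs$suppressed, rs$year, sum)
  expect_true(all(per_year == per_year[1]))
})
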