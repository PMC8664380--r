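test_that("AU frequencies are normalized per-class proportions", {
  labs <- c(rep("UpperNone", 3), "AU1+2")
  f <- au_frequency(labs, "upper")
  expect_equal(unname(f["UpperNone"]), 0.75)
  expect_equal(unname(f["AU1+2"]), 0.25)
  expect_equal(sum(f), 1)
  all_neutral <- au_frequency(rep("UpperNone", 10), "upper")
  expect_equal(unname(all_neutral["UpperNone"]), 1)
  set.seed(3)
  rnd <- sample(au_all_classes("lower"), 40, replace = TRUE)
  expect_equal(sum(au_frequency(rnd, "lower")), 1)
  expect_error(au_frequency(character(0), "upper"), "empty")
})

test_that("co-occurrence cells divide by the rarer unit's frame count", {
  # 10 frames: upper AU in 4, lower AU in 6, both in 2 -> 2/4 = 0.5
  upper <- c(rep("AU1+2", 4), rep("UpperNone", 6))
  lower <- c("AU25+26", "AU25+26", rep("LowerNone", 2),
             rep("AU25+26", 4), rep("LowerNone", 2))
  m <- cooccurrence_matrix(upper, lower, units = c("AU1+2", "AU25+26"))
  expect_equal(m["AU1+2", "AU25+26"], 0.5)
  expect_equal(m["AU25+26", "AU1+2"], 0.5)
  expect_equal(m["AU1+2", "AU1+2"], 1)
  # subset case: the rarer unit always co-occurs -> 1.0
  up2 <- c(rep("AU43_5", 3), rep("UpperNone", 7))
  lo2 <- c(rep("AU25+26", 5), rep("LowerNone", 5))
  m2 <- cooccurrence_matrix(up2, lo2, units = c("AU43_5", "AU25+26"))
  expect_equal(m2["AU43_5", "AU25+26"], 1)
  # disjoint units -> 0; absent units -> NA
  up3 <- c("AU1+2", "UpperNone")
  lo3 <- c("LowerNone", "AU25+26")
  m3 <- cooccurrence_matrix(up3, lo3,
                            units = c("AU1+2", "AU25+26", "AU43_5"))
  expect_equal(m3["AU1+2", "AU25+26"], 0)
  expect_true(is.na(m3["AU43_5", "AU1+2"]))
})

test_that("combination proportions count exact per-period matches", {
  upper <- c(rep("UpperNone", 50), rep("AU1+2", 50))
  lower <- c(rep("AU25+26+18i", 25), rep("LowerNone", 75))
  periods <- block_periods(list(enter_exit = rbind(c(0, 100))))
  p <- combination_proportions(upper, lower, periods,
                               c("UpperNone", "AU25+26+18i"))
  expect_equal(unname(p["enter_exit"]), 0.25)
  # period entirely the combination -> 1; absent combination -> 0
  periods2 <- block_periods(list(open = rbind(c(0, 25)),
                                 closed = rbind(c(50, 100))))
  p2 <- combination_proportions(upper, lower, periods2,
                                c("UpperNone", "AU25+26+18i"))
  expect_equal(unname(p2), c(0, 1)[match(names(p2), c("closed", "open"))])
  # split intervals within one period pool their frames
  periods3 <- block_periods(list(open = rbind(c(0, 10), c(20, 30))))
  p3 <- combination_proportions(upper, lower, periods3,
                                c("UpperNone", "AU25+26+18i"))
  expect_equal(unname(p3["open"]), 15 / 20)
  expect_error(block_periods(list(a = rbind(c(0, 10)), b = rbind(c(5, 8)))),
               "overlap")
})

test_that("chi-square test matches closed-form margin arithmetic", {
  # homogeneous table: statistic 0, p = 1
  h <- chi_square_test(matrix(10, 2, 2))
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)
  # all expected counts are 15; statistic = 4 * 25/15 = 6.667
  t2 <- matrix(c(20, 10, 10, 20), 2, 2)
  r <- chi_square_test(t2)
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-9)
  expect_identical(r$df, 1L)
  expect_equal(r$expected, matrix(15, 2, 2), ignore_attr = TRUE)
  expect_equal(r$p_value, stats::pchisq(20 / 3, 1, lower.tail = FALSE))
  # permutation invariance
  r2 <- chi_square_test(t2[2:1, ])
  expect_equal(r2$statistic, r$statistic)
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2, 2)), "degenerate")
})

test_that("firing-rate z-scores follow the baseline normalization", {
  expect_equal(normalize_firing_rate(10, 4, 2), 3)
  expect_equal(normalize_firing_rate(4, 4, 2), 0)
  # scale invariance
  expect_equal(normalize_firing_rate(2 * 10, 2 * 4, 2 * 2),
               normalize_firing_rate(10, 4, 2))
  expect_error(normalize_firing_rate(1, 0, 0), "baseline_sd")
})

test_that("peri-event binning conserves counts and matches direct counting", {
  # single event, spikes placed in one bin
  spikes <- c(10.05, 10.10, 10.12)
  r <- peri_event_rates(spikes, 10, window = c(-0.3, 0.3), bin_ms = 300,
                        baseline = list(mean = 1, sd = 1))
  expect_identical(dim(r$counts), c(1L, 2L))
  # direct interval count: [10 - 0.3, 10) and [10, 10 + 0.3)
  expect_identical(r$counts[1, ],
                   c(sum(spikes >= 9.7 & spikes < 10),
                     sum(spikes >= 10 & spikes < 10.3)))
  expect_identical(sum(r$counts),
                   sum(spikes >= 9.7 & spikes < 10.3))
  # no spikes anywhere: constant negative z = -mean/sd
  r0 <- peri_event_rates(numeric(0), c(5, 9), window = c(-0.6, 0.6),
                         bin_ms = 300, baseline = list(mean = 4, sd = 2))
  expect_true(all(r0$z == -2))
  # Poisson spikes z-scored against a matching baseline stay near 0
  set.seed(21)
  lambda <- 20
  spikes <- cumsum(stats::rexp(12000, lambda))
  events <- seq(60, 500, by = 3.5)
  rp <- peri_event_rates(spikes, events, window = c(-0.6, 0.6), bin_ms = 300,
                         baseline = c(0, 50))
  se <- stats::sd(rp$z) / sqrt(length(rp$z))
  expect_lt(abs(mean(rp$z)), max(3 * se, 0.5))
  # total count conservation inside the window
  direct <- sum(sapply(events, function(ev)
    sum(spikes >= ev - 0.6 & spikes < ev + 0.6)))
  expect_identical(sum(rp$counts), direct)
  expect_error(peri_event_rates(spikes, numeric(0),
                                baseline = c(0, 50)), "at least one event")
  expect_error(peri_event_rates(spikes, 10, baseline = c(0, 0.1)),
               "baseline")
})

test_that("spike and period tables read back from text", {
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "spikes.txt")
  writeLines(c("3.2", "1.1", "2.0"), sp)
  expect_equal(read_spike_times(sp), c(1.1, 2.0, 3.2))
  sp2 <- file.path(dir, "units.csv")
  utils::write.csv(data.frame(unit_id = c("u1", "u2", "u1"),
                              time_s = c(5, 1, 3)), sp2, row.names = FALSE)
  expect_equal(read_spike_times(sp2, "u1"), c(3, 5))
  pt <- file.path(dir, "periods.csv")
  utils::write.csv(data.frame(video_id = "v1",
                              period_name = c("open", "closed"),
                              start_frame = c(0, 100),
                              end_frame = c(100, 130)),
                   pt, row.names = FALSE)
  periods <- read_period_table(pt)
  expect_named(periods, "v1")
  expect_setequal(names(periods$v1), c("open", "closed"))
})
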