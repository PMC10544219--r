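mk_stats <- function(region_class, depth, fraction, substrate = 1000,
                     edits = NULL) {
  n <- max(length(region_class), length(depth), length(fraction))
  region_class <- rep_len(region_class, n)
  depth <- rep_len(depth, n)
  fraction <- rep_len(fraction, n)
  substrate <- rep_len(substrate, n)
  if (is.null(edits)) edits <- pmax(1L, as.integer(round(fraction * substrate)))
  data.frame(window_id = sprintf("w%d", seq_len(n)), chrom = "c1",
             start = seq_len(n) * 100L, end = seq_len(n) * 100L + 29L,
             strand = "+", gene_id = sprintf("g%d", seq_len(n)),
             region_class = region_class,
             substrate_instances = substrate, edit_instances = edits,
             distinct_edited_positions = pmin(edits, 5L),
             read_depth = depth, edit_fraction = fraction,
             stringsAsFactors = FALSE)
}

test_that("ztp tail probabilities match direct pmf summation", {
  for (lambda in c(0.01, 0.1, 1, 5, 20)) {
    for (k in c(1:10, 25, 50)) {
      expect_equal(ztp_pvalue(k, lambda), ztp_oracle(k, lambda),
                   tolerance = 1e-9)
    }
    # truncated pmf is a distribution
    kmax <- ceiling(lambda + 40 * sqrt(lambda) + 100)
    expect_equal(sum(dpois(1:kmax, lambda)) / (1 - exp(-lambda)), 1,
                 tolerance = 1e-9)
  }
  expect_identical(ztp_pvalue(1, 0.37), 1)
  expect_equal(ztp_pvalue(2, 1), ztp_oracle(2, 1), tolerance = 1e-9)
  expect_equal(ztp_pvalue(3, 0.5), ztp_oracle(3, 0.5), tolerance = 1e-9)
  expect_equal(round(ztp_pvalue(2, 1), 6), 0.418023)
  expect_equal(round(ztp_pvalue(3, 0.5), 6), 0.036566)
  expect_error(ztp_pvalue(0, 1), "zero-truncation")
  expect_error(ztp_pvalue(2, 0), "lambda")
})

test_that("ztp p-value is monotone and loses its truncation at large lambda", {
  for (lambda in c(0.05, 0.5, 2, 10)) {
    p <- ztp_pvalue(1:30, lambda)
    expect_true(all(diff(p) < 0))
  }
  for (k in c(2, 5, 12)) {
    p <- ztp_pvalue(k, c(0.1, 0.5, 1, 2, 5, 10))
    expect_true(all(diff(p) > 0))
  }
  # at lambda = 50 the truncation correction is numerically invisible
  expect_equal(ztp_pvalue(40, 50),
               ppois(39, 50, lower.tail = FALSE), tolerance = 1e-12)
  # tiny lambda with large k stays finite and positive
  p <- ztp_pvalue(20, 1e-10)
  expect_gt(p, 0)
  expect_lt(p, 1e-150)
})

test_that("rates stratify by class and depth with strictly-below bins", {
  st <- mk_stats("exon", depth = c(5, 15, 25), fraction = c(0.2, 0.1, 0.06))
  fit <- fit_background(st)
  r <- fit$rates
  # a window of depth 25 falls in the < 30 stratum, whose rate is the mean
  # fraction over all shallower windows
  expect_equal(r$rate[r$region_class == "exon" & r$bin_upper == 30], 0.12)
  expect_equal(unname(predict(fit, st[3, ])), 0.12 * 1000)

  top <- mk_stats("exon", depth = c(50, 60, 100),
                  fraction = c(0.01, 0.02, 0.03))
  fit2 <- fit_background(top)
  expect_equal(fit2$rates$rate[fit2$rates$bin_upper == Inf], 0.02)
  # depth exactly 50 belongs to the top stratum, not "< 50"
  expect_equal(unname(predict(fit2, top[1, ])), 0.02 * 1000)
  # strata below are empty and inherit the top rate
  expect_true(all(fit2$rates$fallback[fit2$rates$bin_upper != Inf]))
  expect_true(all(fit2$rates$rate == 0.02))

  # the stratum ladder is the default 10/20/30/40/50
  expect_equal(fit$thresholds, c(10, 20, 30, 40, 50))
  expect_error(fit_background(st, thresholds = c(20, 10)), "increasing")

  # zero-edit windows enter the mean only on request
  stz <- rbind(st, mk_stats("exon", depth = 5, fraction = 0, edits = 0L))
  f_ex <- fit_background(stz, include_zero_windows = FALSE)
  f_in <- fit_background(stz, include_zero_windows = TRUE)
  expect_equal(f_ex$rates$rate[f_ex$rates$bin_upper == 30], 0.12)
  expect_equal(f_in$rates$rate[f_in$rates$bin_upper == 30],
               mean(c(0.2, 0.1, 0.06, 0)))
})

test_that("window tests combine lambda, ztp p-values and BH", {
  train <- mk_stats("exon", depth = 60, fraction = c(0.005, 0.015))
  fit <- fit_background(train)   # top-stratum rate exactly 0.01
  q <- mk_stats("exon", depth = 60, fraction = 0.01,
                substrate = 100, edits = 1L)
  t1 <- test_windows(q, fit)
  expect_equal(t1$lambda, 1)
  expect_equal(t1$p_raw, 1)
  q2 <- q; q2$edit_instances <- 2L
  t2 <- test_windows(q2, fit)
  expect_equal(t2$p_raw, 0.418023, tolerance = 1e-6)
  # zero-edit windows are absent from the output
  q3 <- rbind(q, q2); q3$edit_instances <- c(0L, 2L)
  q3$window_id <- c("a", "b")
  t3 <- test_windows(q3, fit)
  expect_equal(t3$window_id, "b")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.5, 0.5)), c(0.5, 0.5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("simulation draws zero-truncated counts deterministically", {
  train <- mk_stats("exon", depth = 60, fraction = c(0.005, 0.015))
  fit <- fit_background(train)
  # one window with lambda = 2, simulated 10,000 times
  q <- mk_stats("exon", depth = 60, fraction = 0.01, substrate = 200,
                edits = 2L)
  draws <- simulate(fit, nsim = 10000, seed = 4, stats = q)
  expect_true(all(draws >= 1))
  mu <- 2 / (1 - exp(-2))           # 2.3130
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu), 3 * se)
  expect_identical(draws, simulate(fit, nsim = 10000, seed = 4, stats = q))

  # vanishing lambda concentrates all mass at one edit
  tiny <- mk_stats("exon", depth = 60, fraction = 0.01, substrate = 1e-4,
                   edits = 1L)
  expect_true(all(simulate(fit, nsim = 50, seed = 1, stats = tiny) == 1L))
})

test_that("fit accessors expose rates and calibrated residuals", {
  cfg <- simulation_config(n_genes = 8, n_foci = 0, background_rate = 0.008,
                           seed = 31)
  ds <- generate_dataset(cfg)
  st <- aggregate_windows(make_windows(ds$models), ds$sites, ds$coverage,
                          cfg$conversion, ds$reference)
  fit <- fit_background(st)
  expect_s3_class(fit, "ztp_bg")
  expect_output(print(fit), "zero-truncated Poisson")
  expect_true(all(coef(fit) > 0))
  r <- residuals(fit)
  expect_equal(length(r), sum(st$edit_instances >= 1))
  # under a pure background the standardized residuals show no gross bias
  expect_lt(abs(mean(r)), 1)
  lam <- predict(fit, st)
  expect_equal(length(lam), nrow(st))
  expect_true(all(lam > 0))
})

test_that("few windows survive BH under a pure background", {
  frac_called <- vapply(1:5, function(s) {
    cfg <- simulation_config(n_genes = 8, n_foci = 0,
                             background_rate = 0.008, seed = 1000 + s)
    ds <- generate_dataset(cfg)
    st <- aggregate_windows(make_windows(ds$models), ds$sites, ds$coverage,
                            cfg$conversion, ds$reference)
    tests <- test_windows(st, fit_background(st))
    mean(tests$p_adj < 0.1)
  }, numeric(1))
  n_typical <- 200
  expect_true(all(frac_called <= 0.1 + 3 * sqrt(0.1 * 0.9 / n_typical)))
})
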