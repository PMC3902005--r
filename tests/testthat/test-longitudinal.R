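make_metrics <- function(values, cultures, batches, days,
                         window = 150) {
  data.frame(culture_id = cultures, batch_id = batches,
             day_in_vitro = days, window_ms = window,
             n_edges = 10L, mean_connection_length_um = values,
             n_incoming_supernodes = 1L, n_outgoing_supernodes = 1L,
             stringsAsFactors = FALSE)
}

test_that("batch averages report mean, standard error and gaps", {
  met <- make_metrics(c(100, 300, 500), c("c1", "c2", "c1"), "b1",
                      c(10, 10, 12))
  summ <- batch_average(met, metric_names = "mean_connection_length_um")
  d10 <- summ[summ$day_in_vitro == 10, ]
  expect_equal(d10$mean, 200)
  expect_equal(d10$se, 100) # sd/sqrt(2) = 141.42/1.414
  expect_equal(d10$n, 2L)
  # single culture on day 12: SE 0 by default, missing when requested
  d12 <- summ[summ$day_in_vitro == 12, ]
  expect_equal(d12$mean, 500)
  expect_equal(d12$se, 0)
  summ2 <- batch_average(met, metric_names = "mean_connection_length_um",
                         single_culture_se = "missing")
  expect_true(is.na(summ2$se[summ2$day_in_vitro == 12]))
  # day 11 is a gap: flagged, no fabricated value
  d11 <- summ[summ$day_in_vitro == 11, ]
  expect_false(d11$recorded)
  expect_true(is.na(d11$mean))
})

test_that("batch averages are invariant to culture ordering", {
  met <- make_metrics(c(120, 180, 240, 90), paste0("c", 1:4),
                      c("b1", "b1", "b2", "b2"), 20)
  s1 <- batch_average(met, metric_names = "mean_connection_length_um")
  s2 <- batch_average(met[4:1, ], metric_names = "mean_connection_length_um")
  s2 <- s2[match(s1$batch_id, s2$batch_id), ]
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$se, s2$se)
})

test_that("one-way ANOVA matches the sum-of-squares oracle", {
  v <- c(1, 2, 3, 101, 102, 103)
  g <- rep(c("a", "b"), each = 3)
  an <- anova_one_way(v, g)
  expect_equal(an$f_statistic, 15000) # between MS 15000, within MS 1
  expect_equal(an$f_statistic, oracle_anova_f(v, g), tolerance = 1e-12)

  set.seed(15)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(3:8, k, replace = TRUE)
    vv <- rnorm(sum(n), mean = rep(rnorm(k, sd = 2), n))
    gg <- rep(seq_len(k), n)
    an2 <- anova_one_way(vv, gg)
    expect_equal(an2$f_statistic, oracle_anova_f(vv, gg),
                 tolerance = 1e-10)
  }
})

test_that("degenerate and undersized ANOVA inputs are handled", {
  an <- anova_one_way(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(an$f_statistic, 0)
  expect_equal(an$p_value, 1)
  expect_error(anova_one_way(1:6, rep("a", 6)), "at least 2 groups")
  expect_error(anova_one_way(1:3, c("a", "a", "b")),
               "at least 2 observations")
})

test_that("null ANOVA p-values are uniform", {
  set.seed(7)
  pv <- replicate(1000, {
    anova_one_way(rnorm(15), rep(1:3, each = 5))$p_value
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("within/across designs separate designed batch structure", {
  # strong batch offsets, no within-batch noise beyond i.i.d. measurement
  set.seed(23)
  hits <- replicate(40, {
    batch_mean <- rnorm(3, 500, 80)
    met <- do.call(rbind, lapply(1:3, function(b) {
      do.call(rbind, lapply(1:3, function(c) {
        make_metrics(rnorm(8, batch_mean[b], 25),
                     sprintf("b%dc%d", b, c), paste0("b", b), 1:8)
      }))
    }))
    bv <- batch_variability_tests(met)
    c(bv$across$p_value < 0.05,
      all(sapply(bv$within, function(a) a$p_value >= 0.05)))
  })
  expect_gt(mean(hits[1, ]), 0.5) # across-batch detected
  expect_gt(mean(hits[2, ]), 0.5) # within-batch quiet

  # no batch structure: across-batch p roughly uniform
  set.seed(24)
  p0 <- replicate(200, {
    met <- make_metrics(rnorm(12, 500, 50), paste0("c", 1:12),
                        rep(c("b1", "b2", "b3"), each = 4), 10)
    batch_variability_tests(met)$across$p_value
  })
  expect_gt(stats::ks.test(p0, "punif")$p.value, 0.01)

  # a single batch cannot support the across test
  met1 <- make_metrics(rnorm(4), paste0("c", 1:4), "b1", 10)
  expect_error(batch_variability_tests(met1), "at least 2 groups")
})

test_that("window comparison flags only genuinely shifted windows", {
  set.seed(31)
  base <- rnorm(10, 500, 10)
  met <- rbind(
    make_metrics(base + rnorm(10, 0, 5), "c1", "b1", 1:10, window = 50),
    make_metrics(base + rnorm(10, 0, 5), "c1", "b1", 1:10, window = 100),
    make_metrics(base + rnorm(10, 0, 5), "c1", "b1", 1:10, window = 150))
  res <- window_comparison(met)
  expect_false(any(res$b1$comparisons$different))

  met_shift <- met
  sel <- met_shift$window_ms == 150
  met_shift$mean_connection_length_um[sel] <-
    met_shift$mean_connection_length_um[sel] + 200
  res2 <- window_comparison(met_shift)
  comp <- res2$b1$comparisons
  has150 <- comp$window_a == "150" | comp$window_b == "150"
  expect_true(all(comp$different[has150]))
  expect_false(any(comp$different[!has150]))
  # each unordered pair appears exactly once (flags are symmetric)
  pairs <- apply(comp[, c("window_a", "window_b")], 1,
                 function(x) paste(sort(x), collapse = "-"))
  expect_equal(anyDuplicated(pairs), 0L)
})

test_that("identical groups produce intervals containing zero", {
  met <- rbind(
    make_metrics(rep(500, 6), "c1", "b1", 1:6, window = 50),
    make_metrics(rep(500, 6), "c1", "b1", 1:6, window = 100),
    make_metrics(rep(500, 6), "c1", "b1", 1:6, window = 150))
  met$mean_connection_length_um <- met$mean_connection_length_um +
    rep(c(-1, 1), 9) # tiny symmetric jitter to keep variances positive
  res <- window_comparison(met)
  comp <- res$b1$comparisons
  expect_true(all(comp$lwr <= 0 & comp$upr >= 0))
  expect_false(any(comp$different))
})
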