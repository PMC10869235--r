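test_that("animal means collapse objects to per-animal dots", {
  tbl <- tibble::tibble(group = "g", animal = c("a", "a", "a", "b"),
                        volume_um3 = c(1, 2, 3, 7))
  am <- animal_means(tbl, "volume_um3")
  expect_equal(am$mean[am$animal == "a"], 2)
  expect_equal(am$mean[am$animal == "b"], 7) # single object: mean is the value
  expect_error(animal_means(dplyr::select(tbl, -animal)),
               class = "mitomorph_validation_error")

  coh_truth <- sample_cohort_truth(cohort_spec(n_animals = 3, n_objects = 4, seed = 3))
  am2 <- animal_means(coh_truth, "volume_true_um3")
  expect_identical(nrow(am2), 6L) # 3 + 3 animals = 6 dots per metric
})

test_that("identical samples compare as no difference", {
  cg <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cg$p_value, 1, tolerance = 1e-6)
  expect_identical(cg$stars, "ns")
  expect_identical(cg$direction, "none")
})

test_that("well-separated samples reach four stars", {
  set.seed(1)
  a <- c(0, 0, 0, 0) + rnorm(4, 0, 1e-3)
  b <- c(10, 10, 10, 10) + rnorm(4, 0, 1e-3)
  cg <- compare_groups(a, b)
  expect_lt(cg$p_value, 1e-4)
  expect_identical(cg$stars, "****")
  expect_identical(cg$direction, "increase")
})

test_that("comparison is symmetric up to the sign of direction", {
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30, 0.8)
  f <- compare_groups(a, b); r <- compare_groups(b, a)
  expect_equal(f$p_value, r$p_value)
  expect_equal(f$p_mann_whitney, r$p_mann_whitney)
  expect_identical(c(f$direction, r$direction), c("increase", "decrease"))
})

test_that("degenerate constant samples are handled, not crashed", {
  same <- compare_groups(rep(2, 4), rep(2, 5))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  diffc <- compare_groups(rep(0, 4), rep(1, 4))
  expect_identical(diffc$p_value, 0)
  expect_identical(diffc$direction, "increase")
})

test_that("auto method switches to rank-sum when normality fails", {
  set.seed(3)
  skewed <- rlnorm(200, 0, 1.5)
  normal <- rnorm(200, mean = 5)
  cg <- compare_groups(skewed, skewed * 1.5)
  expect_identical(cg$test, "mann_whitney")
  cg2 <- compare_groups(normal, normal + rnorm(200, 0.1))
  expect_identical(cg2$test, "welch_t")
  # both p-values always recorded
  expect_true(is.finite(cg$p_t) && is.finite(cg$p_mann_whitney))
  # forced methods respected
  expect_identical(compare_groups(skewed, skewed * 2, method = "t")$test, "welch_t")
  expect_identical(compare_groups(normal, normal, method = "mann_whitney")$test,
                   "mann_whitney")
  expect_identical(compare_groups(normal, normal + 1, method = "t", pooled = TRUE)$test,
                   "student_t")
})

test_that("star assignment is a pure strict-threshold function of p", {
  expect_identical(significance_stars(c(0.2, 0.05, 0.049999, 0.01, 0.009, 1e-3,
                                        9e-4, 1e-4, 9e-5)),
                   c("ns", "ns", "*", "*", "**", "**", "***", "***", "****"))
})

test_that("tidy and glance return one-row summaries", {
  cg <- compare_groups(1:5, 3:9, labels = c("adult", "aged"), metric = "volume_um3")
  td <- tidy(cg)
  expect_identical(nrow(td), 1L)
  expect_identical(td$metric, "volume_um3")
  expect_identical(td$n_a, 5L)
  gl <- glance(cg)
  expect_named(gl, c("test", "statistic", "p_value", "stars", "direction"))
})

test_that("heterogeneity reports hand-computable CVs and dispersion effects", {
  tbl <- tibble::tibble(group = "g", animal = "a", m = c(1, 3))
  h <- heterogeneity(tbl, "m")
  expect_equal(h$within$cv, sqrt(2) / 2, tolerance = 1e-9)

  flat <- tibble::tibble(group = "g", animal = "a", m = rep(4, 5))
  expect_equal(heterogeneity(flat, "m")$within$cv, 0)

  single <- tibble::tibble(group = "g", animal = "a", m = 2)
  expect_true(heterogeneity(single, "m")$within$flagged)

  # doubled dispersion raises within-animal CV
  set.seed(4)
  lo <- tibble::tibble(group = "lo", animal = rep(c("a1", "a2"), each = 50),
                       m = rlnorm(100, 0, 0.4))
  hi <- tibble::tibble(group = "hi", animal = rep(c("b1", "b2"), each = 50),
                       m = rlnorm(100, 0, 0.8))
  h2 <- heterogeneity(dplyr::bind_rows(lo, hi), "m")
  expect_gt(median(h2$within$cv[h2$within$group == "hi"]),
            median(h2$within$cv[h2$within$group == "lo"]))
})
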