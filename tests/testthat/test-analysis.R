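test_that("NRLE distinguishes linear, sublinear and supralinear curves", {
  expect_equal(nrle((1:10) * 0.37), 1)
  expect_equal(nrle(sqrt(1:50)), 1 / sqrt(2))
  piece <- ifelse(1:10 < 5, (1:10) * 2, 3 * (1:10) * 2)
  expect_equal(nrle(piece), 3)
  expect_error(nrle(5), class = "ab_domain_error")
  expect_error(nrle(c(0, 1, 2)), class = "ab_domain_error")
  # concave curves are sublinear, convex-above-linear curves supralinear
  for (i in 1:20) {
    n <- 1:30
    p <- runif(1, 0.2, 0.95)
    expect_lte(nrle(n^p), 1 + 1e-12)
    q <- runif(1, 1.05, 2)
    expect_gte(nrle(n^q), 1 - 1e-12)
  }
})

test_that("OSI follows the preferred/orthogonal rate contrast", {
  expect_equal(osi(1.55, 0.21), 0.761, tolerance = 5e-4)
  expect_equal(osi(2, 2), 0)
  expect_equal(osi(0, 0), 0)
  expect_equal(osi(3, 0), 1)
})

test_that("the Euler-formula expectation matches the brute-force circular mean", {
  expect_equal(expected_preference_euler(c(0, 40))$preferred, 20)
  expect_equal(expected_preference_euler(c(0, 40), c(0.6, 0.4))$preferred,
               15.24, tolerance = 5e-3)
  expect_equal(expected_preference_euler(rep(77, 5))$preferred, 77)
  expect_false(expected_preference_euler(c(0, 90))$defined)
  expect_error(expected_preference_euler(numeric()), class = "ab_domain_error")
  expect_error(expected_preference_euler(c(0, 40), c(0, 0)),
               class = "ab_domain_error")

  # oracle: resultant of doubled angles accumulated term by term
  set.seed(99)
  for (i in 1:1000) {
    k <- sample(2:12, 1)
    th <- runif(k, 0, 180)
    w <- runif(k, 0, 2)
    sx <- sum(w * cos(2 * th * pi / 180))
    sy <- sum(w * sin(2 * th * pi / 180))
    oracle <- (atan2(sy, sx) * 90 / pi) %% 180
    got <- expected_preference_euler(th, w)
    if (got$defined) {
      expect_equal(got$preferred, oracle, tolerance = 1e-9)
    }
  }

  # equivariance under global rotation
  th <- c(10, 50, 120)
  base <- expected_preference_euler(th)$preferred
  rot <- expected_preference_euler((th + 35) %% 180)$preferred
  expect_equal((rot - base) %% 180, 35, tolerance = 1e-9)
})

test_that("spike classification partitions the four survival patterns", {
  expect_equal(as.character(classify_spike(FALSE, TRUE)), "apically_driven")
  expect_equal(as.character(classify_spike(TRUE, FALSE)), "basally_driven")
  expect_equal(as.character(classify_spike(FALSE, FALSE)), "cooperative")
  expect_equal(as.character(classify_spike(TRUE, TRUE)), "independent")
  grid <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE))
  labs <- classify_spike(grid$a, grid$b)
  expect_equal(sort(as.character(labs)),
               sort(c("independent", "apically_driven", "basally_driven",
                      "cooperative")))
})

test_that("dendritic spike detection gates on slope and amplitude", {
  t <- seq(0, 50, by = 0.1)
  epsp <- function(a) a * (exp(-t / 8) - exp(-t / 0.5)) / 0.83
  small <- detect_dendritic_spike(-70 + epsp(8), t, baseline = -70)
  expect_false(small$detected)
  spike <- -70 + epsp(10) + 40 * exp(-(t - 20)^2 / 2) * (t > 15)
  big <- detect_dendritic_spike(spike, t, baseline = -70)
  expect_true(big$detected)
  expect_gt(big$max_slope, 10)
  # monotone: adding a positive transient never un-detects
  bigger <- detect_dendritic_spike(spike + 20 * exp(-(t - 30)^2 / 4), t,
                                   baseline = -70)
  expect_true(bigger$detected)
})

test_that("tuning curve fits recover wrapped-Gaussian parameters", {
  th <- seq(0, 170, by = 10)
  truth <- 0.2 + 1.4 * exp(-circ_orientation_diff(th, 60)^2 / (2 * 25^2))
  fit <- fit_tuning_curve(tibble::tibble(orientation = th, mean_rate = truth))
  expect_equal(fit$preferred, 60, tolerance = 1)
  expect_equal(fit$width, 25, tolerance = 2)
  expect_equal(fit$osi, osi(1.6, 0.2 + 1.4 * exp(-90^2 / (2 * 25^2))),
               tolerance = 0.02)
  # scale invariance of preferred/width/OSI
  fit2 <- fit_tuning_curve(tibble::tibble(orientation = th,
                                          mean_rate = 2 * truth))
  expect_equal(fit2$preferred, fit$preferred, tolerance = 0.5)
  expect_equal(fit2$width, fit$width, tolerance = 0.5)
  expect_equal(fit2$osi, fit$osi, tolerance = 1e-3)
  # flat positive curve: OSI 0; all-zero curve: undefined
  flat <- fit_tuning_curve(tibble::tibble(orientation = th,
                                          mean_rate = rep(2, length(th))))
  expect_equal(flat$osi, 0, tolerance = 1e-6)
  zero <- fit_tuning_curve(tibble::tibble(orientation = th,
                                          mean_rate = rep(0, length(th))))
  expect_false(zero$defined)
  # broom-style accessors
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$preferred, fit$preferred)
})

test_that("matched comparisons test apical vs basal responses", {
  prof <- tibble::tibble(
    segment_id = 1:40,
    tree_label = rep(c("apical", "basal"), each = 20),
    att = c(rnorm(20, 0, 1), rnorm(20, 5, 1)),
    len = runif(40, 50, 150))
  same <- prof
  same$att <- rep(1:20, 2)
  r0 <- matched_compare(same, "att")
  expect_equal(r0$p_value, 1)
  expect_equal(r0$difference, 0)
  r1 <- matched_compare(prof, "att")
  expect_lt(r1$p_value, 1e-3)
  r2 <- matched_compare(prof, "att", covariate = "len", normalize = TRUE)
  expect_true(is.finite(r2$p_value))
  r3 <- matched_compare(prof, "att", exclude = 7L)
  expect_equal(r3$n_apical, 19)
  expect_equal(r3$excluded, "7")
  expect_error(matched_compare(prof[c(1, 21, 22), ], "att"),
               class = "ab_stats_error")
})
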