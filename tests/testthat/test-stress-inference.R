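make_fit_table <- function(days, concs, reps, xi_fun, mu_fun, noise_sd = 0,
                           seed = 1) {
  set.seed(seed)
  g <- expand.grid(replicate = seq_len(reps), day = days,
                   concentration_mM = concs)
  g$xi <- xi_fun(g$day, g$concentration_mM) + rnorm(nrow(g), sd = noise_sd)
  g$mu <- mu_fun(g$day, g$concentration_mM) + rnorm(nrow(g), sd = noise_sd)
  g$sigma <- 0.03
  g$median <- g$mu
  g$mad <- 0.01
  g
}

test_that("star codes map p-value thresholds deterministically", {
  expect_equal(p_stars(c(0.2, 0.049, 0.009, 0.0009, 0.05)),
               c("ns", "*", "**", "***", "ns"))
})

test_that("day-trend ANOVA: null case, t^2 = F identity, and a strong trend", {
  flat <- make_fit_table(c(0, 2, 4), 0, 5, function(d, c) 0.2,
                         function(d, c) 0.03, noise_sd = 0.05, seed = 2)
  a <- gev_trend_anova(flat, "xi", 0)
  expect_gt(a$p_value, 0.05)
  expect_equal(a$stars, "ns")

  # two groups: F equals the square of the pooled-variance t statistic
  two <- make_fit_table(c(0, 4), 0, 6, function(d, c) 0.2 + 0.02 * d,
                        function(d, c) 0.03, noise_sd = 0.03, seed = 3)
  a2 <- gev_trend_anova(two, "xi", 0)
  tt <- t.test(xi ~ day, data = two, var.equal = TRUE)
  expect_equal(a2$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p_value, tt$p.value, tolerance = 1e-10)

  # six days, five replicates, trend much larger than noise
  strong <- make_fit_table(seq(0, 10, 2), 0, 5,
                           function(d, c) 0.15 + 0.03 * d,
                           function(d, c) 0.03, noise_sd = 0.01, seed = 4)
  expect_equal(gev_trend_anova(strong, "xi", 0)$stars, "***")

  # ANOVA p is invariant to affine rescaling of the parameter
  scaled <- strong
  scaled$xi <- 100 * scaled$xi - 7
  expect_equal(gev_trend_anova(scaled, "xi", 0)$p_value,
               gev_trend_anova(strong, "xi", 0)$p_value, tolerance = 1e-12)

  expect_error(gev_trend_anova(flat[flat$day == 0, ], "xi", 0), "2 days")
})

test_that("Spearman correlation: perfect monotone, exact enumeration, and null", {
  dec <- make_fit_table(10, c(0, 100, 200, 300, 400), 1,
                        function(d, c) 0.2, function(d, c) 0.05 - 1e-4 * c)
  s <- spearman_param_vs_concentration(dec, "mu", 10)
  expect_equal(s$rho, -1)

  # n = 5 replicate-level pairs: exact p from full 5! enumeration
  tab <- make_fit_table(4, c(0, 100, 200, 300, 400), 1, function(d, c) 0.2,
                        function(d, c) 0.03, noise_sd = 0.01, seed = 6)
  s <- spearman_param_vs_concentration(tab, "mu", 4)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  rhos <- vapply(perms(1:5), function(p) {
    cor(tab$concentration_mM, tab$mu[p], method = "spearman")
  }, numeric(1))
  p_exact <- mean(abs(rhos) >= abs(s$rho) - 1e-12)
  expect_equal(s$p_value, p_exact)

  # independent values rarely show |rho| > 0.3 at n = 100
  set.seed(8)
  hits <- 0L
  for (i in 1:200) {
    tb <- data.frame(concentration_mM = rep(1:20, 5), day = 1,
                     replicate = rep(1:5, each = 20), mu = rnorm(100))
    if (abs(spearman_param_vs_concentration(tb, "mu", 1)$rho) > 0.3) {
      hits <- hits + 1L
    }
  }
  expect_lt(hits / 200, 0.05)

  expect_error(spearman_param_vs_concentration(dec[dec$concentration_mM < 150, ],
                                               "mu", 10), "3 distinct")
  con <- make_fit_table(1, c(0, 100, 200), 2, function(d, c) 0.2,
                        function(d, c) 0.03)
  expect_error(spearman_param_vs_concentration(con, "mu", 1), "constant")
})

test_that("location-vs-concentration regression recovers exact lines and CIs", {
  exact <- make_fit_table(10, c(0, 100, 200, 300, 400), 3,
                          function(d, c) 0.2, function(d, c) 0.04 - 1e-5 * c)
  # lm warns about the residual-free fit; the zero-width CI is the point here
  r <- suppressWarnings(regress_location_vs_concentration(exact, 10))
  expect_equal(r$slope, -1e-5, tolerance = 1e-12)
  expect_equal(r$intercept, 0.04, tolerance = 1e-12)
  expect_equal(diff(r$slope_ci), 0, tolerance = 1e-12)
  expect_true(all(r$band$fit >= r$band$lwr & r$band$fit <= r$band$upr))

  # balanced replicate-level and replicate-averaged slopes agree
  noisy <- make_fit_table(10, c(0, 100, 200, 300, 400), 5,
                          function(d, c) 0.2, function(d, c) 0.04 - 1e-5 * c,
                          noise_sd = 0.003, seed = 11)
  r_full <- regress_location_vs_concentration(noisy, 10)
  avg2 <- aggregate(mu ~ concentration_mM, noisy, mean)
  avg2$day <- 10; avg2$replicate <- 1
  r_avg <- regress_location_vs_concentration(avg2, 10)
  expect_equal(r_full$slope, r_avg$slope, tolerance = 1e-12)
})

test_that("salt-stress flagging compares groups against the untreated reference", {
  set.seed(14)
  base <- rgamma(4000, 4, scale = 0.01)
  same <- list("0" = base, "100" = base, "400" = base)
  f <- classify_salt_stress(same)
  expect_false(any(f$stressed))

  shifted <- list("0" = rgamma(4000, 4, scale = 0.012),
                  "200" = rgamma(4000, 4, scale = 0.0115),
                  "400" = rgamma(4000, 4, scale = 0.007))
  f <- classify_salt_stress(shifted)
  expect_true(f$stressed[f$concentration == "400"])
  expect_false(f$stressed[f$concentration == "0"])
  expect_error(classify_salt_stress(shifted, reference = "50"), "reference")
})
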