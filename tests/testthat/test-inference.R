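test_that("correlation classification uses strict thresholds and partitions rows", {
  expect_equal(as.character(classify_r(c(-0.30, 0.25, 0.90, NA))),
               c("complementarity", "neutral", "synchrony", "missing"))
  expect_equal(as.character(classify_r(-0.25)), "neutral")
  set.seed(2)
  r <- c(stats::runif(500, -1, 1), NA, NA)
  cls <- classify_r(r)
  expect_equal(sum(table(cls)[c("complementarity", "neutral", "synchrony")]),
               sum(!is.na(r)))
})

test_that("negative-parameter tail rates handle edge cases", {
  tab <- data.frame(s1 = 0, o1 = 0, o2 = 0, s2 = 0, r = c(-0.5, -0.6, 0.1))
  expect_equal(negative_rate(tab, "complementarity"), 0)
  expect_error(negative_rate(tab, "synchrony"), "no rows")
})

test_that("goodness-of-fit chi-square matches the direct formula oracle", {
  res <- chisq_goodness_of_fit(c(90, 10), c(0.5, 0.5))
  expect_equal(res$statistic, 64)
  expect_equal(res$dof, 1L)
  expect_equal(chisq_goodness_of_fit(c(65, 16), c(65, 16) / 81)$statistic, 0)
  # oracle: sum (obs - exp)^2 / exp
  obs <- c(130, 37); p <- c(65, 16) / 81
  exp_counts <- sum(obs) * p
  oracle <- sum((obs - exp_counts)^2 / exp_counts)
  expect_equal(chisq_goodness_of_fit(obs, p)$statistic, oracle,
               tolerance = 1e-12)
  # invariant under category swap; scales linearly with count inflation
  expect_equal(chisq_goodness_of_fit(rev(obs), rev(p))$statistic, oracle)
  expect_equal(chisq_goodness_of_fit(3 * obs, p)$statistic, 3 * oracle,
               tolerance = 1e-12)
  expect_error(chisq_goodness_of_fit(c(1, 1), c(1, 0)), "invalid expectation")
})

test_that("two-proportion chi-square matches the 2x2 contingency oracle", {
  expect_equal(chisq_two_proportions(c(30, 10), c(60, 20))$statistic, 0)
  a <- 90; b <- 10; c <- 50; d <- 50
  oracle <- (a + b + c + d) * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  res <- chisq_two_proportions(c(90, 10), c(50, 50))
  expect_equal(res$statistic, oracle, tolerance = 1e-12)
  expect_equal(res$dof, 1L)
  expect_error(chisq_two_proportions(c(90, 10), c(0, 0)), "degenerate")
})

test_that("the five designs carry the printed and fitted parameter counts", {
  sw <- suppressMessages(run_sweep(sim_config(n_turns = 60, seed = 17),
                                   reps = 2))
  expect_equal(nrow(sw), 162L)
  d_main <- build_design(sw, "main_effects")
  X <- stats::model.matrix(d_main$formula, d_main$data)
  expect_equal(ncol(X), 9L)  # intercept + 8 dummies
  expect_equal(d_main$k_printed, 8L)
  expect_equal(build_design(sw, "interactions")$k_printed, 48L)
  expect_equal(build_design(sw, "overall")$k_printed, 56L)
  expect_equal(build_design(sw, "initiator")$k_printed, 28L)
  expect_equal(build_design(sw, "self_influence")$k_printed, 28L)
  expect_error(build_design(sw, "everything"), "arg")
  fits <- table1_replica(sw)
  # distinct fitted degrees of freedom: mains 8, interaction spans 32, focal 28
  expect_equal(fits$k_unique,  c(8L, 32L, 32L, 28L, 28L))
  # no within-parameter products: every interaction column crosses two bases
  d_int <- build_design(sw, "interactions")
  Xi <- stats::model.matrix(d_int$formula, d_int$data)
  crossed <- grep(":", colnames(Xi), value = TRUE)
  bases <- lapply(strsplit(crossed, ":"), function(p) substr(p, 1, 2))
  expect_true(all(vapply(bases, function(b) b[1] != b[2], logical(1))))
})

test_that("missing correlations are excluded listwise from the designs", {
  sw <- suppressMessages(run_sweep(sim_config(n_turns = 60, seed = 18),
                                   reps = 2))
  sw$r[c(3, 50)] <- NA
  d <- build_design(sw, "main_effects")
  expect_equal(d$n, 160L)
  expect_equal(d$n_excluded, 2L)
})

test_that("OLS fits hit the exact and analytic R-squared anchors", {
  sw <- suppressMessages(run_sweep(sim_config(n_turns = 60, seed = 19),
                                   reps = 2))
  d <- build_design(sw, "main_effects")
  X <- stats::model.matrix(d$formula, d$data)
  beta <- seq_len(ncol(X)) / 10
  f_exact <- fit_ols(d, y = as.vector(X %*% beta))
  expect_equal(f_exact$r_squared, 1, tolerance = 1e-12)
  # response orthogonal to the centered design: R^2 = 0
  set.seed(1)
  y0 <- stats::rnorm(nrow(X))
  y_orth <- stats::residuals(stats::lm(y0 ~ X)) + 5
  f_null <- fit_ols(d, y = y_orth)
  expect_equal(f_null$r_squared, 0, tolerance = 1e-10)
  expect_error(fit_ols(d, y = rep(1, nrow(X))), "degenerate")
})

test_that("R-squared approaches the analytic population value", {
  # population = the balanced design itself, replicated; y = X beta + noise
  ctx <- enumerate_contexts()
  big <- ctx[rep(seq_len(81), each = 62), ]
  big$r <- 0
  d <- build_design(big, "main_effects")
  X <- stats::model.matrix(d$formula, d$data)
  set.seed(123)
  beta <- c(0, stats::rnorm(8, sd = 0.3))
  mu <- as.vector(X %*% beta)
  sigma <- 0.4
  pop_r2 <- stats::var(mu) / (stats::var(mu) + sigma^2)
  f <- fit_ols(d, y = mu + stats::rnorm(length(mu), sd = sigma))
  expect_equal(f$r_squared, pop_r2, tolerance = 0.02)
})

test_that("parameter-count conventions shift the information criteria as documented", {
  sw <- suppressMessages(run_sweep(sim_config(n_turns = 60, seed = 20),
                                   reps = 2))
  d <- build_design(sw, "interactions")
  fu <- fit_ols(d, convention = "unique")
  fp <- fit_ols(d, convention = "printed")
  expect_equal(fp$aic - fu$aic, 2 * (48 - fu$k_unique))
  expect_equal(fp$bic - fu$bic, log(fu$n) * (48 - fu$k_unique))
  expect_equal(fu$loglik, fp$loglik)
  # under the rank convention AIC/BIC agree with R's own lm accounting
  expect_equal(fu$aic, stats::AIC(fu$fit), tolerance = 1e-8)
  expect_equal(fu$bic, stats::BIC(fu$fit), tolerance = 1e-8)
})

test_that("the interaction span contains the main effects (overall identity)", {
  sw <- suppressMessages(run_sweep(sim_config(n_turns = 100, seed = 23),
                                   reps = 3))
  fits <- table1_replica(sw)
  r2 <- fits$r2[match(c("interactions", "overall"), fits$model)]
  expect_lt(abs(r2[1] - r2[2]), 1e-10)
  aic <- fits$aic[match(c("interactions", "overall"), fits$model)]
  expect_lt(abs(aic[1] - aic[2]), 1e-6)
})

test_that("analyze_sweep assembles counts, tests and the model table", {
  sw <- suppressMessages(run_sweep(sim_config(n_turns = 100, seed = 29),
                                   reps = 3))
  an <- analyze_sweep(sw)
  expect_s3_class(an, "sweep_analysis")
  expect_equal(sum(an$class_counts), nrow(sw))
  expect_named(an$chisq, c("fifty_fifty", "structural", "two_proportions"))
  expect_equal(nrow(an$models), 5L)
  expect_equal(an$tails$complementarity$n,
               sum(!is.na(sw$r) & sw$r < -0.25))
})
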