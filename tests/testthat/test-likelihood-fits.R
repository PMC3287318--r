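test_that("constant-rate log-likelihood matches the closed form", {
  toy <- toy_tree()
  expect_equal(yule_time_loglik(rate_constant(0.2), toy),
               log(0.2) - 0.2 * 5 + log(2), tolerance = 1e-12)
  # (n-2) log lambda - lambda X + log((n-1)!) on random trees
  for (seed in 1:100) {
    x <- rand_tree(sample(3:40, 1), seed)
    lam <- stats::runif(1, 0.02, 2)
    X <- sum(x$phy$edge.length)
    expect_equal(yule_time_loglik(rate_constant(lam), x),
                 (x$n - 2) * log(lam) - lam * X + lfactorial(x$n - 1),
                 tolerance = 1e-9)
  }
  expect_error(yule_time_loglik(rate_constant(0.2),
                                read_chronogram("(A:1,B:1);")), "3 tips")
})

test_that("zero rate over an event sends the likelihood to -Inf", {
  toy <- toy_tree()
  # event at age 1 sits in the younger epoch
  expect_equal(yule_time_loglik(rate_piecewise(c(0.5, 0), 1.5), toy), -Inf)
  expect_gt(yule_time_loglik(rate_piecewise(c(0, 0.5), 1.5), toy), -Inf)
})

test_that("the constant Yule MLE is the closed form and maximises", {
  toy <- toy_tree()
  f <- fit_yule_constant(toy)
  expect_equal(unname(f$estimates["lambda"]), 0.2)
  expect_equal(f$logL, log(0.2) - 1 + log(2), tolerance = 1e-12)
  expect_equal(f$AIC, -2 * f$logL + 2)
  expect_gt(f$logL, yule_time_loglik(rate_constant(0.1), toy))
  expect_gt(f$logL, yule_time_loglik(rate_constant(0.3), toy))
  # agrees with ape's independent implementation
  for (seed in 1:5) {
    x <- rand_tree(25, seed)
    f <- fit_yule_constant(x)
    a <- ape::yule(x$phy)
    expect_equal(unname(f$estimates["lambda"]), a$lambda, tolerance = 1e-9)
    expect_equal(f$logL, a$loglik, tolerance = 1e-9)
  }
})

test_that("birth-death fit matches ape and collapses to Yule at mu = 0", {
  for (seed in 1:3) {
    x <- rand_tree(30, seed + 10)
    f <- fit_birth_death_constant(x)
    a <- suppressWarnings(ape::birthdeath(x$phy))
    expect_equal(f$logL, -a$dev / 2, tolerance = 1e-4)
    expect_gte(unname(f$estimates["mu"]), 0)
    # grid oracle: no grid point beats the optimum
    lam <- unname(f$estimates["lambda"]); mu <- unname(f$estimates["mu"])
    bt <- branching_times(x)
    bd_ll <- function(l, m) {
      r <- l - m; aa <- m / l
      lfactorial(x$n - 1) + (x$n - 2) * log(r) + r * sum(bt[-1]) +
        x$n * log(1 - aa) - 2 * sum(log(exp(r * bt) - aa))
    }
    grid <- expand.grid(l = seq(lam * 0.5, lam * 1.5, length.out = 25),
                        m = seq(0, lam * 0.9, length.out = 25))
    gl <- suppressWarnings(mapply(bd_ll, grid$l, grid$m))
    expect_gte(f$logL + 1e-6, max(gl[is.finite(gl)]))
  }
  # pure-birth boundary equals the constant Yule likelihood
  x <- rand_tree(30, 99)
  fy <- fit_yule_constant(x)
  bt <- branching_times(x)
  lam <- unname(fy$estimates["lambda"])
  ll0 <- lfactorial(x$n - 1) + (x$n - 2) * log(lam) + lam * sum(bt[-1]) -
    2 * lam * sum(bt)
  expect_equal(ll0, fy$logL, tolerance = 1e-9)
})

test_that("piecewise fits count events and lineage-time per epoch", {
  toy <- toy_tree()
  f <- fit_yule_piecewise(toy, 2, breakpoints = 1)
  expect_equal(unname(f$estimates[c("lambda_1", "lambda_2")]), c(0, 1 / 3))
  expect_equal(f$k, 3)
  # fit logL must equal the likelihood of its own fitted model
  x <- rand_tree(30, 7)
  f2 <- fit_yule_piecewise(x, 2, grid_resolution = x$root_age / 50)
  expect_equal(f2$logL,
               yule_time_loglik(f2$model, x), tolerance = 1e-9)
  # m = 1 reduces to the constant fit
  f1 <- fit_yule_piecewise(x, 1)
  expect_equal(f1$logL, fit_yule_constant(x)$logL)
  # nesting: more epochs never lose likelihood
  f3 <- fit_yule_piecewise(x, 3, grid_resolution = x$root_age / 50)
  expect_gte(f3$logL + 1e-6, f2$logL)
  expect_gte(f2$logL + 1e-6, f1$logL)
  expect_error(fit_yule_piecewise(x, 40), "events")
})

test_that("covariate fit pools rates by sea-level state", {
  toy <- toy_tree()
  f <- fit_yule_covariate(toy, sea_level_intervals(2, 1))
  expect_equal(unname(f$estimates), c(0, 1 / 3))
  expect_equal(f$k, 2)
  # intervals covering everything collapse to the constant rate
  x <- rand_tree(20, 5)
  fa <- fit_yule_covariate(x, sea_level_intervals(x$root_age + 1, 0))
  expect_equal(unname(fa$estimates["lambda_high"]),
               unname(fit_yule_constant(x)$estimates["lambda"]),
               tolerance = 1e-12)
  expect_warning(f0 <- fit_yule_covariate(
    x, sea_level_intervals(numeric(0), numeric(0))), "constant")
  expect_equal(f0$k, 1)
})

test_that("logistic fit beats a parameter grid around its optimum", {
  x <- rand_tree(40, 11)
  f <- fit_yule_logistic(x)
  a <- unname(f$estimates["a"]); b <- unname(f$estimates["b"])
  grid <- expand.grid(a = a + seq(-0.5, 0.5, length.out = 40) * max(abs(a), 0.05),
                      b = b + seq(-1, 1, length.out = 40) * max(abs(b), 0.5))
  gl <- mapply(function(aa, bb)
    yule_time_loglik(rate_logistic(aa, bb), x), grid$a, grid$b)
  expect_gte(f$logL + 1e-6, max(gl))
})

test_that("no fitted model loses to random parameter draws", {
  x <- rand_tree(30, 13)
  set.seed(4)
  fc <- fit_yule_constant(x)
  expect_true(all(yule_time_loglik_vec(
    lapply(stats::runif(200, 0.01, 3), rate_constant), x) <= fc$logL + 1e-9))
  fl <- fit_yule_logistic(x)
  draws <- lapply(1:200, function(i)
    rate_logistic(stats::runif(1, -1, 1), stats::runif(1, -4, 2)))
  expect_true(all(yule_time_loglik_vec(draws, x) <= fl$logL + 1e-9))
  f2 <- fit_yule_piecewise(x, 2, grid_resolution = x$root_age / 100)
  draws2 <- lapply(1:200, function(i)
    rate_piecewise(stats::runif(2, 0.01, 3),
                   stats::runif(1, 1e-6, x$root_age * 0.999)))
  expect_true(all(yule_time_loglik_vec(draws2, x) <= f2$logL + 1e-9))
})

test_that("AIC and clock LRT arithmetic behave", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(10, 3), -14)
  expect_error(aic(1, -1), "non-negative")
  r <- lrt_clock(-5, -5)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_warning(rw <- lrt_clock(-4, -5), "below")
  expect_equal(rw$statistic, -2)
  expect_equal(rw$p_value, 1)
  r2 <- lrt_clock(-10, -8, df = 2)
  expect_equal(r2$statistic, 4)
  expect_equal(r2$p_value, stats::pchisq(4, 2, lower.tail = FALSE))
})

test_that("model comparison flags the minimum-AIC model", {
  x <- rand_tree(35, 17)
  tab <- model_comparison(x, sea_level_intervals(x$root_age / 2,
                                                 x$root_age / 4),
                          grid_resolution = x$root_age / 40)
  expect_equal(sum(tab$best), 1)
  expect_equal(tab$AIC, -2 * tab$logL + 2 * tab$k)
  expect_true(all(c("yule", "birth_death", "sea_level", "logistic",
                    "breakpoints_1", "breakpoints_2") %in% tab$model))
  best <- tab[tab$best, ]
  expect_equal(best$AIC, min(tab$AIC))
})
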