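test_that("tree simulation is reproducible and respects its stop rules", {
  m <- rate_constant(0.1)
  a <- simulate_yule_tree(m, duration = 25, seed = 5)
  b <- simulate_yule_tree(m, duration = 25, seed = 5)
  expect_identical(ape::write.tree(a$phy), ape::write.tree(b$phy))
  expect_equal(a$root_age, 25, tolerance = 1e-9)

  z <- simulate_yule_tree(rate_constant(0), duration = 10, seed = 1)
  expect_equal(z$n, 2)
  expect_equal(sort(z$phy$edge.length), c(10, 10))
  expect_error(simulate_yule_tree(rate_constant(0), n_tips = 5), "unreachable")

  tn <- simulate_yule_tree(m, n_tips = 37, seed = 6)
  expect_equal(tn$n, 37)
  expect_error(simulate_yule_tree(rate_piecewise(c(0.1, 0.2), 5),
                                  n_tips = 10), "duration")
  expect_error(simulate_yule_tree(m, n_tips = 10, duration = 5), "exactly one")
})

test_that("simulated trees pass the chronogram invariants", {
  models <- list(rate_constant(0.12),
                 rate_piecewise(c(0.2, 0.05), 8),
                 rate_logistic(-0.1, 0.5))
  for (i in seq_along(models)) {
    x <- simulate_yule_tree(models[[i]], duration = 18, seed = 70 + i)
    expect_s3_class(x, "chronogram")          # constructor validates
    expect_length(branching_times(x), x$n - 1)
    expect_equal(lineage_count(x, x$root_age), x$n)
    expect_equal(ltt_integral(x), sum(x$phy$edge.length), tolerance = 1e-9)
  }
})

test_that("mean tip count matches the pure-birth expectation", {
  # E[N(T)] = 2 exp(lambda T)
  ns <- vapply(1:800, function(i)
    simulate_yule_tree(rate_constant(0.1), duration = 10, seed = 1000 + i)$n,
    numeric(1))
  expect_lt(abs(mean(ns) - 2 * exp(1)) / (stats::sd(ns) / sqrt(length(ns))), 3)
})

test_that("conditioned simulation hits the requested size and depth", {
  m <- rate_constant(0.12)
  for (i in 1:10) {
    x <- simulate_conditioned_tree(m, n = 8, root_age = 18, seed = i)
    expect_equal(x$n, 8)
    expect_equal(x$root_age, 18, tolerance = 1e-9)
  }
  cherry <- simulate_conditioned_tree(m, n = 2, root_age = 7, seed = 1,
                                      max_attempts = 500)
  expect_equal(cherry$n, 2)
  expect_error(simulate_conditioned_tree(rate_constant(0.001), n = 40,
                                         root_age = 1, max_attempts = 5,
                                         seed = 1), "attempts")
})

test_that("conditioned draws match size-filtered unconditioned draws", {
  # both samplers target the forward process given (n, root_age), so their
  # branching-age distributions must agree
  m <- rate_constant(0.12)
  cond <- unlist(lapply(1:300, function(i) {
    x <- simulate_conditioned_tree(m, n = 5, root_age = 14, seed = 4000 + i)
    branching_times(x)[-1]
  }))
  set.seed(99)
  unc <- c()
  tries <- 0
  while (length(unc) < 4 * 300 && tries < 30000) {
    tries <- tries + 1
    x <- simulate_yule_tree(m, duration = 14)
    if (x$n == 5) unc <- c(unc, branching_times(x)[-1])
  }
  expect_gt(length(unc), 100)
  ks <- suppressWarnings(stats::ks.test(cond, unc))
  expect_gt(ks$p.value, 0.01)
})

test_that("neutral assembly gives species uniform inclusion probability", {
  x <- rand_tree(20, 81)
  occ <- simulate_communities(x, n_sites = 2000, richness_per_site = 5,
                              mode = "neutral", seed = 12)
  counts <- rowSums(occ$presence)
  expect_equal(sum(counts), 2000 * 5)
  cs <- stats::chisq.test(counts)
  expect_gt(cs$p.value, 0.01)
})

test_that("limiting similarity empties sites when the radius exceeds the root", {
  x <- rand_tree(15, 83)
  expect_warning(
    occ <- simulate_communities(x, n_sites = 3, richness_per_site = 5,
                                mode = "dispersed",
                                strength = x$root_age * 1.1, seed = 2),
    "richness")
  expect_true(all(colSums(occ$presence) <= 1))
})

test_that("recent allopatry splits young sister species across islands", {
  x <- simulate_yule_tree(rate_constant(0.08), n_tips = 40, seed = 91)
  occ <- simulate_communities(x, n_sites = 6, richness_per_site = 15,
                              mode = "recent_allopatry", strength = 5,
                              seed = 13)
  d <- divergence_matrix(x)
  md <- occ$metadata
  for (isl in unique(md$island)) {
    pool <- rownames(occ$presence)[
      rowSums(occ$presence[, md$site[md$island == isl], drop = FALSE]) > 0]
    if (length(pool) >= 2) {
      dd <- d[pool, pool]
      cherries <- which(dd < 5 & upper.tri(dd), arr.ind = TRUE)
      for (k in seq_len(nrow(cherries))) {
        i <- pool[cherries[k, 1]]; j <- pool[cherries[k, 2]]
        # co-occurring sub-threshold pairs are never true sisters
        expect_false(is_cherry_pair(x, i, j))
      }
    }
  }
})

test_that("sea-level fixtures respect their construction rules", {
  expect_equal(sea_level_fixture("toy")$start_age, c(12, 5))
  for (s in 1:5) {
    iv <- sea_level_fixture("cenozoic_like", seed = s)
    expect_s3_class(iv, "sea_level_intervals")
    expect_true(all(iv$start_age <= 30))
    expect_true(all(iv$start_age > iv$end_age))
    iv2 <- sea_level_fixture("cenozoic_like", seed = s)
    expect_identical(iv, iv2)
  }
})
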