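test_that("Sorensen similarity counts shared species", {
  expect_equal(sorensen(c("a", "b"), c("a", "b")), 1)
  expect_equal(sorensen(c("a", "b"), c("c", "d")), 0)
  expect_equal(sorensen(c("a", "b", "c"), c("a", "d", "e", "f", "g")), 0.25)
  expect_error(sorensen(character(0), character(0)), "undefined")
})

test_that("community summaries report richness and within-group similarity", {
  pres <- matrix(0L, 5, 3, dimnames = list(letters[1:5], c("s1", "s2", "s3")))
  pres[c("a", "b"), "s1"] <- 1L
  pres[c("a", "c"), "s2"] <- 1L
  pres[c("d", "e"), "s3"] <- 1L
  md <- data.frame(site = c("s1", "s2", "s3"),
                   island = "isl",
                   habitat = c("inner_reef", "inner_reef", "outer_slope"))
  occ <- occurrence_matrix(pres, md)
  s <- community_summary(occ)
  inner <- s[s$habitat == "inner_reef", ]
  expect_equal(inner$n_sites, 2)
  expect_equal(inner$mean_richness, 2)
  expect_equal(inner$mean_similarity, 0.5)
  # single-site group: similarity is missing, not zero
  outer <- s[s$habitat == "outer_slope", ]
  expect_true(is.na(outer$mean_similarity))
  tot <- s[s$habitat == "total", ]
  expect_equal(tot$n_species, 5)
  expect_equal(tot$mean_similarity, 0)     # cross-habitat pairs share nothing
})

test_that("occurrence matrices validate and round-trip through csv", {
  expect_error(occurrence_matrix(matrix(2, 1, 1,
                                        dimnames = list("a", "s"))), "0 or 1")
  occ <- toy_occ()
  f <- tempfile(fileext = ".csv")
  write_occurrence(occ, f)
  occ2 <- read_occurrence(f)
  expect_equal(occ2$presence, occ$presence)
  unlink(f)
})

test_that("delta means enumerate qualifying pairs within and across sites", {
  toy <- toy_tree()
  occ <- toy_occ()
  d <- divergence_matrix(toy)
  dm <- delta_means(occ, d, Inf)
  expect_equal(dm$delta_S, 1.5)            # pairs (A,B) and (A,C)
  expect_equal(dm$delta_T, 5 / 3)          # all three pooled pairs
  dm2 <- delta_means(occ, d, 1.5)
  expect_equal(dm2$delta_S, 1)             # only (A,B) qualifies
  expect_equal(dm2$delta_T, 1)
  # no qualifying pair: undefined, not NaN
  dm3 <- delta_means(occ, d, 0.5)
  expect_true(is.na(dm3$delta_S) && is.na(dm3$delta_T))
  # one site holding every species: the two means coincide
  all1 <- occurrence_matrix(matrix(1L, 3, 1,
                                   dimnames = list(c("A", "B", "C"), "s1")))
  dm4 <- delta_means(all1, d, Inf)
  expect_equal(dm4$delta_S, dm4$delta_T)
})

test_that("delta means are invariant to ordering and to absent species", {
  x <- rand_tree(12, 31)
  d <- divergence_matrix(x)
  set.seed(31)
  occ <- simulate_communities(x, n_sites = 4, richness_per_site = 5,
                              mode = "neutral", seed = 8)
  base <- delta_means(occ, d, x$root_age / 2)
  # permute species rows and site columns
  p <- occurrence_matrix(
    occ$presence[sample(nrow(occ$presence)), sample(ncol(occ$presence))])
  perm <- delta_means(p, d, x$root_age / 2)
  expect_equal(perm$delta_S, base$delta_S)
  expect_equal(perm$delta_T, base$delta_T)
  # dropping a species absent from every site changes nothing
  absent <- rownames(occ$presence)[rowSums(occ$presence) == 0]
  expect_gt(length(absent), 0)
  sub <- occurrence_matrix(
    occ$presence[!rownames(occ$presence) %in% absent[1], , drop = FALSE])
  red <- delta_means(sub, d, x$root_age / 2)
  expect_equal(red$delta_S, base$delta_S)
  expect_equal(red$delta_T, base$delta_T)
})

test_that("Pi_ST arithmetic and guards", {
  expect_equal(pi_st(1.5, 5 / 3), 0.1)
  expect_equal(pi_st(3, 3), 0)
  expect_true(is.na(pi_st(NA, 2)))
  expect_error(pi_st(1, 0), "positive")
})

test_that("partial randomization converges to the exact permutation null", {
  toy <- toy_tree()
  occ <- toy_occ()
  enum <- enum_pi_null(occ, toy, Inf)
  expect_equal(mean(enum), 0, tolerance = 1e-12)
  expect_equal(mean(enum >= 0.1), 2 / 3)
  r <- partial_randomization_test(occ, toy, Inf, reps = 4000, seed = 17)
  expect_equal(r$pi_st, 0.1, tolerance = 1e-12)
  mcse <- stats::sd(enum) / sqrt(r$reps_valid)
  expect_lt(abs(r$null_mean - mean(enum)), 3 * mcse)
  expect_equal(r$null_sd, stats::sd(enum), tolerance = 0.1)
  expect_equal(mean(r$null >= 0.1), 2 / 3, tolerance = 0.05)
  # p_upper counts ties as extreme, add-one convention
  expect_equal(r$p_upper, (sum(r$null >= 0.1) + 1) / (r$reps_valid + 1))
})

test_that("degenerate nulls are flagged untestable", {
  toy <- toy_tree()
  occ <- toy_occ()
  # threshold below every divergence: all-singleton blocks
  r <- partial_randomization_test(occ, toy, 0.5, reps = 49, seed = 1)
  expect_true(r$untestable)
  # permutation-invariant occupancy: null variance collapses
  all_everywhere <- occurrence_matrix(
    matrix(1L, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2"))))
  r2 <- partial_randomization_test(all_everywhere, toy, Inf, reps = 99,
                                   seed = 2)
  expect_equal(r2$null_sd, 0)
  expect_equal(r2$null_mean, r2$pi_st)
})

test_that("within-block shuffles leave deep structure fixed", {
  x <- rand_tree(16, 41)
  occ <- simulate_communities(x, n_sites = 4, richness_per_site = 6,
                              mode = "neutral", seed = 3)
  thr <- x$root_age / 3
  r <- partial_randomization_test(occ, x, thr, reps = 199, seed = 5)
  if (!r$untestable) {
    # truncate-only nulls shuffle everything: typically wider
    r2 <- partial_randomization_test(occ, x, thr, reps = 199, seed = 5,
                                     null_mode = "truncate_only")
    expect_false(r2$untestable)
    expect_true(is.finite(r$null_sd) && is.finite(r2$null_sd))
  }
  # determinism
  ra <- partial_randomization_test(occ, x, thr, reps = 99, seed = 7)
  rb <- partial_randomization_test(occ, x, thr, reps = 99, seed = 7)
  expect_identical(ra$null, rb$null)
})

test_that("profiles run a result per threshold with derived seeds", {
  x <- rand_tree(20, 51)
  occ <- simulate_communities(x, n_sites = 4, richness_per_site = 8,
                              mode = "neutral", seed = 4)
  thr <- seq(0.2, 1, by = 0.2) * x$root_age
  pr <- pist_profile(occ, x, thr, reps = 49, seed = 9)
  expect_equal(nrow(pr), 5)
  expect_equal(pr$threshold, thr)
  pr2 <- pist_profile(occ, x, thr, reps = 49, seed = 9)
  expect_equal(pr, pr2)
  expect_error(pist_profile(occ, x, rev(thr), reps = 9), "ascending")
})

test_that("filtered assembly clusters and limiting similarity disperses", {
  x <- simulate_yule_tree(rate_constant(0.067), n_tips = 40, seed = 61)
  up <- c(); lo <- c(); obs_f <- c(); obs_d <- c()
  for (r in 1:60) {
    of <- simulate_communities(x, n_sites = 6, richness_per_site = 12,
                               mode = "filtered", strength = 2,
                               seed = 100 + r)
    tf <- partial_randomization_test(of, x, Inf, reps = 99,
                                     seed = 200 + r)
    # a radius that bites on this tree: most pairs diverge > 25 Myr, so a
    # 25-Myr exclusion radius is a strong limiting-similarity regime while
    # 10 species per site remain feasible
    od <- suppressWarnings(
      simulate_communities(x, n_sites = 6, richness_per_site = 10,
                           mode = "dispersed", strength = 25,
                           seed = 300 + r))
    td <- partial_randomization_test(od, x, Inf, reps = 99,
                                     seed = 400 + r)
    obs_f <- c(obs_f, tf$pi_st); up <- c(up, tf$p_upper)
    obs_d <- c(obs_d, td$pi_st); lo <- c(lo, td$p_lower)
  }
  expect_gt(mean(obs_f), 0)
  expect_gt(mean(up < 0.05), 0.5)
  expect_lt(mean(obs_d), 0)
  # rejection toward dispersion far above the 5% nominal rate
  expect_gt(mean(lo < 0.05), 0.25)
})
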