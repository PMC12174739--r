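test_that("sampled lists respect sizes, uniqueness and the determinism contract", {
  cfg <- simulation_config(universe = letters[1:10], list_sizes = c(3, 5, 10),
                           sampling = "uniform", seed = 99)
  lists <- sample_gene_lists(cfg)
  expect_equal(lengths(lists), c(3L, 5L, 10L))
  expect_true(all(vapply(lists, anyDuplicated, integer(1)) == 0))
  expect_setequal(lists[[3]], letters[1:10])  # exhaustive list is the universe
  expect_identical(sample_gene_lists(cfg), lists)
  expect_error(simulation_config(letters[1:3], list_sizes = 4, sampling = "uniform"),
               "exceeds the universe")
  expect_error(simulation_config(letters[1:3], list_sizes = 2, sampling = "weighted"),
               "requires `weights`")
  expect_error(simulation_config(letters[1:3], list_sizes = 2, sampling = "weighted",
                                 weights = c(1, -1, 1)), "strictly positive")
})

test_that("a dominant weight is drawn almost always under weighted sampling", {
  cfg <- simulation_config(universe = c("a", "b", "c"), list_sizes = 1,
                           sampling = "weighted", weights = c(a = 1e6, b = 1, c = 1),
                           seed = 1)
  set.seed(42)
  hits <- sum(replicate(2000, {
    idx <- votenet:::weighted_sample_int(3, 1, c(1e6, 1, 1))
    idx == 1L
  }))
  expect_gte(hits / 2000, 0.99)
})

test_that("weighted draw frequencies match exact successive-renormalized-draw probabilities", {
  w <- c(4, 3, 2, 1)
  subsets <- utils::combn(4, 2, simplify = FALSE)
  exact <- vapply(subsets, exact_weighted_subset_prob, numeric(1), weights = w)
  expect_equal(sum(exact), 1, tolerance = 1e-12)
  set.seed(77)
  n_draw <- 40000
  drawn <- replicate(n_draw, paste(sort(votenet:::weighted_sample_int(4, 2, w)),
                                   collapse = ","))
  freq <- table(factor(drawn, levels = vapply(subsets, function(s)
    paste(sort(s), collapse = ","), character(1)))) / n_draw
  se <- sqrt(exact * (1 - exact) / n_draw)
  expect_true(all(abs(as.numeric(freq) - exact) <= 4 * se))
})

test_that("null summaries and degenerate configurations behave as enumeration dictates", {
  # both lists equal to the whole universe: overlap is always the universe
  cfg <- simulation_config(letters[1:4], c(4, 4), iterations = 50,
                           sampling = "uniform", seed = 2)
  null <- simulate_null(cfg)
  expect_true(all(null$per_iteration_total == 4L))
  expect_equal(null$sd_total, 0)
  # one list only: overlap is always zero
  cfg1 <- simulation_config(letters[1:6], 3, iterations = 50,
                            sampling = "uniform", seed = 2)
  expect_true(all(simulate_null(cfg1)$per_iteration_total == 0L))
  # reproducibility: identical config implies bit-identical null
  cfg3 <- simulation_config(letters[1:8], c(3, 4), iterations = 200,
                            sampling = "uniform", seed = 123)
  expect_identical(simulate_null(cfg3), simulate_null(cfg3))
})

test_that("Monte Carlo tail probabilities match exhaustive enumeration (2 lists, known closed form)", {
  # universe 4, lists of 2: P(no overlap) = C(2,2)/C(4,2) = 1/6
  cfg <- simulation_config(letters[1:4], c(2, 2), iterations = 10000,
                           sampling = "uniform", seed = 7)
  null <- simulate_null(cfg)
  p_hat <- mean(null$per_iteration_total >= 1)
  p_exact <- 5 / 6
  se <- sqrt(p_exact * (1 - p_exact) / cfg$iterations)
  expect_lt(abs(p_hat - p_exact), 3 * se)
})

test_that("empirical p-values follow the add-one convention and the bound rendering", {
  null <- structure(list(per_iteration_total = c(1L, 2L, 3L),
                         level_counts = matrix(c(1L, 2L, 3L), 3, 1,
                                               dimnames = list(NULL, "2")),
                         iterations = 3L), class = "overlap_null")
  t2 <- empirical_pvalue(null, 2)
  expect_equal(t2$exceedances, 2L)
  expect_equal(t2$p_value, 3 / 4)
  expect_false(t2$p_is_bound)
  t0 <- empirical_pvalue(null, 0)
  expect_equal(t0$p_value, 1)
  t9 <- empirical_pvalue(null, 9)
  expect_true(t9$p_is_bound)
  expect_equal(t9$p_value, 1 / 4)
  # at 10000 iterations an unreached observed value renders as "< 0.0001"
  big <- structure(list(per_iteration_total = rep(0L, 10000),
                        level_counts = matrix(0L, 10000, 1,
                                              dimnames = list(NULL, "2")),
                        iterations = 10000L), class = "overlap_null")
  tb <- empirical_pvalue(big, 5)
  expect_equal(tb$p_value, 1 / 10001)
  expect_equal(format_pvalue(tb), "< 0.0001")
})

test_that("equal weights reduce weighted sampling to uniform; unequal weights inflate overlap", {
  uni <- paste0("g", 1:150)
  sizes <- c(25, 30, 35)
  eq <- simulation_config(uni, sizes, iterations = 1500, sampling = "weighted",
                          weights = rep(1, 150), seed = 5)
  pair_eq <- compare_sampling_modes(eq)
  se_comb <- sqrt(pair_eq$weighted$sd_total^2 / 1500 + pair_eq$uniform$sd_total^2 / 1500)
  expect_lt(abs(pair_eq$mean_diff), 3 * se_comb)
  # strongly heterogeneous weights concentrate draws and raise co-occurrence
  hw <- c(rep(30, 30), rep(1, 120))
  het <- simulation_config(uni, sizes, iterations = 1500, sampling = "weighted",
                           weights = hw, seed = 5)
  pair_het <- compare_sampling_modes(het)
  expect_gt(pair_het$mean_diff, 0)
})

test_that("enlarging a list size never decreases mean overlap (matched seeds)", {
  uni <- paste0("g", 1:200)
  base <- c(20, 30, 40)
  null0 <- simulate_null(simulation_config(uni, base, iterations = 800,
                                           sampling = "uniform", seed = 31))
  for (j in 1:3) {
    grown <- base
    grown[j] <- grown[j] + 30
    nullg <- simulate_null(simulation_config(uni, grown, iterations = 800,
                                             sampling = "uniform", seed = 31))
    expect_gte(nullg$mean_total, null0$mean_total)
  }
})

test_that("direction-aware null counts only majority-consistent overlap", {
  # with up-fraction 1 every co-occurrence is consistent: identical to the
  # identity count; with balanced signs two-list overlaps halve on average
  uni <- paste0("g", 1:100)
  cfg_id <- simulation_config(uni, c(20, 20), iterations = 1200,
                              sampling = "uniform", seed = 8)
  cfg_up <- simulation_config(uni, c(20, 20), iterations = 1200,
                              sampling = "uniform", seed = 8,
                              simulate_directions = 1)
  n_up <- simulate_null(cfg_up)
  n_id <- simulate_null(cfg_id)
  se_ud <- sqrt(n_up$sd_total^2 / 1200 + n_id$sd_total^2 / 1200)
  expect_lt(abs(n_up$mean_total - n_id$mean_total), 3 * se_ud)
  cfg_half <- simulation_config(uni, c(20, 20), iterations = 1200,
                                sampling = "uniform", seed = 8,
                                simulate_directions = 0.5)
  half <- simulate_null(cfg_half)
  id <- simulate_null(cfg_id)
  ratio <- half$mean_total / id$mean_total
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)
})
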