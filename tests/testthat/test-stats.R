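test_that("occupancy summary counts and renormalises as documented", {
  s <- summarize_occupancy(c("MA", "MA", "T", "AB"), times = 1:4,
                           equilibration_cutoff_ns = 0, renormalize = FALSE)
  expect_equal(s$percent, c(50, 25, 25, 0, 0))
  expect_equal(sum(s$percent), 100)
  expect_equal(attr(s, "n_equilibrated"), 4L)
  # renormalised: UNASSIGNED excluded from the denominator
  s2 <- summarize_occupancy(c("MA", "MA", "T", "UNASSIGNED"), times = 1:4,
                            equilibration_cutoff_ns = 0, renormalize = TRUE)
  expect_equal(s2$percent[1:4], c(200 / 3, 100 / 3, 0, 0))
  expect_true(is.na(s2$percent[5]))
  expect_equal(s2$n[5], 1L)
  # cutoff excluding everything is an error
  expect_error(summarize_occupancy(c("MA", "T"), times = c(1, 2),
                                   equilibration_cutoff_ns = 10),
               "no equilibrated frames")
  # cutoff is strict: frames at exactly the cutoff are discarded
  s3 <- summarize_occupancy(c("MA", "T"), times = c(150, 151),
                            equilibration_cutoff_ns = 150)
  expect_equal(attr(s3, "n_equilibrated"), 1L)
})

test_that("pipeline occupancy recovers the stationary distribution", {
  b <- big_sim()
  rep <- big_report()
  occ <- rep$monomers$A$occupancy
  pi0 <- 100 * stationary_distribution(b$cfg$transition_matrix)
  for (s in names(pi0)) {
    obs <- occ$percent[as.character(occ$region) == s]
    expect_lt(abs(obs - pi0[[s]]), 2)
  }
})

test_that("pre-reactive cross-tab arithmetic is exact", {
  lab <- c(rep("T", 6), rep("MA", 6), rep("AB", 4))
  fl <- c(rep(TRUE, 3), rep(FALSE, 3),  # 3 flagged T
          TRUE, rep(FALSE, 5),          # 1 flagged MA
          rep(FALSE, 4))
  ct <- crosstab_prereactive(lab, fl, times = 1:16,
                             equilibration_cutoff_ns = 0)
  expect_equal(ct$overall_percent, 25)
  expect_equal(ct$conditional$percent,
               c(25, 75, 0)[match(c("MA", "T", "AB"), ct$conditional$region)])
  expect_equal(sum(ct$conditional$percent), 100)
  # zero flags: overall 0, conditionals absent
  ct0 <- crosstab_prereactive(lab, rep(FALSE, 16), times = 1:16,
                              equilibration_cutoff_ns = 0)
  expect_equal(ct0$overall_percent, 0)
  expect_true(all(is.na(ct0$conditional$percent)))
})

test_that("overall pre-reactive percentage equals the flag mean", {
  set.seed(801)
  lab <- sample(region_levels(), 500, replace = TRUE)
  fl <- runif(500) < 0.3
  tm <- seq_len(500)
  ct <- crosstab_prereactive(lab, fl, tm, equilibration_cutoff_ns = 100)
  keep <- tm > 100
  expect_equal(ct$overall_percent, 100 * mean(fl[keep]))
  expect_lte(ct$overall_percent, 100)
})

test_that("region transfer counting matches the automaton oracle", {
  ct <- function(x, d) {
    out <- count_region_transitions(x, d)$transitions
    stats::setNames(out$n, out$transition)
  }
  expect_equal(ct(c("MA", "MA", "T", "AB", "AB"), 2),
               c("MA->AB" = 1L, "AB->MA" = 0L))
  expect_equal(ct(c("MA", "T", "MA"), 1), c("MA->AB" = 0L, "AB->MA" = 0L))
  # a dwell-qualified NB episode breaks the chain
  expect_equal(ct(c("MA", "MA", "NB", "NB", "AB", "AB"), 2),
               c("MA->AB" = 0L, "AB->MA" = 0L))
  set.seed(802)
  for (i in 1:30) {
    x <- sample(region_levels(), 500, replace = TRUE,
                prob = c(0.3, 0.25, 0.3, 0.1, 0.05))
    d <- sample(1:5, 1)
    want <- oracle_transitions(x, c("MA->AB", "AB->MA"), d,
                               transit = c("T", "UNASSIGNED"), breaker = "NB")
    expect_equal(ct(x, d), want)
  }
})

test_that("transfer counts ignore unassigned frames inside a qualified run", {
  base <- c(rep("MA", 6), rep("AB", 6))
  with_gap <- c(rep("MA", 3), "UNASSIGNED", rep("MA", 3), rep("AB", 6))
  ct <- function(x) count_region_transitions(x, 5)$transitions$n
  expect_equal(ct(with_gap), ct(base))
})

test_that("monomer pooling is frame-weighted and flags disagreement", {
  mk <- function(labels) {
    summarize_occupancy(labels, seq_along(labels),
                        equilibration_cutoff_ns = 0, renormalize = FALSE)
  }
  a <- mk(c(rep("MA", 60), rep("T", 40)))
  b <- mk(c(rep("MA", 120), rep("T", 180)))
  expect_warning(cmp <- compare_monomers(a, b), "percentage points")
  expect_equal(cmp$pooled$percent[cmp$pooled$region == "MA"], 45)
  expect_equal(cmp$max_abs_diff_percent, 20)
  expect_equal(attr(cmp$pooled, "n_equilibrated"), 400L)
  # identical monomers pool to themselves with zero difference
  cmp2 <- compare_monomers(a, a)
  expect_equal(cmp2$max_abs_diff_percent, 0)
  expect_equal(cmp2$pooled$percent, a$percent)
  # configuration mismatch is an error
  a150 <- summarize_occupancy(rep("MA", 10), 151:160,
                              equilibration_cutoff_ns = 150,
                              renormalize = FALSE)
  expect_error(compare_monomers(a, a150), "mismatched")
})

test_that("pooling equals summarising the concatenated label stream", {
  set.seed(803)
  la <- sample(region_levels(), 300, replace = TRUE)
  lb <- sample(region_levels(), 700, replace = TRUE)
  mk <- function(l) summarize_occupancy(l, seq_along(l),
                                        equilibration_cutoff_ns = 0,
                                        renormalize = TRUE)
  pooled <- suppressWarnings(compare_monomers(mk(la), mk(lb)))$pooled
  direct <- mk(c(la, lb))
  expect_equal(pooled$percent, direct$percent)
  expect_equal(pooled$n, direct$n)
})

test_that("two same-parameter monomers agree within the sampling bound", {
  cfg_a <- generator_config(seed = 211L, n_frames = 20000L)
  cfg_b <- generator_config(seed = 212L, n_frames = 20000L)
  sim_a <- generate_trajectory(cfg_a)
  sim_b <- generate_trajectory(cfg_b)
  mk <- function(sim) {
    summarize_occupancy(sim$truth$state, sim$truth$time_ns,
                        equilibration_cutoff_ns = 0, renormalize = FALSE)
  }
  cmp <- compare_monomers(mk(sim_a), mk(sim_b))
  expect_lte(cmp$max_abs_diff_percent, 4)
})
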