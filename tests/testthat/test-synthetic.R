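test_that("the generator is deterministic and leaves the caller's RNG alone", {
  cfg <- generator_config(seed = 5L, n_frames = 200L)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  a <- generate_trajectory(cfg)
  after <- runif(1)
  expect_equal(after, before) # RNG state untouched by the generator
  b <- generate_trajectory(cfg)
  expect_identical(a$trajectory$xyz, b$trajectory$xyz)
  expect_identical(a$truth, b$truth)
  # a different seed changes the draw
  c2 <- generate_trajectory(generator_config(seed = 6L, n_frames = 200L))
  expect_false(identical(a$trajectory$xyz, c2$trajectory$xyz))
})

test_that("zero frames yield an empty trajectory and empty truth", {
  z <- generate_trajectory(generator_config(seed = 1L, n_frames = 0L))
  expect_equal(n_frames(z$trajectory), 0L)
  expect_equal(nrow(z$truth), 0L)
  expect_equal(nrow(z$events), 0L)
})

test_that("inseparable anchors are rejected", {
  anch <- rbind(MA = c(0, 0, 0), T = c(1, 0, 0),
                AB = c(16.5, 0, 0), NB = c(8.25, 25, 0))
  cfg <- generator_config(seed = 1L, n_frames = 10L, anchors = anch,
                          noise_sigma = 0.8)
  expect_error(generate_trajectory(cfg), "not separable")
})

test_that("empirical state fractions approach the configured stationary law", {
  b <- big_sim()
  pi0 <- stationary_distribution(b$cfg$transition_matrix)
  emp <- table(factor(b$sim$truth$state, levels = names(pi0))) / 20000
  for (s in names(pi0)) {
    expect_lt(abs(100 * emp[[s]] - 100 * pi0[[s]]), 2)
  }
  # the event log is consistent with the label sequence
  st <- b$sim$truth$state
  chg <- which(st[-1] != st[-length(st)])
  expect_equal(b$sim$events$frame, chg + 1L)
  expect_equal(b$sim$events$from, st[chg])
  expect_equal(b$sim$events$to, st[chg + 1L])
})

test_that("paddle dihedrals in generated frames realise the drawn mixtures", {
  cfg <- generator_config(seed = 33L, n_frames = 600L)
  sim <- generate_trajectory(cfg)
  pa <- compute_paddle_angles(sim$trajectory)
  # AB frames emit the closed rotamer (~65 deg), MA frames the open (~160)
  ab <- pa$phiF[sim$truth$state == "AB"]
  ma <- pa$phiF[sim$truth$state == "MA"]
  expect_true(all(abs(ab - 65) < 45))
  expect_true(all(abs(ma - 160) < 45))
  # gating modes are tight: circular SD of each unimodal state is ~8 degrees
  expect_lt(stats::sd(ab), 12)
})

test_that("stationary distribution and analytic expectations are exact closed forms", {
  # uniform 4-state chain with pre-reactive injection only in T
  P <- matrix(0.25, 4, 4, dimnames = list(c("MA", "T", "AB", "NB"),
                                          c("MA", "T", "AB", "NB")))
  cfg <- generator_config(seed = 1L, transition_matrix = P,
                          prereactive_prob = c(0, 1, 0, 0))
  ae <- analytic_expectations(cfg)
  expect_equal(ae$occupancy$expected_percent, rep(25, 4))
  expect_equal(ae$overall_prereactive_percent, 25)
  expect_equal(ae$conditional$expected_percent[ae$conditional$state == "T"],
               100)
  # all-zero injection
  cfg0 <- generator_config(seed = 1L, prereactive_prob = rep(0, 4))
  expect_equal(analytic_expectations(cfg0)$overall_prereactive_percent, 0)
  # reducible chain rejected
  P2 <- diag(4)
  dimnames(P2) <- dimnames(P)
  cfg2 <- generator_config(seed = 1L, transition_matrix = P2)
  expect_error(analytic_expectations(cfg2), "reducible")
})

test_that("closed-form expectations match a long simulation", {
  cfg <- generator_config(seed = 77L, n_frames = 20000L,
                          stationary = c(MA = 0.4, T = 0.35, AB = 0.2,
                                         NB = 0.05),
                          self_transition = 0.6,
                          prereactive_prob = c(0.2, 0.5, 0.1, 0))
  sim <- generate_trajectory(cfg)
  ae <- analytic_expectations(cfg)
  emp_overall <- 100 * mean(sim$truth$prereactive)
  expect_lt(abs(emp_overall - ae$overall_prereactive_percent), 2)
  emp_occ <- 100 * table(factor(sim$truth$state,
                                levels = ae$occupancy$state)) / 20000
  expect_true(all(abs(as.numeric(emp_occ) -
                        ae$occupancy$expected_percent) < 2))
})

test_that("fixtures round-trip through PDB, CSV and YAML", {
  cfg <- generator_config(seed = 9L, n_frames = 25L, chain_length = 10L)
  sim <- generate_trajectory(cfg)
  dir <- withr::local_tempdir()
  write_fixture(sim, cfg, dir)
  expect_true(all(file.exists(file.path(dir, c("trajectory.pdb", "truth.csv",
                                               "config.yaml")))))
  fx <- read_fixture(dir)
  # coordinates to PDB fixed-point precision
  expect_equal(fx$trajectory$xyz, sim$trajectory$xyz, tolerance = 1e-3)
  expect_lte(max(abs(fx$trajectory$xyz - sim$trajectory$xyz)), 5.01e-4)
  expect_equal(nrow(fx$truth), 25L)
  expect_equal(fx$truth$state, sim$truth$state)
  # the stored config regenerates the fixture bit-exactly
  sim2 <- generate_trajectory(fx$config)
  expect_identical(sim2$trajectory$xyz, sim$trajectory$xyz)
  # atom identities survive the round trip
  expect_equal(fx$trajectory$topology$name, sim$trajectory$topology$name)
  expect_equal(fx$trajectory$topology$resid, sim$trajectory$topology$resid)
  expect_equal(fx$trajectory$topology$chain, sim$trajectory$topology$chain)
})
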