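# Builds a tiny two-residue topology whose CG atoms realise prescribed chi1
# torsions, frame by frame.
paddle_fixture <- function(phiF, phiW) {
  scaf <- function(ca) list(N = ca + c(-1.46, 0, 0), CA = ca,
                            CB = ca + c(0.5, 1.4, 0))
  sF <- scaf(c(0, 0, 0))
  sW <- scaf(c(10, 0, 0))
  topo <- tibble::tibble(
    serial = 1:8,
    name = rep(c("N", "CA", "CB", "CG"), 2),
    resname = rep(c("PHE", "TRP"), each = 4),
    resid = rep(c(432L, 531L), each = 4),
    chain = "A",
    element = rep(c("N", "C", "C", "C"), 2))
  nf <- length(phiF)
  xyz <- matrix(NA_real_, nf, 24)
  for (f in seq_len(nf)) {
    cgF <- lipidgate:::place_atom(sF$N, sF$CA, sF$CB, 1.5, 114, phiF[f])
    cgW <- lipidgate:::place_atom(sW$N, sW$CA, sW$CB, 1.5, 114, phiW[f])
    xyz[f, ] <- c(sF$N, sF$CA, sF$CB, cgF, sW$N, sW$CA, sW$CB, cgW)
  }
  md_trajectory(topo, xyz)
}

test_that("paddle dihedrals recover constructed rotamers and gate states", {
  pa <- compute_paddle_angles(paddle_fixture(c(65, 160, 110), c(180, 180, 180)))
  expect_equal(pa$phiF, c(65, 160, 110), tolerance = 1e-9)
  expect_equal(pa$phiW, rep(180, 3), tolerance = 1e-9)
  expect_equal(as.character(pa$gate), c("CLOSED", "OPEN", "INTERMEDIATE"))
  # missing atom errors name the residue and atom
  tr <- paddle_fixture(65, 180)
  tr2 <- md_trajectory(tr$topology[-4, ], tr$xyz[, -(10:12), drop = FALSE])
  expect_error(compute_paddle_angles(tr2), "A:432 lacks atom CG")
})

test_that("gate classification is invariant under adding full turns", {
  set.seed(701)
  phi <- runif(200, -720, 720)
  expect_identical(classify_gate(phi), classify_gate(phi + 360))
  expect_identical(classify_gate(phi), classify_gate(phi - 720))
  expect_true(all(wrap_360(phi) >= 0 & wrap_360(phi) < 360))
})

test_that("pre-reactive evaluation obeys bounds, combination and vacuous truth", {
  b <- big_sim()
  tr <- b$sim$trajectory
  crit <- default_prereactive_criteria()
  ev <- evaluate_prereactive(tr, crit)
  # ground-truth injected flags are recovered exactly frame by frame
  expect_identical(ev$flags$prereactive, b$sim$truth$prereactive)
  # report carries one measured value per frame per criterion
  expect_equal(nrow(ev$report), nrow(crit) * n_frames(tr))
  # vacuous truth: all bounds open
  open_crit <- crit
  open_crit$min <- NA_real_
  open_crit$max <- NA_real_
  ev_open <- evaluate_prereactive(tr, open_crit)
  expect_true(all(ev_open$flags$prereactive))
  # combine = any is at least as permissive as all
  ev_any <- evaluate_prereactive(tr, crit, combine = "any")
  expect_true(all(ev$flags$prereactive <= ev_any$flags$prereactive))
})

test_that("tightening any criterion only shrinks the pre-reactive set", {
  b <- big_sim()
  tr <- b$sim$trajectory
  crit <- default_prereactive_criteria()
  base <- evaluate_prereactive(tr, crit)$flags$prereactive
  for (i in seq_len(nrow(crit))) {
    tight <- crit
    if (!is.na(tight$max[i])) tight$max[i] <- tight$max[i] * 0.8
    if (!is.na(tight$min[i])) tight$min[i] <- tight$min[i] * 1.1
    flag <- evaluate_prereactive(tr, tight)$flags$prereactive
    expect_true(all(flag <= base))
  }
})

test_that("flagged fraction lies in the binomial band of the injected probability", {
  b <- big_sim()
  rep <- big_report()
  truth <- b$sim$truth
  flags <- rep$monomers$A$prereactive$prereactive
  p <- b$cfg$prereactive_prob
  for (s in c("MA", "T", "AB")) {
    n_s <- sum(truth$state == s)
    k <- sum(flags[truth$state == s])
    band <- qbinom(c(0.025, 0.975), n_s, p[[s]])
    expect_gte(k, band[1])
    expect_lte(k, band[2])
  }
})

test_that("polar records project exactly the pre-reactive pocket frames", {
  lab <- tibble::tibble(
    label = c("T", "MA", "NB", "AB", "T"),
    dMA = c(7, 4, 14, 8, 7.5),
    dAB = c(7, 8, 15, 4, 7.2),
    dT = c(4.2, 3, 13, 3.5, 4.4))
  pad <- tibble::tibble(phiF = c(150, 60, 70, 65, 155),
                        phiW = c(180, 175, 170, 182, 178))
  flags <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  rec <- build_polar_records(lab, pad, flags)
  expect_equal(nrow(rec), 2L) # NB frame dropped despite flag
  expect_equal(as.character(rec$region), c("T", "AB"))
  expect_equal(rec$radius, c(4.2, 4))
  expect_equal(rec$phiF, c(150, 65))
  expect_equal(nrow(build_polar_records(lab, pad, rep(FALSE, 5))), 0L)
  expect_error(build_polar_records(lab, pad[1:3, ], flags), "length mismatch")
  # counting oracle on random aligned inputs
  set.seed(702)
  for (i in 1:10) {
    n <- 300
    lab2 <- tibble::tibble(
      label = sample(region_levels(), n, replace = TRUE),
      dMA = runif(n, 0, 15), dAB = runif(n, 0, 15), dT = runif(n, 0, 15))
    pad2 <- tibble::tibble(phiF = runif(n, 0, 360), phiW = runif(n, 0, 360))
    fl2 <- runif(n) < 0.3
    rec2 <- build_polar_records(lab2, pad2, fl2)
    expect_equal(nrow(rec2), sum(fl2 & lab2$label %in% c("MA", "T", "AB")))
    expect_lte(nrow(rec2), sum(fl2))
  }
})

test_that("gate transition counting matches the automaton oracle", {
  gt <- function(x, d) {
    out <- count_gate_transitions(x, d)
    stats::setNames(out$n, out$transition)
  }
  expect_equal(gt(c("CLOSED", "CLOSED", "OPEN", "OPEN"), 2),
               c("CLOSED->OPEN" = 1L, "OPEN->CLOSED" = 0L))
  expect_equal(gt(c("CLOSED", "INTERMEDIATE", "CLOSED"), 1),
               c("CLOSED->OPEN" = 0L, "OPEN->CLOSED" = 0L))
  # intermediate frames do not reset a pending transition
  expect_equal(gt(c("CLOSED", "CLOSED", "INTERMEDIATE", "OPEN",
                    "INTERMEDIATE", "OPEN"), 2),
               c("CLOSED->OPEN" = 1L, "OPEN->CLOSED" = 0L))
  set.seed(703)
  for (i in 1:30) {
    x <- sample(c("CLOSED", "OPEN", "INTERMEDIATE"), 500, replace = TRUE,
                prob = c(0.45, 0.45, 0.1))
    d <- sample(1:5, 1)
    want <- oracle_transitions(x, c("CLOSED->OPEN", "OPEN->CLOSED"), d,
                               transit = "INTERMEDIATE")
    expect_equal(gt(x, d), want)
  }
})
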