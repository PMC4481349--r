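test_that("torsion profiles reproduce constructed window angles", {
  pos <- zigzag_chain(10)
  prof <- torsion_profile_from_coords(pos)
  expect_equal(nrow(prof), 7L)
  expect_equal(prof$omega, rep(180, 7), tolerance = 1e-6)
  # a cis kink at one window
  om <- rep(180, 9)
  om[4] <- 0
  prof2 <- torsion_profile_from_coords(chain_with_torsions(om))
  expect_equal(prof2$omega[4], 0, tolerance = 1e-8)
  # element-wise agreement with direct dihedral calls on a random chain
  set.seed(601)
  om3 <- runif(10, -179, 180)
  pos3 <- chain_with_torsions(om3)
  prof3 <- torsion_profile_from_coords(pos3)
  direct <- vapply(seq_len(nrow(pos3) - 3), function(i) {
    dihedral_angle(pos3[i, ], pos3[i + 1, ], pos3[i + 2, ], pos3[i + 3, ])
  }, numeric(1))
  expect_equal(prof3$omega, direct, tolerance = 1e-9)
  expect_error(torsion_profile_from_coords(zigzag_chain(3)), ">= 4")
})

test_that("shape descriptors quantify straight, hairpin and L geometries", {
  straight <- cbind(0:15 * 1.0, 0, 0)
  d <- compute_shape_descriptors(straight)
  expect_equal(d$r, 1, tolerance = 1e-9)
  expect_lt(d$max_bend_deg, 1e-6)
  # hairpin: two antiparallel arms joined at the midpoint
  arm <- 7
  hair <- rbind(cbind(0:arm * 1.0, 0, 0),
                cbind(arm:0 * 1.0, 0.8, 0))
  dh <- compute_shape_descriptors(hair)
  expect_lt(dh$r, 0.1)
  expect_gt(dh$max_bend_deg, 150)
  expect_equal(dh$bend_position, 0.5, tolerance = 0.12)
  # L-shape bent 90 degrees at one quarter of the length
  L <- rbind(cbind(0:3 * 1.0, 0, 0),
             cbind(3, 1:12 * 1.0, 0))
  dL <- compute_shape_descriptors(L, segment_len = 4L)
  expect_lt(abs(dL$max_bend_deg - 90), 15)
  expect_lt(abs(dL$bend_position - 0.25), 0.1)
  expect_error(compute_shape_descriptors(straight[1:5, ], 4L), "too short")
})

test_that("fine classes map to coarse shapes totally and uniquely", {
  fine <- c("Ex", "Uex", "J", "Jp", "U", "Hx", "HxA", "HxB")
  coarse <- fine_to_coarse(fine)
  expect_false(anyNA(coarse))
  expect_equal(coarse[1:2], rep("elongated", 2))
  expect_equal(coarse[3:4], rep("hooked", 2))
  expect_equal(coarse[5:8], rep("curved", 4))
})

test_that("torsion-pattern policy assigns the canonical fine classes", {
  classify_om <- function(om) {
    classify_shape(profile = tibble::tibble(omega = om, missing = is.na(om)),
                   policy = "torsion_pattern")
  }
  expect_equal(classify_om(rep(180, 13))$fine, "Ex")
  expect_equal(classify_om(rep(180, 13))$coarse, "elongated")
  # single isolated non-trans window
  om <- rep(175, 13); om[6] <- 60
  expect_equal(classify_om(om)$fine, "Uex")
  # gauche block at windows 2-3 of 13: terminal third, positive sum -> J
  om <- rep(178, 13); om[2:3] <- 65
  cls <- classify_om(om)
  expect_equal(cls$fine, "J")
  expect_equal(cls$coarse, "hooked")
  om[2:3] <- -65
  expect_equal(classify_om(om)$fine, "Jp")
  # central block -> U
  om <- rep(178, 13); om[6:8] <- 60
  expect_equal(classify_om(om)$coarse, "curved")
  # blocks in both halves -> Hx; single-half variants
  om <- rep(178, 13); om[2:3] <- 60; om[11:12] <- 60
  expect_equal(classify_om(om)$fine, "Hx")
  om <- rep(178, 13); om[2:3] <- 60; om[5] <- 60
  expect_equal(classify_om(om)$fine, "HxA")
  om <- rep(178, 13); om[9:10] <- 60; om[12] <- 60
  expect_equal(classify_om(om)$fine, "HxB")
  # refusal above the missing-torsion budget
  om <- rep(180, 10); om[1:3] <- NA
  expect_error(classify_om(om), "refused")
})

test_that("end-to-end policy depends only on the descriptors", {
  des <- function(r, bp) tibble::tibble(r = r, max_bend_deg = 90,
                                        bend_position = bp)
  pol <- function(r, bp) {
    classify_shape(descriptors = des(r, bp), policy = "end_to_end")$coarse
  }
  expect_equal(pol(1.0, 0.5), "elongated")
  expect_equal(pol(0.80, 0.5), "elongated")
  expect_equal(pol(0.5, 0.2), "hooked")
  expect_equal(pol(0.5, 0.8), "hooked")
  expect_equal(pol(0.5, 0.5), "curved")
  # torsions are irrelevant under this policy
  cls <- classify_shape(profile = tibble::tibble(omega = rep(0, 9),
                                                 missing = FALSE),
                        descriptors = des(0.9, 0.5), policy = "end_to_end")
  expect_equal(cls$coarse, "elongated")
  expect_equal(cls$fine, "NA")
})

test_that("shape classification is invariant under rigid motions", {
  set.seed(602)
  shapes <- list(
    all_trans = rep(178, 11),
    terminal = {om <- rep(178, 11); om[2:3] <- 62; om},
    central = {om <- rep(178, 11); om[5:7] <- 62; om}
  )
  for (om in shapes) {
    pos <- chain_with_torsions(om)
    base <- classify_shape(profile = torsion_profile_from_coords(pos),
                           policy = "torsion_pattern")
    for (i in 1:10) {
      tp <- apply_rigid(pos, random_rigid())
      got <- classify_shape(profile = torsion_profile_from_coords(tp),
                            policy = "torsion_pattern")
      expect_equal(got$fine, base$fine)
    }
  }
})

test_that("per-frame shape series recovers generator emission fractions", {
  b <- big_sim()
  rep <- big_report()
  series <- rep$monomers$A$shapes$series
  expect_equal(nrow(series), 20000L)
  # exact agreement with ground truth labels (noise-free torsion patterns)
  agree <- mean(series$coarse == b$sim$truth$shape)
  expect_gt(agree, 0.97)
  # fractions within 3 points of the analytic mixture
  pi0 <- stationary_distribution(b$cfg$transition_matrix)
  expected <- as.numeric(t(b$cfg$shape_emission) %*% pi0)
  names(expected) <- colnames(b$cfg$shape_emission)
  fr <- rep$monomers$A$shapes$fractions
  for (cl in fr$coarse) {
    expect_lt(abs(100 * fr$fraction[fr$coarse == cl] - 100 * expected[[cl]]), 3)
  }
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)
})

test_that("an empty trajectory yields an empty shape series", {
  topo <- tibble::tibble(serial = 1:4, name = paste0("C", 1:4),
                         resname = "SUB", resid = 1L, chain = "L",
                         element = "C")
  traj <- md_trajectory(topo, matrix(numeric(0), 0, 12))
  st <- shape_time_series(traj, 1:4)
  expect_equal(nrow(st$series), 0L)
  expect_equal(st$n_unclassified, 0L)
})
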