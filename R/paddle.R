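# Dynamic-paddle analysis: side-chain gating dihedrals phiF (Phe432) and phiW
# (Trp531) about the Calpha-Cbeta axis, MA-gate open/closed states,
# pre-reactive (catalytically significant / near-attack) conformation
# detection from configurable geometric criteria, and the polar-coordinate
# records relating phi to the pocket distances.

#' Compute paddle dihedrals and MA-gate state per frame
#'
#' The gating torsion phi is the side-chain dihedral about the Calpha-Cbeta
#' axis, by default the chi1 quadruple N-CA-CB-CG (policy `"N"`; policy `"C"`
#' uses C-CA-CB-CG). Angles are reported in 0..360 degrees. Gate state from
#' phiF: CLOSED if phiF is inside `closed_bin` (default 45-85, bracketing the
#' ~65 degree crystallographic rotamer), OPEN if inside `open_bin` (default
#' 140-200, bracketing the ~160 degree open rotamer), else INTERMEDIATE.
#'
#' @param trajectory An [md_trajectory()].
#' @param resF Reference "chain:resid" for the Phe-like gate residue (default
#'   `"A:432"`).
#' @param resW Reference "chain:resid" for the Trp-like partner (default
#'   `"A:531"`).
#' @param quadruple_policy `"N"` (N-CA-CB-CG, chi1) or `"C"` (C-CA-CB-CG).
#' @param closed_bin,open_bin Length-2 numeric bins in degrees on 0..360.
#' @return Tibble with columns `frame`, `time_ns`, `phiF`, `phiW` (degrees in
#'   0..360), `gate` (factor CLOSED/OPEN/INTERMEDIATE).
#' @export
compute_paddle_angles <- function(trajectory, resF = "A:432", resW = "A:531",
                                  quadruple_policy = c("N", "C"),
                                  closed_bin = c(45, 85),
                                  open_bin = c(140, 200)) {
  quadruple_policy <- match.arg(quadruple_policy)
  first_atom <- if (quadruple_policy == "N") "N" else "C"
  quad <- function(ref) {
    parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("residue reference must be 'chain:resid'",
                                 call. = FALSE)
    vapply(c(first_atom, "CA", "CB", "CG"), function(nm) {
      idx <- select_atoms(trajectory, chain = parts[1],
                          resid = as.integer(parts[2]), name = nm)
      if (length(idx) == 0L) {
        stop("residue ", ref, " lacks atom ", nm, call. = FALSE)
      }
      idx[1]
    }, integer(1))
  }
  phiF <- wrap_360(dihedral_series(trajectory, quad(resF)))
  phiW <- wrap_360(dihedral_series(trajectory, quad(resW)))
  tibble::tibble(
    frame = seq_len(n_frames(trajectory)),
    time_ns = trajectory$times,
    phiF = phiF,
    phiW = phiW,
    gate = classify_gate(phiF, closed_bin, open_bin)
  )
}

#' Wrap angles into the 0..360 degree range
#' @param x Angles in degrees.
#' @return Angles in 0 <= x < 360.
#' @export
wrap_360 <- function(x) ((x %% 360) + 360) %% 360

#' Classify MA-gate state from phiF
#'
#' @param phiF Angles in degrees (any representation; wrapped into 0..360).
#' @inheritParams compute_paddle_angles
#' @return Factor with levels CLOSED, OPEN, INTERMEDIATE.
#' @export
classify_gate <- function(phiF, closed_bin = c(45, 85), open_bin = c(140, 200)) {
  phi <- wrap_360(phiF)
  out <- rep("INTERMEDIATE", length(phi))
  out[phi >= closed_bin[1] & phi <= closed_bin[2]] <- "CLOSED"
  out[phi >= open_bin[1] & phi <= open_bin[2]] <- "OPEN"
  factor(out, levels = c("CLOSED", "OPEN", "INTERMEDIATE"))
}

#' Default pre-reactive criterion set
#'
#' Near-attack geometry of the serine-hydrolase mechanism, expressed as four
#' criteria combined with AND: the nucleophile-attack distance from the
#' catalytic serine Ser241 O-gamma to the substrate carbonyl carbon
#' (<= 4 A); the attack angle O-gamma...C=O at the carbonyl carbon within a
#' Buergi-Dunitz-like window (75-115 degrees); and the two oxyanion-hole
#' hydrogen-bond distances from the backbone N of Gly239 and Gly240 to the
#' carbonyl oxygen (<= 3.5 A each). These numeric bounds are this package's
#' configurable defaults for near-attack geometry, not published values.
#'
#' Atom references are `"chain:resid:atomname"`; the substrate carbonyl here
#' follows the synthetic-topology naming (`L:900:C1` / `L:900:O1`).
#'
#' @param chain Protein chain for the catalytic residues (default "A").
#' @param substrate_C,substrate_O References for the substrate carbonyl carbon
#'   and oxygen.
#' @return Tibble of criteria: `name`, `kind`, `a1`..`a4`, `min`, `max`.
#' @export
default_prereactive_criteria <- function(chain = "A",
                                         substrate_C = "L:900:C1",
                                         substrate_O = "L:900:O1") {
  ser_og <- paste0(chain, ":241:OG")
  tibble::tibble(
    name = c("attack_distance", "attack_angle", "oxyanion_hb1", "oxyanion_hb2"),
    kind = c("distance", "angle", "distance", "distance"),
    a1 = c(ser_og, ser_og, paste0(chain, ":239:N"), paste0(chain, ":240:N")),
    a2 = c(substrate_C, substrate_C, substrate_O, substrate_O),
    a3 = c(NA, substrate_O, NA, NA),
    a4 = NA_character_,
    min = c(NA, 75, NA, NA),
    max = c(4.0, 115, 3.5, 3.5)
  )
}

# Measure one criterion over all frames -> numeric vector.
.measure_criterion <- function(trajectory, crit) {
  refs <- c(crit$a1, crit$a2, crit$a3, crit$a4)
  refs <- refs[!is.na(refs)]
  idx <- vapply(refs, function(r) resolve_atom_ref(trajectory, r), integer(1))
  switch(crit$kind,
    distance = {
      if (length(idx) != 2) stop("distance criterion needs 2 atoms", call. = FALSE)
      sqrt(rowSums((atom_series(trajectory, idx[1]) -
                      atom_series(trajectory, idx[2]))^2))
    },
    angle = {
      if (length(idx) != 3) stop("angle criterion needs 3 atoms", call. = FALSE)
      A <- atom_series(trajectory, idx[1])
      B <- atom_series(trajectory, idx[2])
      C <- atom_series(trajectory, idx[3])
      u <- A - B
      v <- C - B
      cs <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
      acos(pmin(1, pmax(-1, cs))) * 180 / pi
    },
    dihedral = {
      if (length(idx) != 4) stop("dihedral criterion needs 4 atoms", call. = FALSE)
      dihedral_series(trajectory, idx)
    },
    stop("unknown criterion kind: ", crit$kind, call. = FALSE)
  )
}

#' Evaluate pre-reactive criteria over every frame
#'
#' Each criterion passes when its measured value lies within its (possibly
#' one-sided) bounds, inclusive. Criteria combine with `all` (default) or
#' `any`.
#'
#' @param trajectory An [md_trajectory()].
#' @param criteria Criterion tibble as from [default_prereactive_criteria()].
#'   An open bound is `NA`.
#' @param combine `"all"` or `"any"`.
#' @return List with `flags` (tibble: frame, time_ns, prereactive) and
#'   `report` (long tibble: frame, criterion, value, pass).
#' @export
evaluate_prereactive <- function(trajectory, criteria, combine = c("all", "any")) {
  combine <- match.arg(combine)
  if (nrow(criteria) == 0L) stop("criteria must be non-empty", call. = FALSE)
  nf <- n_frames(trajectory)
  vals <- lapply(seq_len(nrow(criteria)), function(i) {
    crit <- criteria[i, ]
    v <- .measure_criterion(trajectory, crit)
    lo <- if (is.na(crit$min)) -Inf else crit$min
    hi <- if (is.na(crit$max)) Inf else crit$max
    tibble::tibble(frame = seq_len(nf), criterion = crit$name,
                   value = v, pass = v >= lo & v <= hi)
  })
  report <- dplyr::bind_rows(vals)
  pass_mat <- vapply(vals, function(v) v$pass, logical(nf))
  if (nf == 1L) pass_mat <- matrix(pass_mat, nrow = 1)
  flag <- if (combine == "all") {
    rowSums(!pass_mat) == 0L
  } else {
    rowSums(pass_mat) > 0L
  }
  list(
    flags = tibble::tibble(frame = seq_len(nf), time_ns = trajectory$times,
                           prereactive = flag),
    report = report
  )
}

#' Polar-plot records for pre-reactive frames
#'
#' One record per pre-reactive frame whose region label is MA, T or AB; the
#' radius is the matching pocket distance (dMA, dT or dAB). These are the
#' coordinates of the phi-versus-pocket-distance polar plots.
#'
#' @param labelled Tibble with aligned columns `label`, `dMA`, `dAB`, `dT`
#'   (from [label_trajectory()]).
#' @param paddle Tibble from [compute_paddle_angles()] (columns `phiF`,
#'   `phiW`), frame-aligned with `labelled`.
#' @param prereactive Logical vector of pre-reactive flags, frame-aligned.
#' @return Tibble with columns `frame`, `region`, `radius`, `phiF`, `phiW`.
#' @export
build_polar_records <- function(labelled, paddle, prereactive) {
  n <- nrow(labelled)
  if (nrow(paddle) != n || length(prereactive) != n) {
    stop("length mismatch: labels ", n, ", paddle ", nrow(paddle),
         ", flags ", length(prereactive), call. = FALSE)
  }
  lab <- as.character(labelled$label)
  keep <- prereactive & lab %in% c("MA", "T", "AB")
  radius <- ifelse(lab == "MA", labelled$dMA,
                   ifelse(lab == "T", labelled$dT, labelled$dAB))
  tibble::tibble(
    frame = seq_len(n)[keep],
    region = factor(lab[keep], levels = c("MA", "T", "AB")),
    radius = radius[keep],
    phiF = paddle$phiF[keep],
    phiW = paddle$phiW[keep]
  )
}

# Shared dwell-qualified transition counter. Drops `transit` states entirely
# (they neither qualify nor reset), RLE-compresses the remaining two-state
# stream, and counts changes between consecutive dwell-qualified runs.
# `breaker` states (if any) reset the automaton when dwell-qualified.
.count_transitions <- function(states, from_to, min_dwell,
                               transit = character(), breaker = character()) {
  stopifnot(min_dwell >= 1)
  counts <- stats::setNames(integer(length(from_to)), from_to)
  s <- as.character(states)
  s <- s[!s %in% transit]
  if (length(s) == 0L) return(counts)
  r <- rle(s)
  current <- NA_character_
  for (i in seq_along(r$values)) {
    v <- r$values[i]
    if (v %in% breaker) {
      if (r$lengths[i] >= min_dwell) current <- NA_character_
      next
    }
    if (r$lengths[i] < min_dwell) next
    if (!is.na(current) && v != current) {
      key <- paste0(current, "->", v)
      if (key %in% names(counts)) counts[key] <- counts[key] + 1L
    }
    current <- v
  }
  counts
}

#' Count MA-gate opening/closing events
#'
#' An event requires at least `min_dwell` (merged) frames in the destination
#' bin; INTERMEDIATE frames neither qualify nor reset a pending transition.
#'
#' @param gate Factor/character vector of gate states (CLOSED / OPEN /
#'   INTERMEDIATE).
#' @param min_dwell Minimum frames in the destination state (default 10).
#' @return Tibble with columns `transition` (`"CLOSED->OPEN"`,
#'   `"OPEN->CLOSED"`) and `n`.
#' @export
count_gate_transitions <- function(gate, min_dwell = 10L) {
  counts <- .count_transitions(gate, c("CLOSED->OPEN", "OPEN->CLOSED"),
                               min_dwell, transit = "INTERMEDIATE")
  tibble::tibble(transition = names(counts), n = unname(counts))
}
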