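# Elementary geometric operations shared by every analysis stage.
# Units: distances in angstrom, angles in degrees, everywhere. Radians are an
# internal detail and never cross a function boundary.

#' Standard atomic masses
#'
#' Masses (amu, IUPAC 2021 standard atomic weights) for the elements that occur
#' in protein/lipid topologies. Used to default per-atom masses from the PDB
#' element column; a topology may override any atom's mass explicitly.
#'
#' @format Named numeric vector, names are upper-case element symbols.
#' @keywords internal
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  NA_ = 22.990, MG = 24.305, P = 30.974, S = 32.06, CL = 35.45, K = 39.098,
  CA = 40.078, FE = 55.845, ZN = 65.38, BR = 79.904, I = 126.904, SE = 78.971
)

#' Look up atomic masses by element symbol
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of masses in amu.
#' @examples
#' element_mass(c("C", "N", "O"))
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA_"
  m <- .atomic_masses[key]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("no standard atomic mass for element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(m)
}

#' Mass-weighted centre of mass
#'
#' @param pos Numeric matrix, one atom per row, columns x/y/z (angstrom).
#' @param mass Numeric vector of per-atom masses in amu; all > 0.
#' @return Length-3 numeric vector (angstrom).
#' @examples
#' centre_of_mass(rbind(c(0, 0, 0), c(4, 0, 0)), mass = c(1, 3))
#' @export
centre_of_mass <- function(pos, mass) {
  pos <- as.matrix(pos)
  if (nrow(pos) == 0L) stop("empty selection", call. = FALSE)
  if (length(mass) != nrow(pos)) {
    stop("mass vector length (", length(mass), ") does not match atom count (",
         nrow(pos), ")", call. = FALSE)
  }
  if (anyNA(mass)) {
    stop("missing mass for atom(s) ", paste(which(is.na(mass)), collapse = ", "),
         call. = FALSE)
  }
  if (any(mass <= 0)) stop("non-positive atomic mass", call. = FALSE)
  as.numeric(colSums(pos * mass) / sum(mass))
}

#' Dihedral (torsion) angle of four points
#'
#' IUPAC sign convention: looking from `p2` towards `p3`, a clockwise rotation
#' of the far bond is positive. Cis (eclipsed) is 0 degrees, trans (anti) is
#' 180 degrees. Range is (-180, 180].
#'
#' @param p1,p2,p3,p4 Length-3 numeric vectors (angstrom).
#' @return Angle in degrees.
#' @examples
#' dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)) # cis, 0
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-14 || sum(n2^2) < 1e-14) {
    stop("undefined torsion: collinear points", call. = FALSE)
  }
  b2u <- b2 / sqrt(sum(b2^2))
  m1 <- .cross3(n1, b2u)
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Vectorised dihedral over aligned coordinate matrices (one row per frame).
# Returns degrees in (-180, 180]; rows with a collinear triple give NA.
.dihedral_rows <- function(P1, P2, P3, P4) {
  B1 <- P2 - P1
  B2 <- P3 - P2
  B3 <- P4 - P3
  crossm <- function(A, B) {
    cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
          A[, 3] * B[, 1] - A[, 1] * B[, 3],
          A[, 1] * B[, 2] - A[, 2] * B[, 1])
  }
  N1 <- crossm(B1, B2)
  N2 <- crossm(B2, B3)
  nb2 <- sqrt(rowSums(B2^2))
  B2u <- B2 / nb2
  M1 <- crossm(N1, B2u)
  y <- rowSums(M1 * N2)
  x <- rowSums(N1 * N2)
  ang <- -atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  bad <- rowSums(N1^2) < 1e-14 | rowSums(N2^2) < 1e-14
  ang[bad] <- NA_real_
  ang
}

#' Planar angle at a vertex
#'
#' Angle a-b-c at vertex `b`, in degrees within 0..180.
#'
#' @param a,b,c Length-3 numeric vectors.
#' @return Angle in degrees.
#' @keywords internal
vertex_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}

#' End-to-end and contour length of an ordered chain
#'
#' `end_to_end_distance()` is the distance between the first and last atom of
#' the declared chain order; `contour_length()` sums consecutive bond-vector
#' norms. For any chain `end_to_end <= contour`.
#'
#' @param pos Numeric matrix of chain atom coordinates in chain order (>= 2
#'   rows).
#' @return Length in angstrom.
#' @export
end_to_end_distance <- function(pos) {
  pos <- as.matrix(pos)
  if (nrow(pos) < 2L) stop("chain needs at least 2 atoms", call. = FALSE)
  sqrt(sum((pos[nrow(pos), ] - pos[1L, ])^2))
}

#' @rdname end_to_end_distance
#' @export
contour_length <- function(pos) {
  pos <- as.matrix(pos)
  if (nrow(pos) < 2L) stop("chain needs at least 2 atoms", call. = FALSE)
  d <- diff(pos)
  sum(sqrt(rowSums(d^2)))
}

#' Minimum distance from a probe group to a set of residue groups
#'
#' Two modes mirror the two distance definitions in common use for
#' channel-occupancy analysis. `com_per_residue` (default) takes the minimum
#' over residues of the distance between the probe centre of mass and each
#' residue's centre of mass — the prose definition of the d-MA/d-AB/d-T
#' distances. `atom_pair` takes the minimum over all probe-atom x residue-atom
#' pairs, the quantity computed by g_mindist-style tools. The two typically
#' differ by 1-3 angstrom for real side chains.
#'
#' @param probe_pos Matrix of probe atom coordinates.
#' @param probe_mass Masses for the probe atoms.
#' @param residues List of residue groups, each a list with elements `pos`
#'   (matrix) and `mass` (vector).
#' @param mode `"com_per_residue"` or `"atom_pair"`.
#' @return Minimum distance in angstrom (>= 0).
#' @export
group_min_distance <- function(probe_pos, probe_mass, residues,
                               mode = c("com_per_residue", "atom_pair")) {
  mode <- match.arg(mode)
  if (length(residues) == 0L) stop("empty residue list", call. = FALSE)
  probe_pos <- as.matrix(probe_pos)
  if (nrow(probe_pos) == 0L) stop("empty selection", call. = FALSE)
  if (mode == "com_per_residue") {
    pc <- centre_of_mass(probe_pos, probe_mass)
    d <- vapply(residues, function(r) {
      rc <- centre_of_mass(as.matrix(r$pos), r$mass)
      sqrt(sum((pc - rc)^2))
    }, numeric(1))
    min(d)
  } else {
    d <- vapply(residues, function(r) {
      rp <- as.matrix(r$pos)
      # all pairwise distances probe x residue
      dx <- outer(probe_pos[, 1], rp[, 1], "-")
      dy <- outer(probe_pos[, 2], rp[, 2], "-")
      dz <- outer(probe_pos[, 3], rp[, 3], "-")
      sqrt(min(dx^2 + dy^2 + dz^2))
    }, numeric(1))
    min(d)
  }
}

# NeRF-style internal-coordinate placement: position atom D given A-B-C, the
# C-D bond length (angstrom), the B-C-D angle and the A-B-C-D torsion
# (degrees, IUPAC sign). Inverse of dihedral_angle by construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("cannot place atom: collinear reference", call. = FALSE)
  n <- n / nn
  m <- .cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
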