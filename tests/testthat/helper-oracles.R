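# Independent oracles used across the suite. Each deliberately re-derives its
# quantity by a different route than the package implementation.

# Dihedral via explicit rotation matrix: rotate so the central bond lies on
# +z, then read the angle between the projected outer bonds in the xy plane.
oracle_dihedral <- function(p1, p2, p3, p4) {
  bz <- p3 - p2
  bz <- bz / sqrt(sum(bz^2))
  a <- if (abs(bz[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * bz) * bz
  u <- u / sqrt(sum(u^2))
  v <- c(bz[2] * u[3] - bz[3] * u[2],
         bz[3] * u[1] - bz[1] * u[3],
         bz[1] * u[2] - bz[2] * u[1])
  R <- rbind(u, v, bz)
  q1 <- as.numeric(R %*% (p1 - p2))
  q4 <- as.numeric(R %*% (p4 - p3))
  d <- (atan2(q4[2], q4[1]) - atan2(q1[2], q1[1])) * 180 / pi
  d <- d %% 360
  if (d > 180) d <- d - 360
  d
}

# Literal transcription of the occupancy rule chain, scalar.
oracle_classify <- function(dMA, dAB, dT, cMA = 6, cAB = 6, cT = 5, nb = 12) {
  if (min(dMA, dAB, dT) > nb) return("NB")
  if (dMA < cMA && dAB > cAB) return("MA")
  if (dMA > cMA && dAB < cAB) return("AB")
  if (dT < cT) return("T")
  "UNASSIGNED"
}

# Maximal runs of a character vector as a data.frame (value, len), by
# explicit frame scan (no rle()).
.scan_runs <- function(x) {
  n <- length(x)
  if (n == 0L) return(data.frame(value = character(), len = integer()))
  vals <- character(0)
  lens <- integer(0)
  cur <- x[1]
  len <- 1L
  for (i in seq_len(n)[-1]) {
    if (x[i] == cur) {
      len <- len + 1L
    } else {
      vals <- c(vals, cur); lens <- c(lens, len)
      cur <- x[i]; len <- 1L
    }
  }
  data.frame(value = c(vals, cur), len = c(lens, len),
             stringsAsFactors = FALSE)
}

# Transition-automaton oracle: drop transit frames, scan maximal runs, count
# changes between dwell-qualified runs; dwell-qualified breaker runs reset.
oracle_transitions <- function(labels, pairs, min_dwell,
                               transit = character(), breaker = character()) {
  counts <- stats::setNames(integer(length(pairs)), pairs)
  x <- as.character(labels)
  x <- x[!x %in% transit]
  runs <- .scan_runs(x)
  last <- NA_character_
  for (i in seq_len(nrow(runs))) {
    v <- runs$value[i]
    if (v %in% breaker) {
      if (runs$len[i] >= min_dwell) last <- NA_character_
      next
    }
    if (runs$len[i] < min_dwell) next
    if (!is.na(last) && v != last) {
      key <- paste0(last, "->", v)
      if (key %in% names(counts)) counts[key] <- counts[key] + 1L
    }
    last <- v
  }
  counts
}

# Random rigid transform (rotation from QR of a Gaussian matrix + shift).
random_rigid <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = stats::rnorm(3, 0, 10))
}

apply_rigid <- function(pos, tr) {
  sweep(as.matrix(pos) %*% t(tr$R), 2, -tr$t, "-")
}

# Apply a rigid transform to every frame of a trajectory.
transform_trajectory <- function(trajectory, tr) {
  nf <- n_frames(trajectory)
  na <- n_atoms(trajectory)
  xyz <- trajectory$xyz
  for (f in seq_len(nf)) {
    pos <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    xyz[f, ] <- as.vector(t(apply_rigid(pos, tr)))
  }
  md_trajectory(trajectory$topology, xyz, times = trajectory$times,
                frame_interval = trajectory$frame_interval)
}

# Ideal all-trans zig-zag chain coordinates (n atoms, unit-ish geometry).
zigzag_chain <- function(n, bond = 1.53, angle = 111) {
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- c(0, 0, 0)
  pos[2, ] <- c(bond, 0, 0)
  ang <- angle * pi / 180
  pos[3, ] <- pos[2, ] + bond * c(-cos(ang), sin(ang), 0)
  if (n >= 4) {
    for (i in 4:n) {
      pos[i, ] <- lipidgate:::place_atom(pos[i - 3, ], pos[i - 2, ],
                                         pos[i - 1, ], bond, angle, 180)
    }
  }
  pos
}

# Chain with a prescribed torsion sequence (length n - 3).
chain_with_torsions <- function(om, bond = 1.53, angle = 111) {
  n <- length(om) + 3L
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- c(0, 0, 0)
  pos[2, ] <- c(bond, 0, 0)
  ang <- angle * pi / 180
  pos[3, ] <- pos[2, ] + bond * c(-cos(ang), sin(ang), 0)
  for (i in seq_along(om)) {
    pos[i + 3L, ] <- lipidgate:::place_atom(pos[i, ], pos[i + 1L, ],
                                            pos[i + 2L, ], bond, angle, om[i])
  }
  pos
}

# Wrap a coordinate matrix as a single-frame trajectory of carbon atoms.
coords_as_trajectory <- function(pos, names = paste0("C", seq_len(nrow(pos)))) {
  topo <- tibble::tibble(
    serial = seq_len(nrow(pos)), name = names, resname = "SUB",
    resid = 1L, chain = "L", element = "C")
  md_trajectory(topo, matrix(as.vector(t(pos)), nrow = 1))
}
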