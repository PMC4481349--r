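# Trajectory container and atom selection.
#
# A trajectory couples a topology (one row per atom) with a frames-by-3N
# coordinate matrix in the xyz layout used across structural bioinformatics
# (x1, y1, z1, x2, ...). That layout keeps per-frame group operations
# vectorisable over tens of thousands of frames without copying.

#' Construct a trajectory object
#'
#' @param topology Data frame with one row per atom and columns `serial`
#'   (positive integer), `name` (atom name), `resname` (3-letter residue name),
#'   `resid` (integer residue id, 1-based as in the source PDB), `chain`
#'   (single character), `element` (element symbol). A `mass` column (amu) is
#'   optional; missing masses default from `element` via [element_mass()].
#' @param xyz Numeric matrix, `n_frames` rows by `3 * n_atoms` columns, in
#'   x1,y1,z1,x2,... order; all values finite (angstrom).
#' @param times Numeric vector of non-negative frame times in ns, strictly
#'   increasing. Defaults to `0, dt, 2 dt, ...` with `dt = frame_interval`.
#' @param frame_interval Time between stored frames in ns. Default 0.01 ns
#'   (coordinates saved every 10 ps).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, xyz, times = NULL, frame_interval = 0.01) {
  topology <- tibble::as_tibble(topology)
  needed <- c("serial", "name", "resname", "resid", "chain", "element")
  missing_cols <- setdiff(needed, names(topology))
  if (length(missing_cols) > 0) {
    stop("topology lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"mass" %in% names(topology)) {
    topology$mass <- element_mass(topology$element)
  } else if (anyNA(topology$mass)) {
    idx <- is.na(topology$mass)
    topology$mass[idx] <- element_mass(topology$element[idx])
  }
  if (any(topology$mass <= 0)) stop("all atomic masses must be > 0", call. = FALSE)
  key <- paste(topology$chain, topology$resid, topology$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resid, name) in topology: ",
         key[anyDuplicated(key)], call. = FALSE)
  }
  xyz <- as.matrix(xyz)
  n_atoms <- nrow(topology)
  if (ncol(xyz) != 3L * n_atoms) {
    stop("xyz has ", ncol(xyz), " columns; expected 3 * ", n_atoms, call. = FALSE)
  }
  if (nrow(xyz) > 0 && !all(is.finite(xyz))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (is.null(times)) times <- seq_len(nrow(xyz)) * frame_interval - frame_interval
  if (length(times) != nrow(xyz)) {
    stop("times length does not match frame count", call. = FALSE)
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  structure(
    list(topology = topology, xyz = xyz, times = as.numeric(times),
         frame_interval = frame_interval),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", n_frames(x), " frames x ", n_atoms(x), " atoms",
      if (n_frames(x) > 0) {
        sprintf(" | t = %.4g..%.4g ns (dt %.4g ns)",
                min(x$times), max(x$times), x$frame_interval)
      } else "",
      "\n", sep = "")
  cat("chains:", paste(unique(x$topology$chain), collapse = " "), "\n")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param trajectory An `md_trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(trajectory) nrow(trajectory$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(trajectory) nrow(trajectory$topology)

#' Select atom indices by topology predicates
#'
#' Predicates combine with AND; a `NULL` predicate matches everything. Indices
#' are returned in topology order and are duplicate-free.
#'
#' @param trajectory An `md_trajectory`.
#' @param chain,resid,resname,name Optional vectors restricting the selection.
#' @return Integer vector of atom indices into the topology.
#' @export
select_atoms <- function(trajectory, chain = NULL, resid = NULL,
                         resname = NULL, name = NULL) {
  top <- trajectory$topology
  keep <- rep(TRUE, nrow(top))
  if (!is.null(chain)) keep <- keep & top$chain %in% chain
  if (!is.null(resid)) keep <- keep & top$resid %in% resid
  if (!is.null(resname)) keep <- keep & top$resname %in% resname
  if (!is.null(name)) keep <- keep & top$name %in% name
  which(keep)
}

# Resolve a "chain:resid:atomname" reference to a single atom index.
resolve_atom_ref <- function(trajectory, ref) {
  parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) {
    stop("atom reference must be 'chain:resid:atomname', got '", ref, "'",
         call. = FALSE)
  }
  idx <- select_atoms(trajectory, chain = parts[1],
                      resid = as.integer(parts[2]), name = parts[3])
  if (length(idx) == 0L) {
    stop("cannot resolve atom '", ref, "' in topology", call. = FALSE)
  }
  idx[1]
}

# Resolve a residue given chain + resid (+ optional resname check); errors name
# the chain/residue.
resolve_residue <- function(trajectory, chain, resid, resname = NULL) {
  idx <- select_atoms(trajectory, chain = chain, resid = resid)
  if (length(idx) == 0L) {
    stop("cannot resolve residue ", chain, ":", resid,
         if (!is.null(resname)) paste0(" (", resname, ")"), " in topology",
         call. = FALSE)
  }
  if (!is.null(resname)) {
    found <- unique(trajectory$topology$resname[idx])
    if (!resname %in% found) {
      stop("residue ", chain, ":", resid, " is ", paste(found, collapse = "/"),
           ", expected ", resname, call. = FALSE)
    }
  }
  idx
}

#' Coordinates of one frame
#'
#' @param trajectory An `md_trajectory`.
#' @param frame Frame number (1-based).
#' @param atoms Optional atom indices (default all).
#' @return Numeric matrix, atoms by 3.
#' @export
frame_coords <- function(trajectory, frame, atoms = NULL) {
  if (frame < 1 || frame > n_frames(trajectory)) {
    stop("frame ", frame, " out of range", call. = FALSE)
  }
  if (is.null(atoms)) atoms <- seq_len(n_atoms(trajectory))
  cols <- rbind(3 * (atoms - 1) + 1, 3 * (atoms - 1) + 2, 3 * atoms)
  matrix(trajectory$xyz[frame, as.vector(cols)], ncol = 3, byrow = TRUE)
}

# Per-frame coordinates of a single atom: n_frames x 3 matrix.
atom_series <- function(trajectory, atom) {
  j <- 3 * (atom - 1)
  trajectory$xyz[, c(j + 1, j + 2, j + 3), drop = FALSE]
}

# Per-frame centre of mass of an atom group: n_frames x 3 matrix.
com_series <- function(trajectory, atoms) {
  if (length(atoms) == 0L) stop("empty selection", call. = FALSE)
  w <- trajectory$topology$mass[atoms]
  w <- w / sum(w)
  X <- trajectory$xyz[, 3 * (atoms - 1) + 1, drop = FALSE] %*% w
  Y <- trajectory$xyz[, 3 * (atoms - 1) + 2, drop = FALSE] %*% w
  Z <- trajectory$xyz[, 3 * atoms, drop = FALSE] %*% w
  cbind(X, Y, Z)
}

# Per-frame dihedral (degrees) over four atom indices: length n_frames.
dihedral_series <- function(trajectory, atoms4) {
  stopifnot(length(atoms4) == 4)
  .dihedral_rows(atom_series(trajectory, atoms4[1]),
                 atom_series(trajectory, atoms4[2]),
                 atom_series(trajectory, atoms4[3]),
                 atom_series(trajectory, atoms4[4]))
}

#' Centre of mass of a selection in one frame
#'
#' @inheritParams frame_coords
#' @param atoms Atom indices (non-empty).
#' @return Length-3 numeric vector (angstrom).
#' @export
selection_com <- function(trajectory, frame, atoms) {
  if (length(atoms) == 0L) stop("empty selection", call. = FALSE)
  centre_of_mass(frame_coords(trajectory, frame, atoms),
                 trajectory$topology$mass[atoms])
}
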