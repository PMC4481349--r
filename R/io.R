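# PDB reading/writing. Reading goes through bio3d (multi-model aware); writing
# multi-model PDB is done directly (fixed-width records) because single-model
# writers cannot express a trajectory. Coordinates are taken as written in the
# file (angstrom, no re-imaging); periodic-boundary unwrapping is a
# preprocessing requirement, not handled here.

#' Read a (multi-model) PDB file as a trajectory
#'
#' Each MODEL block becomes one frame; a single-model PDB yields a one-frame
#' trajectory. Atoms are identified by (chain, resid, atom name). Frame times
#' are `0, dt, 2 dt, ...`.
#'
#' @param path Path to a PDB file (topology + coordinates, possibly
#'   multi-model).
#' @param frame_interval Time between models in ns (default 0.01, i.e. 10 ps).
#' @return An [md_trajectory()].
#' @export
read_trajectory <- function(path, frame_interval = 0.01) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  .check_model_sizes(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom
  element <- trimws(at$elesy)
  if (any(element == "" | is.na(element))) {
    # fall back to the first alphabetic character of the atom name
    guess <- sub("^[0-9]*", "", trimws(at$elety))
    guess <- substr(guess, 1, 1)
    element <- ifelse(element == "" | is.na(element), guess, element)
  }
  topology <- tibble::tibble(
    serial = at$eleno,
    name = trimws(at$elety),
    resname = trimws(at$resid),
    resid = at$resno,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    element = element
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  md_trajectory(topology, unclass(xyz), frame_interval = frame_interval)
}

# Validate that every MODEL block carries the same number of ATOM/HETATM
# records; errors name the first offending model.
.check_model_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(grepl("^MODEL", lines))
  if (length(model_starts) <= 1) return(invisible(TRUE))
  model_ends <- which(rec == "ENDMDL")
  if (length(model_ends) < length(model_starts)) {
    stop("trajectory PDB: model ", length(model_starts),
         " is truncated (missing ENDMDL)", call. = FALSE)
  }
  counts <- mapply(function(s, e) sum(rec[s:e] %in% c("ATOM  ", "HETATM")),
                   model_starts, model_ends)
  if (length(unique(counts)) > 1) {
    bad <- which(counts != counts[1])[1]
    stop("trajectory PDB: model ", bad, " has ", counts[bad],
         " atoms; expected ", counts[1], call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written with 3 decimal places (the PDB fixed-point format),
#' so a read-back reproduces them to 1e-3 angstrom.
#'
#' @param trajectory An [md_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(trajectory, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory ", dir,
                             " does not exist", call. = FALSE)
  top <- trajectory$topology
  name4 <- ifelse(nchar(top$name) < 4, paste0(" ", top$name), top$name)
  prefix <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    ",
                    top$serial, name4, top$resname, top$chain, top$resid)
  suffix <- sprintf("  1.00  0.00          %2s", top$element)
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(trajectory)
  for (f in seq_len(nf)) {
    pos <- frame_coords(trajectory, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(paste0(prefix,
                      sprintf("%8.3f%8.3f%8.3f", pos[, 1], pos[, 2], pos[, 3]),
                      suffix), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
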