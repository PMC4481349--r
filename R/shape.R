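# Acyl-chain conformational taxonomy (Applegate-Glomset): per-frame torsion
# profiles along the chain, coarse shape descriptors, and classification into
# elongated / hooked / curved with fine classes Ex, Uex, J, J', U, Hx, Hx-A/B.
# Saturated chains (no C=C to pin a torsion pattern) use the end-to-end-length
# fallback policy instead.

#' Torsion profile of an ordered chain in one frame
#'
#' One torsion omega_i per sliding 4-atom window (atoms i..i+3) along the
#' declared head-to-tail chain path; profile length is `n_atoms - 3`. A window whose
#' inner triple is collinear yields `NA` and is flagged.
#'
#' @param trajectory An [md_trajectory()].
#' @param chain_atoms Integer atom indices, ordered head to tail (>= 4).
#' @param frame Frame number.
#' @return Tibble with columns `window`, `omega` (degrees, (-180, 180]),
#'   `missing` (logical).
#' @export
compute_torsion_profile <- function(trajectory, chain_atoms, frame) {
  if (length(chain_atoms) < 4L) stop("chain needs >= 4 atoms", call. = FALSE)
  pos <- frame_coords(trajectory, frame, chain_atoms)
  torsion_profile_from_coords(pos)
}

#' @rdname compute_torsion_profile
#' @param pos Matrix of ordered chain coordinates (used directly instead of a
#'   trajectory + frame).
#' @export
torsion_profile_from_coords <- function(pos) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (n < 4L) stop("chain needs >= 4 atoms", call. = FALSE)
  idx <- seq_len(n - 3L)
  om <- .dihedral_rows(pos[idx, , drop = FALSE],
                       pos[idx + 1L, , drop = FALSE],
                       pos[idx + 2L, , drop = FALSE],
                       pos[idx + 3L, , drop = FALSE])
  tibble::tibble(window = idx, omega = om, missing = is.na(om))
}

#' Coarse geometric descriptors of a chain conformation
#'
#' * `r`: end-to-end / contour-length ratio, in 0..1;
#' * `max_bend_deg`: largest angle between direction vectors of successive
#'   non-overlapping segments of `segment_len` atoms;
#' * `bend_position`: fractional position (0 head, 1 tail) of that largest
#'   bend along the chain.
#'
#' @param pos Matrix of ordered chain coordinates (>= `2 * segment_len` rows).
#' @param segment_len Atoms per direction segment (default 4).
#' @return Tibble with one row: `r`, `max_bend_deg`, `bend_position`.
#' @export
compute_shape_descriptors <- function(pos, segment_len = 4L) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (n < 2L * segment_len) {
    stop("chain too short: need >= ", 2L * segment_len, " atoms", call. = FALSE)
  }
  r <- end_to_end_distance(pos) / contour_length(pos)
  n_seg <- n %/% segment_len
  starts <- (seq_len(n_seg) - 1L) * segment_len + 1L
  ends <- starts + segment_len - 1L
  dirs <- pos[ends, , drop = FALSE] - pos[starts, , drop = FALSE]
  nd <- sqrt(rowSums(dirs^2))
  dirs <- dirs / nd
  if (n_seg < 2L) {
    bend <- 0
    bp <- 0.5
  } else {
    cs <- rowSums(dirs[-n_seg, , drop = FALSE] * dirs[-1L, , drop = FALSE])
    ang <- acos(pmin(1, pmax(-1, cs))) * 180 / pi
    k <- which.max(ang)
    bend <- ang[k]
    # joint between segments k and k+1 sits at the boundary atom
    bp <- (ends[k] - 1) / (n - 1)
  }
  tibble::tibble(r = min(1, r), max_bend_deg = bend, bend_position = bp)
}

.fine_to_coarse <- c(Ex = "elongated", Uex = "elongated",
                     J = "hooked", Jp = "hooked",
                     U = "curved", Hx = "curved", HxA = "curved", HxB = "curved",
                     `NA` = NA_character_)

#' Map fine Applegate-Glomset classes to coarse shapes
#'
#' Fixed total map: Ex/Uex -> elongated; J/J' -> hooked; U/Hx/Hx-A/Hx-B ->
#' curved.
#'
#' @param fine Character vector of fine class names.
#' @return Character vector of coarse classes.
#' @export
fine_to_coarse <- function(fine) {
  out <- .fine_to_coarse[as.character(fine)]
  unname(out)
}

#' Classify a chain conformation
#'
#' Two policies:
#'
#' * `"torsion_pattern"` (unsaturated chains): each window is a torsion state —
#'   trans if the absolute torsion is at least `trans_min` (default 150
#'   degrees), otherwise non-trans (gauche between 30 and 90, cis below 30).
#'   Contiguous non-trans blocks drive the fine class: none -> Ex; a single
#'   isolated non-trans window -> Uex; one block wholly inside a terminal
#'   third -> J (block torsion sum > 0) or J' (< 0); one longer central
#'   block -> U; two or more blocks -> Hx (both halves), Hx-A (first half
#'   only) or Hx-B (second half only).
#' * `"end_to_end"` (saturated chains, e.g. the palmitoyl chain of PEA, which
#'   has no double bonds to anchor a torsion pattern): elongated if the ratio
#'   is at least `r_elongated`; hooked if below and the maximal bend sits in a
#'   terminal region (`bend_position` at most `bend_terminal` or at least
#'   `1 - bend_terminal`); curved otherwise. Fine class is `NA`.
#'
#' @param profile Torsion profile tibble (columns `omega`, `missing`);
#'   required for `torsion_pattern`.
#' @param descriptors Descriptor tibble from [compute_shape_descriptors()];
#'   required for `end_to_end`.
#' @param policy `"torsion_pattern"` or `"end_to_end"`.
#' @param trans_min Trans threshold on `|omega|` in degrees (default 150).
#' @param r_elongated End-to-end ratio threshold for elongated (default 0.75).
#' @param bend_terminal Fractional chain position bounding the terminal
#'   regions (default 0.35).
#' @param max_missing_frac Refuse classification when more than this fraction
#'   of windows is missing (default 0.2).
#' @return Tibble with one row: `fine`, `coarse`.
#' @export
classify_shape <- function(profile = NULL, descriptors = NULL,
                           policy = c("torsion_pattern", "end_to_end"),
                           trans_min = 150, r_elongated = 0.75,
                           bend_terminal = 0.35, max_missing_frac = 0.2) {
  policy <- match.arg(policy)
  if (policy == "end_to_end") {
    if (is.null(descriptors)) stop("end_to_end policy needs descriptors",
                                   call. = FALSE)
    r <- descriptors$r[1]
    bp <- descriptors$bend_position[1]
    coarse <- if (r >= r_elongated) {
      "elongated"
    } else if (bp <= bend_terminal || bp >= 1 - bend_terminal) {
      "hooked"
    } else {
      "curved"
    }
    return(tibble::tibble(fine = "NA", coarse = coarse))
  }
  if (is.null(profile)) stop("torsion_pattern policy needs a profile",
                             call. = FALSE)
  fine <- .fine_from_omegas(profile$omega, trans_min, max_missing_frac)
  if (is.na(fine)) {
    nw <- length(profile$omega)
    stop("classification refused: ", sum(is.na(profile$omega)), " of ", nw,
         " torsions missing (> ", round(100 * max_missing_frac), "%)",
         call. = FALSE)
  }
  tibble::tibble(fine = fine, coarse = unname(.fine_to_coarse[fine]))
}

# Core torsion-pattern rule on one omega vector; NA when refused (too many
# missing windows). Missing windows are treated as trans: they cannot witness
# a bend.
.fine_from_omegas <- function(om, trans_min, max_missing_frac) {
  nw <- length(om)
  if (sum(is.na(om)) > max_missing_frac * nw) return(NA_character_)
  nontrans <- !is.na(om) & abs(om) < trans_min
  if (!any(nontrans)) return("Ex")
  r <- rle(nontrans)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bs <- starts[r$values]
  be <- ends[r$values]
  if (length(bs) == 1L) {
    if (be - bs == 0L) return("Uex")
    # terminal third in window positions (1-based)
    if (be <= nw / 3 || bs >= nw - nw / 3 + 1) {
      return(if (sum(om[bs:be]) > 0) "J" else "Jp")
    }
    return("U")
  }
  mids <- (bs + be) / 2
  half <- (nw + 1) / 2
  if (all(mids < half)) return("HxA")
  if (all(mids > half)) return("HxB")
  "Hx"
}

#' Per-frame shape classification over a trajectory
#'
#' Applies [classify_shape()] frame-wise and tabulates class fractions over
#' the frames at or after `equilibration_cutoff_ns`. Frames whose
#' classification is refused (too many missing torsions) are counted in an
#' `unclassified` bin.
#'
#' @param trajectory An [md_trajectory()].
#' @param chain_atoms Ordered chain atom indices.
#' @param policy Classification policy, see [classify_shape()].
#' @param segment_len Segment length for descriptors (end_to_end policy).
#' @param equilibration_cutoff_ns Frames strictly before this time are
#'   excluded from the fractions (default 0).
#' @param ... Further threshold arguments passed to [classify_shape()].
#' @return List with `series` (tibble: frame, time_ns, fine, coarse) and
#'   `fractions` (tibble: coarse, n, fraction over equilibrated classified
#'   frames), plus `n_unclassified`.
#' @export
shape_time_series <- function(trajectory, chain_atoms,
                              policy = c("torsion_pattern", "end_to_end"),
                              segment_len = 4L, equilibration_cutoff_ns = 0,
                              ...) {
  policy <- match.arg(policy)
  nf <- n_frames(trajectory)
  if (nf == 0L) {
    return(list(
      series = tibble::tibble(frame = integer(), time_ns = numeric(),
                              fine = character(), coarse = character()),
      fractions = tibble::tibble(coarse = character(), n = integer(),
                                 fraction = numeric()),
      n_unclassified = 0L
    ))
  }
  dots <- list(...)
  arg <- function(nm, default) dots[[nm]] %||% default
  if (policy == "torsion_pattern") {
    # omega matrix: frames x windows, each window vectorised over frames
    n_chain <- length(chain_atoms)
    if (n_chain < 4L) stop("chain needs >= 4 atoms", call. = FALSE)
    series_list <- lapply(chain_atoms, function(a) atom_series(trajectory, a))
    om <- vapply(seq_len(n_chain - 3L), function(i) {
      .dihedral_rows(series_list[[i]], series_list[[i + 1L]],
                     series_list[[i + 2L]], series_list[[i + 3L]])
    }, numeric(nf))
    if (nf == 1L) om <- matrix(om, nrow = 1)
    trans_min <- arg("trans_min", 150)
    max_missing <- arg("max_missing_frac", 0.2)
    fine <- vapply(seq_len(nf), function(f) {
      .fine_from_omegas(om[f, ], trans_min, max_missing)
    }, character(1))
    coarse <- unname(.fine_to_coarse[fine])
    coarse[is.na(fine)] <- "unclassified"
    fine[is.na(fine)] <- NA_character_
  } else {
    fine <- character(nf)
    coarse <- character(nf)
    for (f in seq_len(nf)) {
      pos <- frame_coords(trajectory, f, chain_atoms)
      cls <- tryCatch(
        classify_shape(descriptors = compute_shape_descriptors(pos, segment_len),
                       policy = "end_to_end", ...),
        error = function(e) tibble::tibble(fine = NA_character_,
                                           coarse = "unclassified"))
      fine[f] <- cls$fine
      coarse[f] <- cls$coarse
    }
  }
  series <- tibble::tibble(frame = seq_len(nf), time_ns = trajectory$times,
                           fine = fine, coarse = coarse)
  eq <- series[series$time_ns >= equilibration_cutoff_ns, ]
  n_unclassified <- sum(eq$coarse == "unclassified")
  cl <- eq[eq$coarse != "unclassified", ]
  fractions <- tibble::tibble(coarse = c("elongated", "hooked", "curved")) |>
    dplyr::left_join(dplyr::count(cl, .data$coarse), by = "coarse") |>
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
                  fraction = if (nrow(cl) > 0) .data$n / nrow(cl) else 0)
  list(series = series, fractions = fractions, n_unclassified = n_unclassified)
}
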