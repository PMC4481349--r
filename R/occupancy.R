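# Pocket-occupancy classification: per-frame minimum distances from the
# substrate tail to the MA / AB / T residue groups, cutoff-rule region labels,
# and not-bound (NB) episode detection.

#' Default FAAH channel region definitions
#'
#' Residue groups and cutoffs for the membrane-access (MA) channel, the
#' acyl-chain-binding (AB) channel, and the MA/AB transition (T) region of
#' FAAH: MA = Asp403, Ile407, Arg486, Ile530 (cutoff 6 A); AB = Tyr335,
#' Glu373, Arg428, Phe527 (cutoff 6 A); T = Phe381, Phe432, Trp531 (cutoff
#' 5 A). The cutoffs reflect the ~16/17 A centre-to-centre separation of the
#' MA and AB channels: ~6 A for each channel and ~4/5 A of interface between
#' them.
#'
#' @param chain Chain identifier the residue ids refer to (default "A").
#' @return A named list of region definitions, each with `name`, `residues`
#'   (tibble of resid/resname) and `cutoff`.
#' @export
faah_region_definitions <- function(chain = "A") {
  def <- function(name, resid, resname, cutoff) {
    list(name = name,
         chain = chain,
         residues = tibble::tibble(resid = resid, resname = resname),
         cutoff = cutoff)
  }
  list(
    MA = def("MA", c(403L, 407L, 486L, 530L), c("ASP", "ILE", "ARG", "ILE"), 6.0),
    AB = def("AB", c(335L, 373L, 428L, 527L), c("TYR", "GLU", "ARG", "PHE"), 6.0),
    T  = def("T",  c(381L, 432L, 531L),       c("PHE", "PHE", "TRP"),        5.0)
  )
}

# Resolve a region definition into a list of per-residue atom-index vectors.
.resolve_region <- function(trajectory, region) {
  lapply(seq_len(nrow(region$residues)), function(i) {
    resolve_residue(trajectory, region$chain, region$residues$resid[i],
                    region$residues$resname[i])
  })
}

#' Per-frame distances from the substrate tail to the MA/AB/T groups
#'
#' For every frame, the minimum distance between the centre of mass of the
#' tail selection (by default the last three heavy atoms of the acyl chain)
#' and the centres of mass of the residues in each region group
#' (`mode = "com_per_residue"`), or the minimum interatomic distance
#' (`mode = "atom_pair"`).
#'
#' @param trajectory An [md_trajectory()].
#' @param tail Integer atom indices of the substrate tail (typically 3 atoms).
#' @param regions Region definitions as from [faah_region_definitions()].
#' @param mode Distance mode, see [group_min_distance()].
#' @return Tibble with columns `frame`, `time_ns`, `dMA`, `dAB`, `dT`
#'   (angstrom), one row per frame.
#' @export
compute_distance_series <- function(trajectory, tail,
                                    regions = faah_region_definitions(),
                                    mode = c("com_per_residue", "atom_pair")) {
  mode <- match.arg(mode)
  if (length(tail) == 0L) stop("empty tail selection", call. = FALSE)
  stopifnot(all(c("MA", "AB", "T") %in% names(regions)))
  res_idx <- lapply(regions, function(r) .resolve_region(trajectory, r))
  nf <- n_frames(trajectory)
  if (nf == 0L) {
    return(tibble::tibble(frame = integer(), time_ns = numeric(),
                          dMA = numeric(), dAB = numeric(), dT = numeric()))
  }
  one_region <- function(residues) {
    if (mode == "com_per_residue") {
      tail_com <- com_series(trajectory, tail)
      d <- vapply(residues, function(idx) {
        rc <- com_series(trajectory, idx)
        sqrt(rowSums((tail_com - rc)^2))
      }, numeric(nf))
      if (nf == 1L) d <- matrix(d, nrow = 1)
      do.call(pmin, as.data.frame(d))
    } else {
      d <- vapply(residues, function(idx) {
        pair_min <- rep(Inf, nf)
        for (p in tail) {
          pp <- atom_series(trajectory, p)
          for (q in idx) {
            qq <- atom_series(trajectory, q)
            pair_min <- pmin(pair_min, sqrt(rowSums((pp - qq)^2)))
          }
        }
        pair_min
      }, numeric(nf))
      if (nf == 1L) d <- matrix(d, nrow = 1)
      do.call(pmin, as.data.frame(d))
    }
  }
  tibble::tibble(
    frame = seq_len(nf),
    time_ns = trajectory$times,
    dMA = one_region(res_idx$MA),
    dAB = one_region(res_idx$AB),
    dT = one_region(res_idx$T)
  )
}

#' Classify pocket occupancy from a distance triplet
#'
#' Rule order (all inequalities strict; equality with a cutoff fails the
#' condition):
#' 1. NB (not bound) if `min(dMA, dAB, dT) > nb_threshold`;
#' 2. MA if `dMA < cutoff_MA` and `dAB > cutoff_AB`;
#' 3. AB if `dMA > cutoff_MA` and `dAB < cutoff_AB`;
#' 4. T if neither holds and `dT < cutoff_T`;
#' 5. UNASSIGNED otherwise.
#'
#' Vectorised over its distance arguments.
#'
#' @param dMA,dAB,dT Distances in angstrom.
#' @param regions Region definitions supplying cutoffs (defaults 6/6/5 A).
#' @param nb_threshold Not-bound threshold in angstrom on the minimum of all
#'   three distances; must exceed every region cutoff. Default 12 A (the
#'   channel length scale).
#' @return Factor with levels MA, T, AB, NB, UNASSIGNED.
#' @export
classify_region <- function(dMA, dAB, dT,
                            regions = faah_region_definitions(),
                            nb_threshold = 12.0) {
  cMA <- regions$MA$cutoff
  cAB <- regions$AB$cutoff
  cT <- regions$T$cutoff
  stopifnot(cMA > 0, cAB > 0, cT > 0)
  if (nb_threshold <= max(cMA, cAB, cT)) {
    stop("nb_threshold must exceed every region cutoff", call. = FALSE)
  }
  n <- length(dMA)
  stopifnot(length(dAB) == n, length(dT) == n)
  lab <- rep("UNASSIGNED", n)
  is_ma <- dMA < cMA & dAB > cAB
  is_ab <- dMA > cMA & dAB < cAB
  lab[dT < cT & !is_ma & !is_ab] <- "T"
  lab[is_ma] <- "MA"
  lab[is_ab] <- "AB"
  lab[pmin(dMA, pmin(dAB, dT)) > nb_threshold] <- "NB"
  factor(lab, levels = region_levels())
}

#' Occupancy label vocabulary
#' @return Character vector of the five labels in canonical order.
#' @export
region_levels <- function() c("MA", "T", "AB", "NB", "UNASSIGNED")

#' Label every frame of a distance series
#'
#' @param distances Tibble from [compute_distance_series()] (columns `dMA`,
#'   `dAB`, `dT`; other columns pass through).
#' @inheritParams classify_region
#' @return The input tibble with a `label` factor column appended.
#' @export
label_trajectory <- function(distances,
                             regions = faah_region_definitions(),
                             nb_threshold = 12.0) {
  distances <- tibble::as_tibble(distances)
  distances$label <- classify_region(distances$dMA, distances$dAB,
                                     distances$dT, regions, nb_threshold)
  distances
}

#' Detect not-bound (unbinding) episodes
#'
#' Maximal runs of NB labels. Runs of at least `min_dwell` frames are reported
#' as unbinding episodes; shorter NB runs are reported as transient
#' excursions.
#'
#' @param labels Factor/character vector of region labels.
#' @param min_dwell Minimum run length (frames) for a genuine episode,
#'   default 10.
#' @return Tibble with columns `start_frame`, `end_frame` (0-based, inclusive),
#'   `n_frames`, `episode` (`"unbinding"` or `"transient"`).
#' @export
detect_unbinding <- function(labels, min_dwell = 10L) {
  stopifnot(min_dwell >= 1)
  labels <- as.character(labels)
  if (length(labels) == 0L) {
    return(tibble::tibble(start_frame = integer(), end_frame = integer(),
                          n_frames = integer(), episode = character()))
  }
  r <- rle(labels == "NB")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(
    start_frame = starts[keep] - 1L,
    end_frame = ends[keep] - 1L,
    n_frames = r$lengths[keep],
    episode = ifelse(r$lengths[keep] >= min_dwell, "unbinding", "transient")
  )
}
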