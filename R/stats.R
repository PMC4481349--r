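# Equilibration-aware aggregation: occupancy percentages, pre-reactive
# cross-tabs, MA<->AB transfer counts, and per-monomer pooling.

#' Summarise pocket occupancy over equilibrated frames
#'
#' Fractions of each region label over the frames with `time > cutoff`. With
#' `renormalize = TRUE` (default) percentages are taken over the assigned
#' labels (MA/T/AB/NB), the convention of occupancy bar plots that sum to
#' 100% over pockets; UNASSIGNED frames are still counted and reported.
#'
#' @param labels Factor/character vector of region labels.
#' @param times Numeric frame times in ns, aligned with `labels`.
#' @param equilibration_cutoff_ns Frames at or before this time are discarded
#'   (default 150 ns; use 0 for synthetic data generated at stationarity).
#' @param renormalize Percentage denominator: assigned frames only (`TRUE`,
#'   default) or all equilibrated frames (`FALSE`).
#' @return An `occupancy_summary`: tibble with one row per region (`region`,
#'   `n`, `percent`) and attributes `n_total`, `n_equilibrated`,
#'   `equilibration_cutoff_ns`, `renormalize`.
#' @export
summarize_occupancy <- function(labels, times,
                                equilibration_cutoff_ns = 150,
                                renormalize = TRUE) {
  stopifnot(length(labels) == length(times), equilibration_cutoff_ns >= 0)
  keep <- times > equilibration_cutoff_ns
  if (!any(keep)) stop("no equilibrated frames", call. = FALSE)
  lab <- factor(as.character(labels)[keep], levels = region_levels())
  n <- as.integer(table(lab))
  denom <- if (renormalize) sum(n[region_levels() != "UNASSIGNED"]) else sum(n)
  pct <- if (denom > 0) 100 * n / denom else rep(NA_real_, length(n))
  if (renormalize) pct[region_levels() == "UNASSIGNED"] <- NA_real_
  out <- tibble::tibble(region = factor(region_levels(),
                                        levels = region_levels()),
                        n = n, percent = pct)
  structure(out,
            n_total = length(labels),
            n_equilibrated = sum(keep),
            equilibration_cutoff_ns = equilibration_cutoff_ns,
            renormalize = renormalize,
            class = c("occupancy_summary", class(out)))
}

#' Cross-tabulate pre-reactive conformations by region
#'
#' Overall pre-reactive percentage over the equilibrated frames, and the
#' conditional distribution of pre-reactive frames across MA, T and AB
#' (summing to 100% when any pre-reactive frame falls in a pocket).
#'
#' @param labels Region labels, aligned with `flags` and `times`.
#' @param flags Logical pre-reactive flags.
#' @param times Frame times in ns.
#' @inheritParams summarize_occupancy
#' @return List with `overall_percent`, `n_prereactive`, `n_equilibrated`, and
#'   `conditional` (tibble region / n / percent over MA, T, AB; percentages
#'   `NA` when no pre-reactive frame exists).
#' @export
crosstab_prereactive <- function(labels, flags, times,
                                 equilibration_cutoff_ns = 150) {
  stopifnot(length(labels) == length(flags), length(labels) == length(times))
  keep <- times > equilibration_cutoff_ns
  if (!any(keep)) stop("no equilibrated frames", call. = FALSE)
  lab <- as.character(labels)[keep]
  fl <- flags[keep]
  n_eq <- sum(keep)
  n_pre <- sum(fl)
  pockets <- c("MA", "T", "AB")
  n_cond <- vapply(pockets, function(p) sum(fl & lab == p), integer(1))
  cond_pct <- if (sum(n_cond) > 0) 100 * n_cond / sum(n_cond) else
    rep(NA_real_, 3)
  list(
    overall_percent = 100 * n_pre / n_eq,
    n_prereactive = n_pre,
    n_equilibrated = n_eq,
    conditional = tibble::tibble(region = factor(pockets, levels = pockets),
                                 n = unname(n_cond),
                                 percent = unname(cond_pct))
  )
}

#' Count MA<->AB transfer events
#'
#' A transfer is a dwell-qualified MA run followed by a dwell-qualified AB run
#' (or vice versa) with no intervening qualified run of the origin pocket.
#' T and UNASSIGNED frames are "in transit": they neither qualify nor break a
#' pending transfer. Dwell-qualified NB episodes reset the automaton (an
#' unbound substrate has left the channel system).
#'
#' @param labels Region labels.
#' @param min_dwell Minimum frames in a pocket for a qualified run
#'   (default 10).
#' @param frame_interval_ns Frame spacing, for mean dwell times (default
#'   0.01 ns).
#' @return List with `transitions` (tibble: transition, n) and `dwell`
#'   (tibble: region, n_runs, mean_dwell_ns over maximal runs of each pocket
#'   label).
#' @export
count_region_transitions <- function(labels, min_dwell = 10L,
                                     frame_interval_ns = 0.01) {
  counts <- .count_transitions(labels, c("MA->AB", "AB->MA"), min_dwell,
                               transit = c("T", "UNASSIGNED"), breaker = "NB")
  s <- as.character(labels)
  r <- rle(s)
  dwell <- tibble::tibble(region = factor(region_levels(),
                                          levels = region_levels())) |>
    dplyr::left_join(
      tibble::tibble(region = r$values, len = r$lengths) |>
        dplyr::group_by(.data$region) |>
        dplyr::summarise(n_runs = dplyr::n(),
                         mean_dwell_ns = mean(.data$len) * frame_interval_ns),
      by = "region")
  dwell$n_runs[is.na(dwell$n_runs)] <- 0L
  list(transitions = tibble::tibble(transition = names(counts),
                                    n = unname(counts)),
       dwell = dwell)
}

#' Compare and pool per-monomer occupancy summaries
#'
#' Pooled fractions are frame-weighted over the monomers (equal to summarising
#' the concatenated label streams); the maximum absolute per-region
#' difference in percentage points is reported, with a warning (not an error)
#' when it exceeds `agreement_warn`.
#'
#' @param summary_a,summary_b `occupancy_summary` objects from
#'   [summarize_occupancy()] with identical settings.
#' @param agreement_warn Warn when max per-region |difference| exceeds this
#'   many percentage points (default 5).
#' @return List with `pooled` (occupancy_summary-like tibble),
#'   `max_abs_diff_percent`, and `per_monomer` (region x monomer tibble).
#' @export
compare_monomers <- function(summary_a, summary_b, agreement_warn = 5) {
  ra <- attr(summary_a, "renormalize")
  rb <- attr(summary_b, "renormalize")
  ca <- attr(summary_a, "equilibration_cutoff_ns")
  cb <- attr(summary_b, "equilibration_cutoff_ns")
  if (!identical(ra, rb) || !identical(ca, cb)) {
    stop("mismatched summary configuration (renormalize/cutoff)", call. = FALSE)
  }
  if (!identical(as.character(summary_a$region), as.character(summary_b$region))) {
    stop("mismatched region vocabulary", call. = FALSE)
  }
  n_pool <- summary_a$n + summary_b$n
  denom <- if (ra) sum(n_pool[summary_a$region != "UNASSIGNED"]) else sum(n_pool)
  pct <- if (denom > 0) 100 * n_pool / denom else rep(NA_real_, length(n_pool))
  if (ra) pct[summary_a$region == "UNASSIGNED"] <- NA_real_
  pooled <- tibble::tibble(region = summary_a$region, n = n_pool, percent = pct)
  pooled <- structure(pooled,
                      n_total = attr(summary_a, "n_total") + attr(summary_b, "n_total"),
                      n_equilibrated = attr(summary_a, "n_equilibrated") +
                        attr(summary_b, "n_equilibrated"),
                      equilibration_cutoff_ns = ca,
                      renormalize = ra,
                      class = c("occupancy_summary", class(pooled)))
  diffs <- abs(summary_a$percent - summary_b$percent)
  max_diff <- if (all(is.na(diffs))) NA_real_ else max(diffs, na.rm = TRUE)
  if (!is.na(max_diff) && max_diff > agreement_warn) {
    warning("monomer occupancy summaries differ by up to ",
            round(max_diff, 1), " percentage points", call. = FALSE)
  }
  per_monomer <- tibble::tibble(
    region = summary_a$region,
    percent_a = summary_a$percent,
    percent_b = summary_b$percent,
    n_a = summary_a$n,
    n_b = summary_b$n
  )
  list(pooled = pooled, max_abs_diff_percent = max_diff,
       per_monomer = per_monomer)
}
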