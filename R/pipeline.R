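# Pipeline composition: a declarative configuration (YAML-serialisable)
# naming the tail selection, chain path, region cutoffs, paddle residues and
# pre-reactive criteria; a runner that executes every stage per monomer and
# pools; and a deterministic JSON report writer.

#' Default pipeline configuration
#'
#' Encodes the standard analysis settings: 6/6/5 A region cutoffs, 12 A
#' not-bound threshold, 10-frame dwell, 150 ns equilibration cutoff (0 for
#' synthetic fixtures generated at stationarity), chi1 (N-CA-CB-CG) gating
#' quadruple with closed/open bins 45-85 / 140-200 degrees, and the
#' near-attack criterion set of [default_prereactive_criteria()]. The default
#' monomer mapping matches the synthetic topology (protein chain A, substrate
#' chain L, resid 900).
#'
#' @param equilibration_cutoff_ns Equilibration cutoff (default 0).
#' @param shape_policy `"torsion_pattern"` or `"end_to_end"`.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(equilibration_cutoff_ns = 0,
                                    shape_policy = "torsion_pattern") {
  cfg <- list(
    frame_interval = 0.01,
    monomers = list(
      list(id = "A", protein_chain = "A", substrate_chain = "L",
           substrate_resid = 900L)
    ),
    tail_n_atoms = 3L,
    regions = faah_region_definitions(),
    nb_threshold = 12.0,
    min_dwell = 10L,
    equilibration_cutoff_ns = equilibration_cutoff_ns,
    renormalize = TRUE,
    distance_mode = "com_per_residue",
    paddle = list(resF = 432L, resW = 531L, quadruple_policy = "N",
                  closed_bin = c(45, 85), open_bin = c(140, 200)),
    prereactive = list(criteria = NULL, combine = "all"),
    shape = list(policy = shape_policy, trans_min = 150, r_elongated = 0.75,
                 bend_terminal = 0.35, segment_len = 4L)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

# Ordered acyl-chain atom indices of a substrate residue: carbon atoms sorted
# by the numeric suffix of their name (C1, C2, ...), skipping the carbonyl
# marker pair when present.
.substrate_chain_atoms <- function(trajectory, chain, resid) {
  idx <- select_atoms(trajectory, chain = chain, resid = resid)
  top <- trajectory$topology[idx, ]
  is_chain_c <- grepl("^C[0-9]+$", top$name)
  cn <- as.integer(sub("^C", "", top$name[is_chain_c]))
  ord <- order(cn)
  chain_idx <- idx[is_chain_c][ord]
  # drop the carbonyl marker when an O1 partner identifies C1 as the carbonyl
  if ("O1" %in% top$name && 1L %in% cn) {
    chain_idx <- chain_idx[-1]
  }
  chain_idx
}

#' Run the full analysis pipeline on a trajectory
#'
#' Per monomer: distance series, region labels, unbinding episodes, paddle
#' angles and gate states, pre-reactive evaluation, shape classification,
#' occupancy summary, pre-reactive cross-tab, transfer and gate-transition
#' counts, polar records. With two monomers, occupancy summaries are compared
#' and pooled. Deterministic given its inputs.
#'
#' @param trajectory An [md_trajectory()].
#' @param config A `pipeline_config` (default [default_pipeline_config()]).
#' @return A `pipeline_report` list: per-monomer results under `$monomers`,
#'   pooled summary under `$pooled` (when two monomers), and the effective
#'   `$config`.
#' @export
run_pipeline <- function(trajectory, config = default_pipeline_config()) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  monomers <- lapply(config$monomers, function(m) {
    regions <- config$regions
    for (r in names(regions)) regions[[r]]$chain <- m$protein_chain
    chain_atoms <- .substrate_chain_atoms(trajectory, m$substrate_chain,
                                          m$substrate_resid)
    if (length(chain_atoms) < 4L) {
      stop("monomer ", m$id, ": substrate chain has ", length(chain_atoms),
           " atoms; need >= 4", call. = FALSE)
    }
    n_tail <- config$tail_n_atoms
    tail <- chain_atoms[(length(chain_atoms) - n_tail + 1L):length(chain_atoms)]
    distances <- compute_distance_series(trajectory, tail, regions,
                                         mode = config$distance_mode)
    labelled <- label_trajectory(distances, regions, config$nb_threshold)
    unbinding <- detect_unbinding(labelled$label, config$min_dwell)
    paddle <- compute_paddle_angles(
      trajectory,
      resF = paste0(m$protein_chain, ":", config$paddle$resF),
      resW = paste0(m$protein_chain, ":", config$paddle$resW),
      quadruple_policy = config$paddle$quadruple_policy,
      closed_bin = config$paddle$closed_bin,
      open_bin = config$paddle$open_bin)
    criteria <- config$prereactive$criteria
    if (is.null(criteria)) {
      criteria <- default_prereactive_criteria(
        chain = m$protein_chain,
        substrate_C = paste0(m$substrate_chain, ":", m$substrate_resid, ":C1"),
        substrate_O = paste0(m$substrate_chain, ":", m$substrate_resid, ":O1"))
    }
    prer <- evaluate_prereactive(trajectory, criteria,
                                 combine = config$prereactive$combine)
    shapes <- shape_time_series(
      trajectory, chain_atoms, policy = config$shape$policy,
      segment_len = config$shape$segment_len,
      equilibration_cutoff_ns = config$equilibration_cutoff_ns,
      trans_min = config$shape$trans_min,
      r_elongated = config$shape$r_elongated,
      bend_terminal = config$shape$bend_terminal)
    occupancy <- summarize_occupancy(
      labelled$label, labelled$time_ns,
      equilibration_cutoff_ns = config$equilibration_cutoff_ns,
      renormalize = config$renormalize)
    crosstab <- crosstab_prereactive(
      labelled$label, prer$flags$prereactive, labelled$time_ns,
      equilibration_cutoff_ns = config$equilibration_cutoff_ns)
    transitions <- count_region_transitions(
      labelled$label, config$min_dwell,
      frame_interval_ns = trajectory$frame_interval)
    gates <- count_gate_transitions(paddle$gate, config$min_dwell)
    polar <- build_polar_records(labelled, paddle, prer$flags$prereactive)
    list(id = m$id, labelled = labelled, unbinding = unbinding,
         paddle = paddle, prereactive = prer$flags, shapes = shapes,
         occupancy = occupancy, crosstab = crosstab,
         transitions = transitions, gate_transitions = gates, polar = polar)
  })
  names(monomers) <- vapply(config$monomers, `[[`, character(1), "id")
  pooled <- NULL
  if (length(monomers) == 2L) {
    pooled <- compare_monomers(monomers[[1]]$occupancy,
                               monomers[[2]]$occupancy)
  }
  structure(list(monomers = monomers, pooled = pooled, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> ", length(x$monomers), " monomer(s)\n", sep = "")
  for (m in x$monomers) {
    cat("-- monomer", m$id, "--\n")
    occ <- m$occupancy
    cat("  occupancy (%):",
        paste(sprintf("%s %.1f", occ$region, occ$percent), collapse = ", "),
        "\n")
    cat(sprintf("  pre-reactive: %.1f%% of %d equilibrated frames\n",
                m$crosstab$overall_percent, m$crosstab$n_equilibrated))
  }
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' A deterministic machine-readable bundle: per-monomer occupancy percentages,
#' pre-reactive cross-tab, transfer and gate-transition counts, shape
#' fractions, unbinding episodes, pooled summary, and the effective numeric
#' settings (units in the field names).
#'
#' @param report A `pipeline_report`.
#' @param path Output JSON path (created); `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_report_json <- function(report, path = NULL) {
  mono <- lapply(report$monomers, function(m) {
    list(
      occupancy_percent = stats::setNames(as.list(m$occupancy$percent),
                                          as.character(m$occupancy$region)),
      occupancy_n = stats::setNames(as.list(m$occupancy$n),
                                    as.character(m$occupancy$region)),
      n_equilibrated = attr(m$occupancy, "n_equilibrated"),
      prereactive_overall_percent = m$crosstab$overall_percent,
      prereactive_conditional_percent = stats::setNames(
        as.list(m$crosstab$conditional$percent),
        as.character(m$crosstab$conditional$region)),
      transitions = stats::setNames(as.list(m$transitions$transitions$n),
                                    m$transitions$transitions$transition),
      gate_transitions = stats::setNames(as.list(m$gate_transitions$n),
                                         m$gate_transitions$transition),
      shape_fractions = stats::setNames(as.list(m$shapes$fractions$fraction),
                                        m$shapes$fractions$coarse),
      n_unbinding_episodes = sum(m$unbinding$episode == "unbinding"),
      n_polar_records = nrow(m$polar)
    )
  })
  cfg <- report$config
  out <- list(
    monomers = mono,
    pooled = if (!is.null(report$pooled)) {
      list(occupancy_percent = stats::setNames(
             as.list(report$pooled$pooled$percent),
             as.character(report$pooled$pooled$region)),
           max_abs_diff_percent = report$pooled$max_abs_diff_percent)
    },
    settings = list(
      cutoff_MA_A = cfg$regions$MA$cutoff,
      cutoff_AB_A = cfg$regions$AB$cutoff,
      cutoff_T_A = cfg$regions$T$cutoff,
      nb_threshold_A = cfg$nb_threshold,
      min_dwell_frames = cfg$min_dwell,
      equilibration_cutoff_ns = cfg$equilibration_cutoff_ns,
      renormalize = cfg$renormalize,
      shape_policy = cfg$shape$policy
    )
  )
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Write / read a pipeline configuration (YAML)
#'
#' Round-trips all fields; criteria tibbles are stored as column lists.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  ser <- unclass(config)
  ser$regions <- lapply(ser$regions, function(r) {
    list(name = r$name, chain = r$chain, resid = r$residues$resid,
         resname = r$residues$resname, cutoff = r$cutoff)
  })
  if (!is.null(ser$prereactive$criteria)) {
    ser$prereactive$criteria <- lapply(as.list(ser$prereactive$criteria),
                                       function(col) {
                                         col[is.na(col)] <- NA
                                         as.list(col)
                                       })
  }
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  for (nm in names(y)) cfg[[nm]] <- y[[nm]]
  cfg$regions <- lapply(y$regions, function(r) {
    list(name = r$name, chain = r$chain,
         residues = tibble::tibble(resid = as.integer(unlist(r$resid)),
                                   resname = unlist(r$resname)),
         cutoff = r$cutoff)
  })
  names(cfg$regions) <- vapply(cfg$regions, `[[`, character(1), "name")
  cfg$paddle$closed_bin <- as.numeric(unlist(cfg$paddle$closed_bin))
  cfg$paddle$open_bin <- as.numeric(unlist(cfg$paddle$open_bin))
  if (!is.null(y$prereactive$criteria)) {
    cr <- y$prereactive$criteria
    cfg$prereactive$criteria <- tibble::tibble(
      name = unlist(cr$name),
      kind = unlist(cr$kind),
      a1 = unlist(cr$a1), a2 = unlist(cr$a2),
      a3 = vapply(cr$a3, function(v) if (is.null(v)) NA_character_ else
        as.character(v), character(1)),
      a4 = vapply(cr$a4, function(v) if (is.null(v)) NA_character_ else
        as.character(v), character(1)),
      min = vapply(cr$min, function(v) if (is.null(v)) NA_real_ else
        as.numeric(v), numeric(1)),
      max = vapply(cr$max, function(v) if (is.null(v)) NA_real_ else
        as.numeric(v), numeric(1))
    )
  }
  class(cfg) <- "pipeline_config"
  cfg
}
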