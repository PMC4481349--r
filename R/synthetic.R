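# Synthetic-trajectory generator: desk-scale trajectories with the statistical
# structure the analysis pipeline assumes, plus exact ground truth. The
# substrate tail hops among the MA/T/AB/NB pocket anchors with Markov dwell
# structure; the acyl chain is built kinematically so its torsion profile
# realises an emitted shape label; gating-residue CG atoms are placed so the
# computed phiF/phiW equal draws from per-state von Mises mixtures; and
# reactive-geometry marker atoms satisfy or violate the pre-reactive criteria
# according to an injected per-state Bernoulli flag. No forces, no membrane:
# the generator emulates the *statistics* of pocket hopping, not physics.

#' Generator configuration
#'
#' Defaults emulate the wild-type FAAH/anandamide system at desk scale: a
#' 4-state (MA, T, AB, NB) Markov chain whose stationary distribution is
#' (24, 69, 7, 0)%, per-state pre-reactive injection probabilities
#' (0.10, 0.40, 0.05, 0), T-dominated curved shapes, and tight (~8 degree
#' spread) von Mises gating modes at the ~65 degree (closed) and ~160 degree
#' (open) rotamers with a bimodal mixture in the transition state. The
#' default self-transition probability (0.70 per frame) keeps Markov dwell
#' structure while leaving an effective sample size at 20000 frames
#' (about n(1-a)/(1+a) = 3500) large enough that stationary occupancy is
#' recoverable to well under two percentage points.
#'
#' @param seed Integer seed; fixes every random draw.
#' @param n_frames Number of frames (default 20000, i.e. 200 ns at 10 ps).
#' @param frame_interval Frame spacing in ns (default 0.01).
#' @param stationary Target stationary distribution over (MA, T, AB, NB); used
#'   to build the default transition matrix.
#' @param self_transition Per-frame probability mass kept on the current state
#'   in the default transition matrix (default 0.98).
#' @param transition_matrix Optional explicit 4x4 row-stochastic matrix over
#'   (MA, T, AB, NB); overrides `stationary`/`self_transition`.
#' @param anchors 4x3 matrix of pocket anchor coordinates (rows MA, T, AB,
#'   NB, angstrom). Default: MA at the origin, AB 16.5 A away (the
#'   centre-to-centre channel separation), T midway, NB 25 A off-channel.
#' @param noise_sigma Isotropic Gaussian noise on the tail placement
#'   (angstrom, default 0.8).
#' @param chain_length Number of acyl-chain atoms (default 14).
#' @param shape_emission 4x3 row-stochastic matrix: per-state distribution
#'   over (elongated, hooked, curved).
#' @param prereactive_prob Per-state pre-reactive injection probability.
#' @param phiF_mix,phiW_mix Per-state von Mises mixtures for the gating
#'   dihedrals: a list of 4 data frames with columns `mean` (degrees),
#'   `kappa`, `weight`.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_frames = 20000L,
                             frame_interval = 0.01,
                             stationary = c(MA = 0.24, T = 0.69, AB = 0.07, NB = 0),
                             self_transition = 0.70,
                             transition_matrix = NULL,
                             anchors = NULL,
                             noise_sigma = 0.8,
                             chain_length = 14L,
                             shape_emission = NULL,
                             prereactive_prob = c(MA = 0.10, T = 0.40,
                                                  AB = 0.05, NB = 0),
                             phiF_mix = NULL,
                             phiW_mix = NULL) {
  states <- c("MA", "T", "AB", "NB")
  if (is.null(transition_matrix)) {
    stationary <- stationary / sum(stationary)
    # P = a*I + (1-a) * 1 pi^T has stationary pi for any 0 <= a < 1
    transition_matrix <- self_transition * diag(4) +
      (1 - self_transition) * matrix(stationary, 4, 4, byrow = TRUE)
  }
  transition_matrix <- as.matrix(transition_matrix)
  dimnames(transition_matrix) <- list(states, states)
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12)) {
    stop("transition_matrix rows must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (is.null(anchors)) {
    anchors <- rbind(MA = c(0, 0, 0), T = c(8.25, 0, 0),
                     AB = c(16.5, 0, 0), NB = c(8.25, 25, 0))
  }
  anchors <- as.matrix(anchors)
  dimnames(anchors) <- list(states, c("x", "y", "z"))
  if (is.null(shape_emission)) {
    shape_emission <- rbind(MA = c(0.45, 0.30, 0.25),
                            T  = c(0.10, 0.15, 0.75),
                            AB = c(0.30, 0.30, 0.40),
                            NB = c(0.20, 0.60, 0.20))
  }
  shape_emission <- as.matrix(shape_emission)
  dimnames(shape_emission) <- list(states, c("elongated", "hooked", "curved"))
  if (any(abs(rowSums(shape_emission) - 1) > 1e-12)) {
    stop("shape_emission rows must sum to 1", call. = FALSE)
  }
  prereactive_prob <- stats::setNames(as.numeric(prereactive_prob), states)
  if (any(prereactive_prob < 0 | prereactive_prob > 1)) {
    stop("prereactive_prob must lie in [0, 1]", call. = FALSE)
  }
  mix <- function(m, k, w) data.frame(mean = m, kappa = k, weight = w)
  if (is.null(phiF_mix)) {
    phiF_mix <- list(MA = mix(160, 50, 1),
                     T = mix(c(65, 150), c(50, 50), c(0.5, 0.5)),
                     AB = mix(65, 50, 1),
                     NB = mix(160, 50, 1))
  }
  if (is.null(phiW_mix)) {
    phiW_mix <- list(MA = mix(180, 50, 1),
                     T = mix(c(145, 180), c(50, 50), c(0.5, 0.5)),
                     AB = mix(180, 50, 1),
                     NB = mix(180, 50, 1))
  }
  names(phiF_mix) <- states
  names(phiW_mix) <- states
  stopifnot(n_frames >= 0, frame_interval > 0, noise_sigma > 0,
            chain_length >= 6)
  cfg <- list(seed = as.integer(seed), n_frames = as.integer(n_frames),
              frame_interval = frame_interval,
              transition_matrix = transition_matrix, anchors = anchors,
              noise_sigma = noise_sigma, chain_length = as.integer(chain_length),
              shape_emission = shape_emission,
              prereactive_prob = prereactive_prob,
              phiF_mix = phiF_mix, phiW_mix = phiW_mix)
  class(cfg) <- "generator_config"
  cfg
}

# Draws from a von Mises distribution (Best & Fisher 1979 rejection sampler).
# mu in degrees; returns degrees in (-180, 180].
rvonmises <- function(n, mu_deg, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) {
    return(stats::runif(n, -180, 180))
  }
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      u3 <- stats::runif(1)
      theta <- mu + sign(u3 - 0.5) * acos(f)
      theta <- atan2(sin(theta), cos(theta))
      out[i] <- theta * 180 / pi
      i <- i + 1L
    }
  }
  out
}

# Draw from a von Mises mixture data.frame (mean, kappa, weight).
rvm_mixture <- function(n, mix) {
  if (n == 0L) return(numeric(0))
  w <- mix$weight / sum(mix$weight)
  comp <- sample.int(nrow(mix), n, replace = TRUE, prob = w)
  out <- numeric(n)
  for (k in seq_len(nrow(mix))) {
    sel <- comp == k
    if (any(sel)) out[sel] <- rvonmises(sum(sel), mix$mean[k], mix$kappa[k])
  }
  out
}

# Evaluate a function with a local RNG stream; the caller's RNG state is
# untouched (no hidden global randomness).
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Static part of the synthetic topology + coordinates. Chain A holds the
# pocket pseudo-residues (named and numbered as in the real enzyme so one
# configuration drives real and synthetic runs), chain L the substrate.
.synthetic_static <- function(cfg) {
  anchors <- cfg$anchors
  # residue offsets perpendicular to the MA->AB channel axis (x), so pocket
  # separation along the axis is not eroded
  off <- rbind(c(0, 0, 0), c(0, 0.8, 0), c(0, 0, 0.8), c(0, -0.8, 0))
  atoms <- list()
  pos <- list()
  add <- function(name, resname, resid, chain, element, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, resname = resname, resid = resid, chain = chain,
      element = element, stringsAsFactors = FALSE)
    pos[[length(pos) + 1L]] <<- xyz
  }
  regions <- faah_region_definitions()
  for (rg in c("MA", "AB")) {
    rr <- regions[[rg]]$residues
    for (i in seq_len(nrow(rr))) {
      add("CA", rr$resname[i], rr$resid[i], "A", "C",
          anchors[rg, ] + off[i, ])
    }
  }
  add("CA", "PHE", 381L, "A", "C", anchors["T", ])
  # gating residues: fixed N/CA/CB scaffold near the T anchor; CG is placed
  # per frame to realise the drawn phi
  paddle_scaffold <- function(ca) {
    list(N = ca + c(-1.46, 0, 0), CA = ca, CB = ca + c(0.5, 1.4, 0))
  }
  scafF <- paddle_scaffold(anchors["T", ] + c(0, 1.8, 1.2))
  scafW <- paddle_scaffold(anchors["T", ] + c(0, -1.8, 1.2))
  add("N", "PHE", 432L, "A", "N", scafF$N)
  add("CA", "PHE", 432L, "A", "C", scafF$CA)
  add("CB", "PHE", 432L, "A", "C", scafF$CB)
  add("CG", "PHE", 432L, "A", "C", scafF$CB + c(0, 1.5, 0)) # per-frame
  add("N", "TRP", 531L, "A", "N", scafW$N)
  add("CA", "TRP", 531L, "A", "C", scafW$CA)
  add("CB", "TRP", 531L, "A", "C", scafW$CB)
  add("CG", "TRP", 531L, "A", "C", scafW$CB + c(0, 1.5, 0)) # per-frame
  # reactive-geometry markers around a nominal active-site point
  og <- c(8.25, -8, 0)
  u <- c(0, 1, 0)
  c1_sat <- og + 3.2 * u
  o1_dir <- c(sin(95 * pi / 180), -cos(95 * pi / 180), 0)
  o1_sat <- c1_sat + 1.23 * o1_dir
  add("OG", "SER", 241L, "A", "O", og)
  add("N", "GLY", 239L, "A", "N", o1_sat + c(2.9, 0, 0))
  add("N", "GLY", 240L, "A", "N", o1_sat + c(0, 0, 2.9))
  # substrate: carbonyl marker pair + acyl chain C2..C(chain_length+1)
  add("C1", "SUB", 900L, "L", "C", c1_sat) # per-frame
  add("O1", "SUB", 900L, "L", "O", o1_sat) # per-frame
  for (i in seq_len(cfg$chain_length)) {
    add(paste0("C", i + 1L), "SUB", 900L, "L", "C", c(0, 0, 0)) # per-frame
  }
  topo <- do.call(rbind, atoms)
  topo$serial <- seq_len(nrow(topo))
  list(topology = tibble::as_tibble(topo),
       base = do.call(rbind, pos),
       scafF = scafF, scafW = scafW,
       og = og, u = u, c1_sat = c1_sat, o1_sat = o1_sat, o1_dir = o1_dir)
}

# Torsion sequence (length n_windows) realising a coarse shape label.
.shape_torsions <- function(shape, n_windows) {
  om <- 180 + stats::rnorm(n_windows, 0, 5)
  om[om > 180] <- om[om > 180] - 360
  gauche <- 65 + stats::rnorm(n_windows, 0, 5)
  if (shape == "hooked") {
    k <- max(2L, min(3L, floor(n_windows / 3)))
    om[seq_len(k)] <- gauche[seq_len(k)]
  } else if (shape == "curved") {
    mid <- ceiling(n_windows / 2)
    lo <- max(1L, mid - 2L)
    hi <- min(n_windows, mid + 2L)
    om[lo:hi] <- gauche[lo:hi]
  }
  om
}

# Build an n-atom chain whose window torsions are `om` (length n - 3) and
# whose last-3-atom centre of mass sits at `target`. Atoms are returned in
# head-to-tail order.
.build_chain <- function(n, om, target, bond = 1.53, angle = 111) {
  pos <- matrix(NA_real_, n, 3)
  pos[n, ] <- c(0, 0, 0)
  pos[n - 1, ] <- c(bond, 0, 0)
  ang <- angle * pi / 180
  pos[n - 2, ] <- pos[n - 1, ] + bond * c(-cos(ang), sin(ang), 0)
  for (i in seq(n - 3, 1)) {
    pos[i, ] <- place_atom(pos[i + 3, ], pos[i + 2, ], pos[i + 1, ],
                           bond, angle, om[i])
  }
  tail_com <- colMeans(pos[(n - 2):n, , drop = FALSE])
  sweep(pos, 2, tail_com - target, "-")
}

#' Generate a synthetic trajectory with ground truth
#'
#' See [generator_config()] for the generative model. The same seed yields a
#' bit-identical trajectory.
#'
#' @param config A [generator_config()].
#' @return List with `trajectory` (an [md_trajectory()]), `truth` (tibble:
#'   frame, time_ns, state, shape, prereactive), and `events` (tibble of
#'   state changes: frame, from, to).
#' @export
generate_trajectory <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  states <- c("MA", "T", "AB", "NB")
  amat <- config$anchors
  dmin <- min(stats::dist(amat))
  if (dmin < 2 * config$noise_sigma) {
    stop("states not separable: closest anchors ", round(dmin, 2),
         " A apart with noise sigma ", config$noise_sigma, call. = FALSE)
  }
  st <- .synthetic_static(config)
  topo <- st$topology
  nf <- config$n_frames
  na <- nrow(topo)
  if (nf == 0L) {
    traj <- md_trajectory(topo, matrix(numeric(0), 0, 3 * na),
                          frame_interval = config$frame_interval)
    return(list(trajectory = traj,
                truth = tibble::tibble(frame = integer(), time_ns = numeric(),
                                       state = character(), shape = character(),
                                       prereactive = logical()),
                events = tibble::tibble(frame = integer(), from = character(),
                                        to = character())))
  }
  idx_of <- function(chain, resid, name) {
    which(topo$chain == chain & topo$resid == resid & topo$name == name)
  }
  iCGF <- idx_of("A", 432L, "CG")
  iCGW <- idx_of("A", 531L, "CG")
  iC1 <- idx_of("L", 900L, "C1")
  iO1 <- idx_of("L", 900L, "O1")
  chain_idx <- vapply(seq_len(config$chain_length),
                      function(i) idx_of("L", 900L, paste0("C", i + 1L)),
                      integer(1))
  n_chain <- config$chain_length
  n_win <- n_chain - 3L
  P <- config$transition_matrix
  with_local_seed(config$seed, {
    pi0 <- stationary_distribution(P)
    state <- character(nf)
    state[1] <- sample(states, 1, prob = pi0)
    for (f in seq_len(nf - 1L)) {
      state[f + 1L] <- sample(states, 1, prob = P[state[f], ])
    }
    shape <- vapply(state, function(s) {
      sample(colnames(config$shape_emission), 1,
             prob = config$shape_emission[s, ])
    }, character(1), USE.NAMES = FALSE)
    prer <- unname(stats::runif(nf) < config$prereactive_prob[state])
    phiF <- numeric(nf)
    phiW <- numeric(nf)
    for (s in states) {
      sel <- state == s
      if (any(sel)) {
        phiF[sel] <- rvm_mixture(sum(sel), config$phiF_mix[[s]])
        phiW[sel] <- rvm_mixture(sum(sel), config$phiW_mix[[s]])
      }
    }
    xyz <- matrix(rep(as.vector(t(st$base)), nf), nrow = nf, byrow = TRUE)
    put <- function(f, atom, p) xyz[f, (3 * (atom - 1) + 1):(3 * atom)] <<- p
    for (f in seq_len(nf)) {
      target <- amat[state[f], ] + stats::rnorm(3, 0, config$noise_sigma)
      om <- .shape_torsions(shape[f], n_win)
      chain_pos <- .build_chain(n_chain, om, target)
      for (j in seq_len(n_chain)) put(f, chain_idx[j], chain_pos[j, ])
      put(f, iCGF, place_atom(st$scafF$N, st$scafF$CA, st$scafF$CB,
                              1.5, 114, phiF[f]))
      put(f, iCGW, place_atom(st$scafW$N, st$scafW$CA, st$scafW$CB,
                              1.5, 114, phiW[f]))
      if (prer[f]) {
        c1 <- st$c1_sat + stats::rnorm(3, 0, 0.05)
        o1 <- st$o1_sat + stats::rnorm(3, 0, 0.05)
      } else {
        shift <- 2.8 * st$u
        c1 <- st$c1_sat + shift + stats::rnorm(3, 0, 0.05)
        o1 <- st$o1_sat + shift + stats::rnorm(3, 0, 0.05)
      }
      put(f, iC1, c1)
      put(f, iO1, o1)
    }
    traj <- md_trajectory(topo, xyz, frame_interval = config$frame_interval)
    truth <- tibble::tibble(frame = seq_len(nf), time_ns = traj$times,
                            state = state, shape = shape, prereactive = prer)
    chg <- which(state[-1] != state[-nf])
    events <- tibble::tibble(frame = chg + 1L, from = state[chg],
                             to = state[chg + 1L])
    list(trajectory = traj, truth = truth, events = events)
  })
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector for eigenvalue 1, normalised to sum to 1. Errors when the
#' stationary distribution is not unique (reducible chain).
#'
#' @param P Square row-stochastic matrix.
#' @return Named numeric vector.
#' @export
stationary_distribution <- function(P) {
  P <- as.matrix(P)
  e <- eigen(t(P))
  is_one <- abs(e$values - 1) < 1e-8
  if (sum(is_one) != 1L) {
    stop("reducible transition matrix: stationary distribution not unique",
         call. = FALSE)
  }
  v <- Re(e$vectors[, which(is_one)])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)),
                  rownames(P) %||% colnames(P))
}

#' Closed-form expectations for a generator configuration
#'
#' Stationary occupancy fractions, expected overall pre-reactive percentage
#' (`sum(pi_s * p_s)`), and the expected conditional distribution of
#' pre-reactive frames over MA, T, AB (`pi_s * p_s` normalised).
#'
#' @param config A [generator_config()].
#' @return List with `occupancy` (tibble: state, expected_percent),
#'   `overall_prereactive_percent`, `conditional` (tibble: state,
#'   expected_percent over MA/T/AB).
#' @export
analytic_expectations <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  pi0 <- stationary_distribution(config$transition_matrix)
  p <- config$prereactive_prob
  joint <- pi0 * p
  pockets <- c("MA", "T", "AB")
  cond <- if (sum(joint[pockets]) > 0) {
    100 * joint[pockets] / sum(joint[pockets])
  } else {
    stats::setNames(rep(NA_real_, 3), pockets)
  }
  list(
    occupancy = tibble::tibble(state = names(pi0),
                               expected_percent = 100 * as.numeric(pi0)),
    overall_prereactive_percent = 100 * sum(joint),
    conditional = tibble::tibble(state = pockets,
                                 expected_percent = as.numeric(cond))
  )
}

#' Write a synthetic fixture to disk
#'
#' Writes `trajectory.pdb` (multi-model), `truth.csv` and `config.yaml` into
#' `directory`. Re-reading with [read_fixture()] reproduces the trajectory to
#' PDB precision (1e-3 angstrom); re-running the generator from the stored
#' config reproduces it bit-exactly.
#'
#' @param sim Result of [generate_trajectory()].
#' @param config The [generator_config()] that produced it.
#' @param directory Output directory (created if missing).
#' @return `directory`, invisibly.
#' @export
write_fixture <- function(sim, config, directory) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE,
                                            showWarnings = FALSE)
  if (!ok) stop("unwritable path: ", directory, call. = FALSE)
  write_trajectory_pdb(sim$trajectory, file.path(directory, "trajectory.pdb"))
  readr::write_csv(sim$truth, file.path(directory, "truth.csv"))
  write_generator_config(config, file.path(directory, "config.yaml"))
  invisible(directory)
}

#' Read a synthetic fixture from disk
#'
#' @param directory Directory written by [write_fixture()].
#' @return List with `trajectory`, `truth`, `config`.
#' @export
read_fixture <- function(directory) {
  config <- read_generator_config(file.path(directory, "config.yaml"))
  trajectory <- read_trajectory(file.path(directory, "trajectory.pdb"),
                                frame_interval = config$frame_interval)
  truth <- readr::read_csv(file.path(directory, "truth.csv"),
                           show_col_types = FALSE)
  list(trajectory = trajectory, truth = truth, config = config)
}

#' Serialise / parse a generator configuration (YAML)
#'
#' Round-trips all fields, including matrices (stored row-wise) and the von
#' Mises mixtures.
#'
#' @param config A [generator_config()].
#' @param path File path.
#' @return `read_generator_config()` returns a [generator_config()];
#'   `write_generator_config()` returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  ser <- list(
    seed = config$seed,
    n_frames = config$n_frames,
    frame_interval = config$frame_interval,
    transition_matrix = apply(config$transition_matrix, 1, as.list,
                              simplify = FALSE),
    anchors = apply(config$anchors, 1, as.list, simplify = FALSE),
    noise_sigma = config$noise_sigma,
    chain_length = config$chain_length,
    shape_emission = apply(config$shape_emission, 1, as.list,
                           simplify = FALSE),
    prereactive_prob = as.list(config$prereactive_prob),
    phiF_mix = lapply(config$phiF_mix, function(d) lapply(d, as.numeric)),
    phiW_mix = lapply(config$phiW_mix, function(d) lapply(d, as.numeric))
  )
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  tomat <- function(x) do.call(rbind, lapply(x, function(r) unlist(r)))
  generator_config(
    seed = y$seed,
    n_frames = y$n_frames,
    frame_interval = y$frame_interval,
    transition_matrix = tomat(y$transition_matrix),
    anchors = tomat(y$anchors),
    noise_sigma = y$noise_sigma,
    chain_length = y$chain_length,
    shape_emission = tomat(y$shape_emission),
    prereactive_prob = unlist(y$prereactive_prob),
    phiF_mix = lapply(y$phiF_mix, as.data.frame),
    phiW_mix = lapply(y$phiW_mix, as.data.frame)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
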