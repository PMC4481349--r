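# Enzyme kinetics: Michaelis-Menten saturation fits, competition-assay
# exponential decays, selectivity (rate) ratios, and seeded assay simulation
# for recovery studies. Fits use Levenberg-Marquardt nonlinear least squares
# with closed-form linearisation starts (Hanes-Woolf for saturation,
# log-linear for decay); unweighted by default, optional 1/y weighting.

#' Fit a Michaelis-Menten saturation curve
#'
#' Nonlinear least squares of `v = Vmax * S / (Km + S)`, started from the
#' Hanes-Woolf linearisation (`S/v` on `S`).
#'
#' @param data Data frame of the rate curve.
#' @param conc,velocity Column names (strings) for substrate concentration
#'   (micromolar) and velocity (pmol min^-1 ug^-1). Defaults
#'   `"concentration_uM"`, `"velocity"`.
#' @param weights `"none"` (default) or `"1/y"` for inverse-velocity
#'   weighting.
#' @return An `mm_fit` object; supports [tidy()][generics::tidy],
#'   [glance()][generics::glance], `predict()`, `autoplot()`. Fields include
#'   `Vmax`, `Km`, standard errors, and the residual sum of squares. A
#'   non-positive parameter at the optimum is flagged (`flagged = TRUE`).
#' @examples
#' d <- data.frame(concentration_uM = c(3.3, 6.25, 12.5, 25, 33, 50))
#' d$velocity <- 1 * d$concentration_uM / (5 + d$concentration_uM)
#' fit <- fit_michaelis_menten(d)
#' generics::tidy(fit)
#' @export
fit_michaelis_menten <- function(data, conc = "concentration_uM",
                                 velocity = "velocity",
                                 weights = c("none", "1/y")) {
  weights <- match.arg(weights)
  S <- data[[conc]]
  v <- data[[velocity]]
  if (is.null(S) || is.null(v)) {
    stop("data must contain columns '", conc, "' and '", velocity, "'",
         call. = FALSE)
  }
  keep <- is.finite(S) & is.finite(v)
  S <- S[keep]; v <- v[keep]
  if (length(unique(S)) < 3) {
    stop("need >= 3 distinct concentrations", call. = FALSE)
  }
  if (any(S <= 0)) stop("concentrations must be > 0", call. = FALSE)
  # Hanes-Woolf start: S/v = S/Vmax + Km/Vmax
  hw <- stats::lm(I(S / v) ~ S, subset = v > 0)
  vmax0 <- 1 / stats::coef(hw)[["S"]]
  km0 <- stats::coef(hw)[["(Intercept)"]] * vmax0
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(v)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(S)
  w <- if (weights == "1/y") 1 / pmax(v, .Machine$double.eps) else rep(1, length(v))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                      start = list(Vmax = vmax0, Km = km0),
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(
    list(Vmax = est[["Vmax"]], Km = est[["Km"]],
         se_Vmax = se[["Vmax"]], se_Km = se[["Km"]],
         rss = sum(stats::resid(fit)^2),
         n = length(v),
         flagged = any(est <= 0),
         weights = weights,
         fit = fit,
         data = tibble::tibble(concentration_uM = S, velocity = v)),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  Vmax = %.4g +/- %.3g pmol min^-1 ug^-1\n", x$Vmax, x$se_Vmax))
  cat(sprintf("  Km   = %.4g +/- %.3g uM\n", x$Km, x$se_Km))
  if (x$flagged) cat("  [flagged: non-positive parameter at optimum]\n")
  invisible(x)
}

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$concentration_uM else
    newdata$concentration_uM
  object$Vmax * S / (object$Km + S)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Michaelis-Menten fit
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(term = c("Vmax", "Km"),
                 estimate = c(x$Vmax, x$Km),
                 std.error = c(x$se_Vmax, x$se_Km))
}

#' Glance at a Michaelis-Menten fit
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return One-row tibble with `rss`, `n`, `flagged`.
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, flagged = x$flagged)
}

#' Fit an exponential decay
#'
#' Least squares of `y = A exp(-k t)` (plus a plateau `c` when
#' `with_plateau = TRUE`), started from a log-linear regression on the
#' positive signal values. A fitted rate indistinguishable from zero (|k| <
#' 2 standard errors) is flagged.
#'
#' @param data Data frame of the decay curve.
#' @param time,signal Column names for time (minutes) and remaining-substrate
#'   signal. Defaults `"time_min"`, `"signal"`.
#' @param with_plateau Add a constant plateau term (default FALSE).
#' @return A `decay_fit` object with `A`, `k` (min^-1), optional `plateau`,
#'   standard errors, `rss`, `flagged`; supports `tidy()`, `glance()`,
#'   `predict()`, `autoplot()`.
#' @export
fit_exponential_decay <- function(data, time = "time_min", signal = "signal",
                                  with_plateau = FALSE) {
  t <- data[[time]]
  y <- data[[signal]]
  if (is.null(t) || is.null(y)) {
    stop("data must contain columns '", time, "' and '", signal, "'",
         call. = FALSE)
  }
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(unique(t)) < 3) stop("need >= 3 time points", call. = FALSE)
  if (all(y == 0)) stop("all-zero signal", call. = FALSE)
  pos <- y > 0
  ll <- stats::lm(log(y[pos]) ~ t[pos])
  a0 <- exp(stats::coef(ll)[[1]])
  k0 <- max(-stats::coef(ll)[[2]], 1e-6)
  fit <- tryCatch({
    if (with_plateau) {
      minpack.lm::nlsLM(y ~ A * exp(-k * t) + cc,
                        start = list(A = a0, k = k0, cc = min(y)),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ A * exp(-k * t),
                        start = list(A = a0, k = k0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) stop("exponential-decay fit did not converge: ",
                              conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  k_est <- est[["k"]]
  k_se <- se[["k"]]
  structure(
    list(A = est[["A"]], k = k_est,
         plateau = if (with_plateau) est[["cc"]] else NULL,
         se_A = se[["A"]], se_k = k_se,
         se_plateau = if (with_plateau) se[["cc"]] else NULL,
         rss = sum(stats::resid(fit)^2),
         n = length(y),
         flagged = !is.finite(k_se) || abs(k_est) < 2 * k_se || k_est <= 0,
         with_plateau = with_plateau,
         fit = fit,
         data = tibble::tibble(time_min = t, signal = y)),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential-decay fit (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  A = %.4g +/- %.3g\n", x$A, x$se_A))
  cat(sprintf("  k = %.4g +/- %.3g min^-1\n", x$k, x$se_k))
  if (x$with_plateau) cat(sprintf("  plateau = %.4g\n", x$plateau))
  if (x$flagged) cat("  [flagged: rate indistinguishable from zero]\n")
  invisible(x)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_min else newdata$time_min
  object$A * exp(-object$k * t) + (object$plateau %||% 0)
}

#' Tidy an exponential-decay fit
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.decay_fit <- function(x, ...) {
  terms <- c("A", "k", if (x$with_plateau) "plateau")
  tibble::tibble(term = terms,
                 estimate = c(x$A, x$k, x$plateau),
                 std.error = c(x$se_A, x$se_k, x$se_plateau))
}

#' Glance at an exponential-decay fit
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return One-row tibble with `rss`, `n`, `flagged`.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, flagged = x$flagged)
}

#' Selectivity ratio of two decay rates
#'
#' `k1 / k2` with first-order (delta-method) error propagation:
#' `SE = ratio * sqrt((se1/k1)^2 + (se2/k2)^2)`.
#'
#' @param fit1,fit2 `decay_fit` objects (numerator / denominator).
#' @return Tibble with `ratio`, `se`, `k1`, `k2`.
#' @export
selectivity_ratio <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "decay_fit"), inherits(fit2, "decay_fit"))
  if (fit2$k <= 0) stop("denominator rate must be > 0", call. = FALSE)
  ratio <- fit1$k / fit2$k
  se <- abs(ratio) * sqrt((fit1$se_k / fit1$k)^2 + (fit2$se_k / fit2$k)^2)
  tibble::tibble(ratio = ratio, se = se, k1 = fit1$k, k2 = fit2$k)
}

#' Simulate a saturation (Michaelis-Menten) assay
#'
#' Multiplicative Gaussian noise: `v = Vmax S / (Km + S) * (1 + eps)`,
#' `eps ~ N(0, noise_sd)`. Deterministic under `seed`.
#'
#' @param Vmax,Km True parameters.
#' @param concentrations Assay design in micromolar; defaults to the
#'   six-point dilution series 3.3, 6.25, 12.5, 25, 33, 50.
#' @param noise_sd Relative noise standard deviation (default 0.02).
#' @param replicates Replicates per concentration (default 1).
#' @param seed Optional integer seed.
#' @return Tibble with `concentration_uM`, `velocity`, `replicate`.
#' @export
simulate_mm_assay <- function(Vmax, Km,
                              concentrations = c(3.3, 6.25, 12.5, 25, 33, 50),
                              noise_sd = 0.02, replicates = 1L, seed = NULL) {
  if (length(concentrations) < 1 || any(concentrations <= 0)) {
    stop("invalid design: concentrations must be positive", call. = FALSE)
  }
  draw <- function() {
    S <- rep(concentrations, times = replicates)
    mu <- Vmax * S / (Km + S)
    tibble::tibble(
      concentration_uM = S,
      velocity = mu * (1 + stats::rnorm(length(S), 0, noise_sd)),
      replicate = rep(seq_len(replicates), each = length(concentrations))
    )
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Simulate a competition-assay decay curve
#'
#' `y = A exp(-k t) + plateau`, multiplicative Gaussian noise, time points
#' defaulting to the assay design 0, 5, 15, 30 minutes.
#'
#' @param A,k,plateau True parameters (`plateau` default 0).
#' @param times Time points in minutes.
#' @param noise_sd Relative noise standard deviation (default 0.05).
#' @param replicates Replicates per time point (default 3).
#' @param seed Optional integer seed.
#' @return Tibble with `time_min`, `signal`, `replicate`.
#' @export
simulate_decay_assay <- function(A, k, plateau = 0,
                                 times = c(0, 5, 15, 30),
                                 noise_sd = 0.05, replicates = 3L,
                                 seed = NULL) {
  if (length(times) < 1 || any(times < 0)) {
    stop("invalid design: times must be >= 0", call. = FALSE)
  }
  draw <- function() {
    t <- rep(times, times = replicates)
    mu <- A * exp(-k * t) + plateau
    tibble::tibble(
      time_min = t,
      signal = mu * (1 + stats::rnorm(length(t), 0, noise_sd)),
      replicate = rep(seq_len(replicates), each = length(times))
    )
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}
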