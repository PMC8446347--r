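#' Simulate a Galton-Watson branching process
#'
#' Each trial starts from a single seed event; every event in a generation
#' independently spawns offspring drawn from the chosen family with mean
#' `m` (the branching ratio), and the avalanche size is the total number of
#' events until extinction or the generation cap. Below `m = 1` activity
#' dies out (subcritical); above, it grows without bound (supercritical);
#' at `m = 1` avalanche sizes follow the critical power law
#' p(n) ~ n^(-3/2).
#'
#' Trials still alive at `max_generations` are flagged truncated; they are
#' excluded from exponent fitting to avoid tail bias from the cap.
#'
#' @param m branching ratio, >= 0 (expected offspring per event).
#' @param offspring offspring family: `"poisson"` (default; Poisson(m)) or
#'   `"fixed"` (deterministic integer m offspring per event).
#' @param n_trials number of avalanches, >= 1.
#' @param max_generations generation cap, default 10000.
#' @param seed optional RNG seed, recorded.
#' @return An `avalanche_ensemble`: `sizes`, `generations`, `truncated`,
#'   plus the generating parameters.
#' @examples
#' e <- simulate_branching(0.8, n_trials = 1000, seed = 1)
#' mean(e$sizes)  # close to 1/(1 - 0.8) = 5
#' @export
simulate_branching <- function(m, offspring = c("poisson", "fixed"),
                               n_trials = 1000, max_generations = 10000,
                               seed = NULL) {
  offspring <- match.arg(offspring)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0)
    stop("'m' must be a single nonnegative number", call. = FALSE)
  if (offspring == "fixed" && m != round(m))
    stop("'fixed' offspring requires integer 'm'", call. = FALSE)
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  z <- rep(1, n_trials)          # active events in current generation
  sizes <- rep(1, n_trials)      # the seed event counts
  gens <- rep(0L, n_trials)
  alive <- rep(TRUE, n_trials)
  for (g in seq_len(max_generations)) {
    if (!any(alive)) break
    z[alive] <- if (offspring == "poisson")
      stats::rpois(sum(alive), m * z[alive]) else m * z[alive]
    sizes[alive] <- sizes[alive] + z[alive]
    gens[alive] <- g
    alive <- alive & z > 0
  }
  structure(list(sizes = sizes, generations = gens, truncated = alive,
                 branching_ratio = m, offspring_model = offspring,
                 n_trials = n_trials, max_generations = max_generations,
                 seed = seed),
            class = "avalanche_ensemble")
}

#' @export
print.avalanche_ensemble <- function(x, ...) {
  cat(sprintf(
    "<avalanche_ensemble> m = %g (%s), %d trials, cap %d; mean size %.3g, %d truncated\n",
    x$branching_ratio, x$offspring_model, x$n_trials, x$max_generations,
    mean(x$sizes), sum(x$truncated)))
  invisible(x)
}

#' @export
as.data.frame.avalanche_ensemble <- function(x, ...) {
  data.frame(size = x$sizes, generations = x$generations,
             truncated = x$truncated)
}

## Hurwitz zeta(s, a) = sum_{k>=0} (a + k)^(-s), s > 1, by direct summation
## of the first K terms plus an Euler-Maclaurin tail.
hurwitz_zeta <- function(s, a, K = 30L) {
  k <- 0:(K - 1L)
  b <- a + K
  sum((a + k)^(-s)) +
    b^(1 - s) / (s - 1) + b^(-s) / 2 +
    s * b^(-s - 1) / 12 - s * (s + 1) * (s + 2) * b^(-s - 3) / 720
}

#' Discrete power-law exponent by maximum likelihood
#'
#' Fits p(n) = n^(-alpha) / zeta(alpha, n_min) to the avalanche sizes at or
#' above the lower cutoff `n_min`, maximizing the discrete likelihood
#' (normalized by the Hurwitz zeta function), and reports the asymptotic
#' standard error from the observed Fisher information. At criticality the
#' expected exponent is 3/2.
#'
#' @param sizes avalanche sizes (an `avalanche_ensemble` or an integer
#'   vector). For an ensemble, truncated avalanches are excluded.
#' @param n_min lower cutoff, default 10 (reduces finite-size bias from
#'   the head of the distribution).
#' @return A list of class `powerlaw_fit`: `alpha`, `se`, `n_tail`
#'   (number of sizes used), `n_min`.
#' @export
fit_powerlaw_exponent <- function(sizes, n_min = 10) {
  if (inherits(sizes, "avalanche_ensemble"))
    sizes <- sizes$sizes[!sizes$truncated]
  if (!is.numeric(sizes) || any(sizes < 1))
    stop("'sizes' must be numeric, all >= 1", call. = FALSE)
  x <- sizes[sizes >= n_min]
  n <- length(x)
  if (n < 100)
    stop(sprintf("need >= 100 sizes >= n_min; got %d", n), call. = FALSE)
  if (length(unique(x)) == 1L)
    stop("all sizes identical: exponent undefined", call. = FALSE)
  mean_log <- mean(log(x))
  nll <- function(a) a * mean_log + log(hurwitz_zeta(a, n_min))
  opt <- stats::optimize(nll, interval = c(1.001, 8))
  alpha <- opt$minimum
  h <- 1e-4
  d2 <- (nll(alpha + h) - 2 * opt$objective + nll(alpha - h)) / h^2
  structure(list(alpha = alpha, se = 1 / sqrt(n * d2),
                 n_tail = n, n_min = n_min),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> alpha = %.4f (se %.4f), n = %d at n_min = %g\n",
              x$alpha, x$se, x$n_tail, x$n_min))
  invisible(x)
}

#' Survival probability of a supercritical Poisson branching process
#'
#' For Poisson offspring with mean `m > 1`, the probability that the
#' process survives forever is the positive root q of the extinction
#' fixed-point equation 1 - q = exp(-m q); for `m <= 1` it is 0.
#'
#' @param m branching ratio.
#' @return Survival probability in \[0, 1).
#' @export
poisson_survival_prob <- function(m) {
  stopifnot(is.numeric(m), all(is.finite(m)), all(m >= 0))
  vapply(m, function(mi) {
    if (mi <= 1) return(0)
    stats::uniroot(function(q) 1 - q - exp(-mi * q),
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }, numeric(1))
}

#' Locate the criticality transition of a branching process
#'
#' Sweeps the branching ratio across a grid straddling the transition,
#' measuring the fraction of avalanches still alive at a deep generation
#' cap (the finite-horizon survival frequency). Below the transition this
#' frequency is essentially zero; above it, it rises steeply. The
#' transition ratio is estimated by linear interpolation of the survival
#' frequency across the first grid interval in which it crosses
#' `threshold`. For an ideal Galton-Watson process the transition is at
#' exactly 1.
#'
#' @param offspring offspring family, as in [simulate_branching()].
#' @param ratios grid of branching ratios; must straddle the transition.
#' @param n_trials trials per grid point, default 10000.
#' @param max_generations generation cap, default 200.
#' @param seed optional RNG seed for the whole sweep.
#' @param threshold survival-frequency level whose crossing defines the
#'   transition; default 0.05, well above the finite-cap survival at
#'   criticality (~2/cap) and well below the survival one grid step into
#'   the supercritical side.
#' @return A list of class `critical_ratio`: `estimate`, `survival`
#'   (data.frame: ratio, survival), `threshold`.
#' @export
locate_critical_ratio <- function(offspring = "poisson",
                                  ratios = seq(0.6, 1.4, by = 0.1),
                                  n_trials = 10000, max_generations = 200,
                                  seed = NULL, threshold = 0.05) {
  if (length(ratios) < 2 || is.unsorted(ratios))
    stop("'ratios' must be an increasing grid", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  surv <- vapply(ratios, function(m) {
    e <- simulate_branching(m, offspring, n_trials, max_generations)
    mean(e$truncated)
  }, numeric(1))
  above <- surv > threshold
  if (all(above))
    stop("grid entirely supercritical: extend 'ratios' downward",
         call. = FALSE)
  if (!any(above))
    stop("grid entirely subcritical: extend 'ratios' upward", call. = FALSE)
  i <- which(above)[1]
  if (i == 1L) stop("survival already above threshold at the lowest ratio",
                    call. = FALSE)
  est <- ratios[i - 1] + (threshold - surv[i - 1]) /
    (surv[i] - surv[i - 1]) * (ratios[i] - ratios[i - 1])
  structure(list(estimate = est,
                 survival = data.frame(ratio = ratios, survival = surv),
                 threshold = threshold),
            class = "critical_ratio")
}

#' @export
print.critical_ratio <- function(x, ...) {
  cat(sprintf("<critical_ratio> transition estimate %.4f (threshold %g)\n",
              x$estimate, x$threshold))
  invisible(x)
}
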