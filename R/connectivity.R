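#' @keywords internal
new_connectivity <- function(weights, cell_class, sigma, g_i, seed) {
  structure(list(weights = weights, cell_class = cell_class,
                 sigma = sigma, g_i = g_i, seed = seed),
            class = "connectivity")
}

#' Truncated-Gaussian excitatory connectivity
#'
#' Draws every weight J\[i, j\] (from sender neuron j onto receiver neuron i)
#' i.i.d. from a zero-mean Gaussian of standard deviation `sigma`, then sets
#' negative draws to exactly zero. The result is a dense nonnegative matrix
#' in which approximately half of the possible connections are absent, and
#' the mean weight equals sigma/sqrt(2*pi). Self-connections are permitted.
#'
#' @param N number of neurons (>= 2).
#' @param sigma width (standard deviation) of the Gaussian, default 0.05.
#' @param seed optional RNG seed, recorded in the result.
#' @return A `connectivity` object: `weights` (N x N), `cell_class`
#'   (all `"excitatory"`), `sigma`, `g_i` (`NA`), `seed`.
#' @seealso [make_ei_weights()], [adaptation_strength()]
#' @export
make_excitatory_weights <- function(N, sigma = 0.05, seed = NULL) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("'N' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  J <- matrix(stats::rnorm(N * N, mean = 0, sd = sigma), N, N)
  J[J < 0] <- 0
  new_connectivity(J, rep("excitatory", N), sigma, NA_real_, seed)
}

#' Balanced excitatory-inhibitory connectivity
#'
#' Generates weights as [make_excitatory_weights()], then labels the second
#' half of the neurons inhibitory and multiplies every column of an
#' inhibitory sender by the factor `g_i` (default -1.5). With the default
#' the recurrent connections are dominated by inhibition: the mean weight is
#' (sigma/sqrt(2*pi)) * (1 + g_i)/2 < 0.
#'
#' @param N number of neurons; must be even (half are inhibitory).
#' @param sigma Gaussian width, default 0.05.
#' @param g_i inhibitory scaling factor, must be negative; default -1.5.
#' @param seed optional RNG seed, recorded.
#' @return A `connectivity` object with `cell_class` `"excitatory"` for the
#'   first N/2 neurons and `"inhibitory"` for the rest.
#' @export
make_ei_weights <- function(N, sigma = 0.05, g_i = -1.5, seed = NULL) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("'N' must be an integer >= 2", call. = FALSE)
  if (N %% 2 != 0) stop("'N' must be even: half the neurons are inhibitory",
                        call. = FALSE)
  if (!is.numeric(g_i) || length(g_i) != 1L || g_i >= 0)
    stop("'g_i' must be a single negative number", call. = FALSE)
  J <- make_excitatory_weights(N, sigma, seed)
  inh <- (N / 2 + 1):N
  J$weights[, inh] <- g_i * J$weights[, inh]
  J$cell_class[inh] <- "inhibitory"
  J$g_i <- g_i
  J
}

#' Adaptation strength matched to the connectivity
#'
#' The strength of intrinsic adaptation used in the pure-excitatory model is
#' set to the average summed input weight per neuron,
#' g_w = (1/N) * sum_ij J\[i, j\]. At the silent steady state adaptation then
#' cancels the mean recurrent excitation.
#'
#' @param J a `connectivity` object.
#' @return The scalar g_w.
#' @export
adaptation_strength <- function(J) {
  stopifnot(inherits(J, "connectivity"))
  sum(J$weights) / nrow(J$weights)
}

#' Attenuate inhibitory weights
#'
#' Scales every column of an inhibitory sender by `factor` in \[0, 1\],
#' emulating a pharmacological block of inhibition (glycinergic or
#' GABAergic antagonists). `factor = 1` is the identity; `factor = 0`
#' removes inhibition entirely, leaving only the excitatory columns.
#'
#' @param J a `connectivity` object from [make_ei_weights()].
#' @param factor scalar in \[0, 1\].
#' @return A `connectivity` object with attenuated inhibitory columns.
#' @export
scale_inhibition <- function(J, factor) {
  stopifnot(inherits(J, "connectivity"))
  if (!any(J$cell_class == "inhibitory"))
    stop("'J' has no inhibitory neurons; need an E/I matrix", call. = FALSE)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor < 0 || factor > 1)
    stop("'factor' must be a single number in [0, 1]", call. = FALSE)
  inh <- which(J$cell_class == "inhibitory")
  J$weights[, inh] <- factor * J$weights[, inh]
  J
}

#' @export
print.connectivity <- function(x, ...) {
  n_inh <- sum(x$cell_class == "inhibitory")
  cat(sprintf(
    "<connectivity> %d x %d, sigma = %g, %d inhibitory%s, %.1f%% zero entries\n",
    nrow(x$weights), ncol(x$weights), x$sigma, n_inh,
    if (n_inh > 0) sprintf(" (g_i = %g)", x$g_i) else "",
    100 * mean(x$weights == 0)))
  invisible(x)
}

#' Write / read a connectivity matrix
#'
#' The weight matrix is written as a headerless CSV of N rows and the
#' metadata (sigma, g_i, seed, cell classes) as a JSON sidecar next to it.
#'
#' @param J a `connectivity` object.
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @return `write_connectivity` returns `path` invisibly;
#'   `read_connectivity` returns a `connectivity` object.
#' @export
write_connectivity <- function(J, path) {
  stopifnot(inherits(J, "connectivity"))
  utils::write.table(J$weights, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(sigma = J$sigma, g_i = J$g_i, seed = J$seed,
               cell_class = J$cell_class)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_connectivity
#' @param path CSV file path written by [write_connectivity()].
#' @export
read_connectivity <- function(path) {
  W <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(W) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_connectivity(W, meta$cell_class, meta$sigma,
                   if (is.null(meta$g_i)) NA_real_ else meta$g_i,
                   meta$seed)
}
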