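#' Generator configuration
#'
#' Bundles the settings shared by every synthetic-data generator: the RNG
#' seed, the noise level, and the number of replicates. Identical seed and
#' parameters give bit-identical output; `noise_sd = 0` gives noiseless
#' output.
#'
#' @param seed Integer RNG seed.
#' @param noise_sd Non-negative noise standard deviation. Units depend on the
#'   generator: mP for titrations, intensity units for spectra, Angstrom for
#'   coordinate jitter.
#' @param n_replicates Positive integer number of replicates to generate.
#'
#' @return An object of class `gen_config`.
#' @examples
#' gen_config(seed = 1, noise_sd = 5, n_replicates = 3)
#' @export
gen_config <- function(seed = 1L, noise_sd = 0, n_replicates = 1L) {
  seed <- as.integer(seed)
  if (length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) ||
      noise_sd < 0) {
    stop("'noise_sd' must be a single non-negative number", call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)
  if (length(n_replicates) != 1L || is.na(n_replicates) || n_replicates < 1L) {
    stop("'n_replicates' must be a positive integer", call. = FALSE)
  }
  structure(
    list(seed = seed, noise_sd = noise_sd, n_replicates = n_replicates),
    class = "gen_config"
  )
}

#' @export
print.gen_config <- function(x, ...) {
  cat(sprintf("<gen_config> seed=%d noise_sd=%g n_replicates=%d\n",
              x$seed, x$noise_sd, x$n_replicates))
  invisible(x)
}

as_gen_config <- function(gen) {
  if (inherits(gen, "gen_config")) return(gen)
  if (is.list(gen)) return(do.call(gen_config, gen))
  stop("'gen' must be a gen_config object", call. = FALSE)
}
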