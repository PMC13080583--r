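#' Generate a synthetic fluorescence-polarization titration
#'
#' Draws a 2-fold dilution series from `top` downward (`n_points` points) and
#' evaluates the ligand-depletion isotherm [eval_isotherm()] at each
#' concentration, adding homoscedastic Gaussian noise of standard deviation
#' `gen$noise_sd` (mP). With `gen$n_replicates > 1` the same design is
#' repeated with independent noise and stacked in the `replicate` column.
#' Generating parameters are stored in the `gen_params` attribute for
#' recovery tests.
#'
#' @param kd Generating dissociation constant, nM (> 0).
#' @param probe_lt Total labelled probe, nM (> 0).
#' @param fmin,fmax Baseline and saturating polarization, mP.
#' @param top Highest titrant concentration, nM (> 0).
#' @param n_points Number of 2-fold dilutions (>= 6).
#' @param gen A [gen_config()].
#'
#' @return An `rs_titration` data frame (see [titration_curve()]).
#' @examples
#' generate_titration(200, 10, 50, 250, 8000, 14, gen_config(seed = 1))
#' @export
generate_titration <- function(kd, probe_lt, fmin, fmax, top, n_points = 14L,
                               gen = gen_config()) {
  gen <- as_gen_config(gen)
  if (!is.finite(kd) || kd <= 0) stop("'kd' must be > 0", call. = FALSE)
  if (!is.finite(probe_lt) || probe_lt <= 0) {
    stop("'probe_lt' must be > 0", call. = FALSE)
  }
  if (!is.finite(top) || top <= 0) stop("'top' must be > 0", call. = FALSE)
  n_points <- as.integer(n_points)
  if (n_points < 6L) stop("'n_points' must be >= 6", call. = FALSE)

  conc <- top / 2^(seq_len(n_points) - 1L)
  mean_fp <- eval_isotherm(conc, probe_lt, kd, fmin, fmax)
  withr::with_seed(gen$seed, {
    curves <- lapply(seq_len(gen$n_replicates), function(r) {
      fp <- mean_fp + stats::rnorm(n_points, sd = gen$noise_sd)
      data.frame(titrant_nM = conc, FP_mP = fp, replicate = r)
    })
  })
  out <- do.call(rbind, curves)
  out <- titration_curve(out$titrant_nM, out$FP_mP, probe_lt, out$replicate)
  attr(out, "gen_params") <- list(kd = kd, probe_lt = probe_lt, fmin = fmin,
                                  fmax = fmax, top = top,
                                  n_points = n_points,
                                  noise_sd = gen$noise_sd, seed = gen$seed)
  out
}

#' Generate a urea series of two-band emission spectra
#'
#' Builds one synthetic Tyr + Trp emission spectrum per urea concentration on
#' a 280--400 nm grid at 1 nm. The tryptophan band amplitude is fixed and the
#' tyrosine band amplitude is set so that the Tyr/Trp peak-intensity ratio
#' equals the two-state unfolding model [eval_unfolding_ratio()] evaluated at
#' that urea concentration. Gaussian noise of sd `gen$noise_sd` (intensity
#' units) is added pointwise.
#'
#' @param dg Generating unfolding free energy, kcal/mol.
#' @param m Generating urea m-value, kcal/mol/M.
#' @param n_base,d_base Native and denatured baseline ratios.
#' @param urea_grid Urea concentrations, M (each within 0--8).
#' @param band_params List with elements `tyr` and `trp`, each a list with
#'   `peak`, `width`, `asymmetry` (and for `trp` an `amplitude`). Defaults:
#'   Tyr 303/34/1.45, Trp 350/60/1.48 at amplitude 100.
#' @param temperature Temperature, K.
#' @param gen A [gen_config()].
#'
#' @return A list of [emission_spectrum()] objects, one per urea value, with
#'   the generating parameters in the `gen_params` attribute.
#' @export
generate_spectra_series <- function(dg, m, n_base, d_base,
                                    urea_grid = seq(0, 7, by = 0.5),
                                    band_params = NULL,
                                    temperature = 295,
                                    gen = gen_config()) {
  gen <- as_gen_config(gen)
  if (any(urea_grid < 0) || any(urea_grid > 8)) {
    stop("urea grid must lie within [0, 8] M", call. = FALSE)
  }
  bp <- band_params
  if (is.null(bp)) bp <- list()
  tyr <- utils::modifyList(list(peak = 303, width = 34, asymmetry = 1.45),
                           if (is.null(bp$tyr)) list() else bp$tyr)
  trp <- utils::modifyList(list(peak = 350, width = 60, asymmetry = 1.48,
                                amplitude = 100),
                           if (is.null(bp$trp)) list() else bp$trp)
  if (trp$amplitude <= 0) {
    stop("tryptophan band amplitude must be > 0 (ratio undefined otherwise)",
         call. = FALSE)
  }
  wl <- seq(280, 400, by = 1)
  out <- withr::with_seed(gen$seed, {
    lapply(urea_grid, function(x) {
      ratio <- eval_unfolding_ratio(x, dg, m, n_base, d_base, temperature)
      tyr_band <- lognormal_band(ratio * trp$amplitude, tyr$peak, tyr$width,
                                 tyr$asymmetry)
      trp_band <- lognormal_band(trp$amplitude, trp$peak, trp$width,
                                 trp$asymmetry)
      y <- eval_lognormal_band(tyr_band, wl) + eval_lognormal_band(trp_band, wl)
      if (gen$noise_sd > 0) y <- y + stats::rnorm(length(wl), sd = gen$noise_sd)
      emission_spectrum(wl, pmax(y, 0), urea = x)
    })
  })
  attr(out, "gen_params") <- list(dg = dg, m = m, n_base = n_base,
                                  d_base = d_base, temperature = temperature,
                                  tyr = tyr, trp = trp,
                                  noise_sd = gen$noise_sd, seed = gen$seed)
  out
}

#' Generate an RS-repeat peptide sequence
#'
#' Emits stylised arginine/serine-repeat sequences as a character vector of
#' residue codes (three-letter, lower case; `"sep"` marks phosphoserine).
#' Flavors:
#' \describe{
#'   \item{`srsf1-like`}{pure RS repeats, unit `R S` (the SR-protein
#'     prototype).}
#'   \item{`u2af1-like`}{RS clusters separated by a glycine/serine-rich
#'     linker, unit `R S R S G S G S` (moderate net positive charge).}
#'   \item{`bad1-like`}{RS interleaved with RE and RD dipeptides, unit
#'     `R S R E R S R D R S R S` (net positive overall, as in basic-acidic
#'     dipeptide regions).}
#' }
#' A fraction `phospho_fraction` of the serines (selected reproducibly under
#' the seed) is converted to `"sep"`.
#'
#' @param n_repeats Number of repeat units (>= 1).
#' @param phospho_fraction Fraction of serines phosphorylated, in \[0, 1\].
#' @param flavor `"srsf1-like"`, `"u2af1-like"` or `"bad1-like"`.
#' @param gen A [gen_config()].
#'
#' @return Character vector of residue codes with attribute `net_charge`.
#' @examples
#' generate_rs_sequence(5, 1, "srsf1-like", gen_config(seed = 1))
#' @export
generate_rs_sequence <- function(n_repeats, phospho_fraction = 0,
                                 flavor = c("srsf1-like", "u2af1-like",
                                            "bad1-like"),
                                 gen = gen_config()) {
  gen <- as_gen_config(gen)
  flavor <- match.arg(flavor)
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stop("'n_repeats' must be >= 1", call. = FALSE)
  if (phospho_fraction < 0 || phospho_fraction > 1) {
    stop("'phospho_fraction' must be in [0, 1]", call. = FALSE)
  }
  unit <- switch(flavor,
    "srsf1-like" = c("arg", "ser"),
    "u2af1-like" = c("arg", "ser", "arg", "ser", "gly", "ser", "gly", "ser"),
    "bad1-like" = c("arg", "ser", "arg", "glu", "arg", "ser", "arg", "asp",
                    "arg", "ser", "arg", "ser")
  )
  seqv <- rep(unit, n_repeats)
  ser_idx <- which(seqv == "ser")
  n_phos <- round(phospho_fraction * length(ser_idx))
  if (n_phos > 0) {
    chosen <- withr::with_seed(gen$seed,
                               sort(sample(ser_idx, n_phos)))
    seqv[chosen] <- "sep"
  }
  attr(seqv, "net_charge") <- sequence_net_charge(seqv)
  seqv
}

#' Net charge of a residue-code sequence
#'
#' Convention: Arg/Lys +1, Asp/Glu -1, phosphoserine (`sep`) -2, everything
#' else 0 (neutral pH).
#'
#' @param seqv Character vector of lower-case three-letter residue codes.
#' @return Integer net charge.
#' @export
sequence_net_charge <- function(seqv) {
  charges <- c(arg = 1, lys = 1, asp = -1, glu = -1, sep = -2)
  ch <- charges[tolower(seqv)]
  ch[is.na(ch)] <- 0
  sum(ch)
}
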