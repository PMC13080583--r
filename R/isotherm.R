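#' Ligand-depletion fluorescence-polarization binding isotherm
#'
#' Evaluates the exact (quadratic) single-site binding isotherm used for
#' fluorescence-polarization (FP) titrations in which the labelled probe is
#' present at a concentration comparable to the dissociation constant, so
#' that depletion of free titrant by the bound complex cannot be neglected.
#'
#' The polarization signal is
#' \deqn{FP = F_{min} + (F_{max}-F_{min})\,\theta}
#' with bound fraction
#' \deqn{\theta = \frac{(P_T+L_T+K_D) - \sqrt{(P_T+L_T+K_D)^2 - 4 P_T L_T}}{2 L_T}}
#' where \eqn{P_T} is total titrant, \eqn{L_T} total labelled probe and
#' \eqn{K_D} the dissociation constant, all in the same concentration units
#' (nM throughout this package). As \eqn{L_T \to 0} this reduces to the
#' hyperbolic isotherm \eqn{P_T/(P_T+K_D)}, which is used as the analytic
#' limit when `lt = 0`.
#'
#' @param pt Total titrant concentration(s), nM. Vectorised.
#' @param lt Total labelled probe concentration, nM (scalar, >= 0).
#' @param kd Dissociation constant, nM (>= 0).
#' @param fmin Polarization of free probe, mP.
#' @param fmax Polarization of fully bound probe, mP.
#'
#' @return Polarization value(s) in mP, same length as `pt`.
#' @examples
#' eval_isotherm(pt = 200, lt = 10, kd = 200, fmin = 50, fmax = 250)
#' @seealso [fit_isotherm()], [generate_titration()]
#' @export
eval_isotherm <- function(pt, lt, kd, fmin, fmax) {
  if (any(!is.finite(pt)) || any(pt < 0)) {
    stop("'pt' must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(lt) || lt < 0) stop("'lt' must be >= 0", call. = FALSE)
  if (!is.finite(kd) || kd < 0) stop("'kd' must be >= 0", call. = FALSE)
  fmin + (fmax - fmin) * bound_fraction(pt, lt, kd)
}

# Bound fraction theta of the probe; handles the lt -> 0 analytic limit and
# clamps tiny negative round-off at pt = 0.
bound_fraction <- function(pt, lt, kd) {
  if (lt == 0) {
    theta <- ifelse(pt + kd == 0, 0, pt / (pt + kd))
  } else {
    s <- pt + lt + kd
    disc <- pmax(s^2 - 4 * pt * lt, 0)
    theta <- (s - sqrt(disc)) / (2 * lt)
  }
  pmin(pmax(theta, 0), 1)
}

#' Construct a titration curve object
#'
#' A titration curve is a data frame with columns `titrant_nM`, `FP_mP` and
#' `replicate`, plus the probe concentration as an attribute.
#'
#' @param titrant_nM Total titrant concentrations, nM.
#' @param FP_mP Polarization readings, mP.
#' @param probe_nM Total labelled probe concentration, nM (> 0).
#' @param replicate Replicate identifier(s); recycled.
#'
#' @return A `data.frame` of class `rs_titration`.
#' @export
titration_curve <- function(titrant_nM, FP_mP, probe_nM, replicate = 1L) {
  if (length(titrant_nM) != length(FP_mP)) {
    stop("'titrant_nM' and 'FP_mP' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(titrant_nM)) || any(titrant_nM < 0)) {
    stop("titrant concentrations must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(FP_mP))) {
    stop("polarization values must be finite", call. = FALSE)
  }
  if (!is.finite(probe_nM) || probe_nM <= 0) {
    stop("'probe_nM' must be > 0", call. = FALSE)
  }
  out <- data.frame(
    titrant_nM = as.numeric(titrant_nM),
    FP_mP = as.numeric(FP_mP),
    replicate = rep_len(as.integer(replicate), length(titrant_nM))
  )
  attr(out, "probe_nM") <- as.numeric(probe_nM)
  class(out) <- c("rs_titration", "data.frame")
  out
}

#' Fit the ligand-depletion isotherm to one or more titration replicates
#'
#' Nonlinear least squares over \eqn{(K_D, F_{min}, F_{max})} with the probe
#' concentration fixed at its known value. Replicates (distinct values of the
#' `replicate` column, or a list of curves) are fitted independently; the
#' reported `kd` is the mean across replicate estimates and `kd_sd` the
#' standard deviation across them. With a single replicate `kd_sd` is the
#' asymptotic standard error of the fit. Starting values are
#' `fmin = min(FP)`, `fmax = max(FP)` and `kd` at the titrant concentration
#' closest to half signal span; `kd` is bounded to (1e-3, 1e9) nM during
#' optimisation.
#'
#' @param curve An `rs_titration` (possibly containing several replicates), a
#'   plain data frame with columns `titrant_nM`, `FP_mP` (and optionally
#'   `replicate`), or a list of such curves.
#' @param probe_nM Probe concentration, nM. Defaults to the `probe_nM`
#'   attribute of `curve`.
#' @param top_titrant Highest titrant concentration used for the
#'   determinability call; defaults to `max(titrant_nM)`.
#'
#' @return A list of class `rs_binding_fit` with elements `kd`, `fmin`,
#'   `fmax`, `kd_sd`, `kd_sd_kind` (`"replicate"` or `"asymptotic"`),
#'   `converged`, `determinable`, `determinability_rule`, `residual_rms`,
#'   `n_replicates` and `replicate_kd`.
#' @examples
#' gen <- gen_config(seed = 1, noise_sd = 0)
#' cur <- generate_titration(kd = 200, probe_lt = 10, fmin = 50, fmax = 250,
#'                           top = 8000, n_points = 14, gen = gen)
#' fit <- fit_isotherm(cur)
#' fit$kd
#' @export
fit_isotherm <- function(curve, probe_nM = NULL, top_titrant = NULL) {
  curves <- split_replicates(curve)
  if (is.null(probe_nM)) {
    probe_nM <- attr(curves[[1L]], "probe_nM")
  }
  if (is.null(probe_nM) || !is.finite(probe_nM) || probe_nM <= 0) {
    stop("a positive 'probe_nM' is required", call. = FALSE)
  }

  fits <- lapply(curves, fit_isotherm_single, probe_nM = probe_nM)
  kds <- vapply(fits, function(f) f$kd, numeric(1))
  conv <- vapply(fits, function(f) f$converged, logical(1))
  rms <- vapply(fits, function(f) f$residual_rms, numeric(1))
  span <- vapply(fits, function(f) f$fmax - f$fmin, numeric(1))

  if (length(fits) >= 2L) {
    kd_sd <- stats::sd(kds)
    kd_sd_kind <- "replicate"
  } else {
    kd_sd <- fits[[1L]]$kd_se
    kd_sd_kind <- "asymptotic"
  }

  if (is.null(top_titrant)) {
    top_titrant <- max(unlist(lapply(curves, function(d) d$titrant_nM)))
  }

  res <- structure(
    list(
      kd = mean(kds),
      fmin = mean(vapply(fits, function(f) f$fmin, numeric(1))),
      fmax = mean(vapply(fits, function(f) f$fmax, numeric(1))),
      kd_sd = kd_sd,
      kd_sd_kind = kd_sd_kind,
      converged = all(conv),
      residual_rms = mean(rms),
      signal_span = mean(span),
      n_replicates = length(fits),
      replicate_kd = kds,
      probe_nM = probe_nM,
      top_titrant = top_titrant
    ),
    class = "rs_binding_fit"
  )
  cls <- classify_determinability(res, top_titrant)
  res$determinable <- cls
  res$determinability_rule <- attr(cls, "rule")
  res
}

split_replicates <- function(curve) {
  if (is.list(curve) && !is.data.frame(curve)) {
    curves <- lapply(curve, as_titration_df)
  } else {
    df <- as_titration_df(curve)
    curves <- split(df, df$replicate)
    curves <- lapply(curves, function(d) {
      attr(d, "probe_nM") <- attr(df, "probe_nM")
      d
    })
  }
  if (!length(curves)) stop("no titration data supplied", call. = FALSE)
  curves
}

as_titration_df <- function(curve) {
  if (!is.data.frame(curve) ||
      !all(c("titrant_nM", "FP_mP") %in% names(curve))) {
    stop("a titration needs columns 'titrant_nM' and 'FP_mP'", call. = FALSE)
  }
  if (is.null(curve$replicate)) curve$replicate <- 1L
  if (any(!is.finite(curve$titrant_nM)) || any(!is.finite(curve$FP_mP))) {
    stop("non-finite values in titration data", call. = FALSE)
  }
  curve
}

fit_isotherm_single <- function(df, probe_nM) {
  n <- nrow(df)
  if (n < 4L) {
    stop("need at least 4 points to fit 3 parameters", call. = FALSE)
  }
  pos <- df$titrant_nM[df$titrant_nM > 0]
  if (length(unique(pos)) >= 2L &&
      log10(max(pos) / min(pos)) < 1) {
    warning("titrant spans less than one order of magnitude; fit may be poor")
  }
  fmin0 <- min(df$FP_mP)
  fmax0 <- max(df$FP_mP)
  half <- (fmin0 + fmax0) / 2
  kd0 <- df$titrant_nM[which.min(abs(df$FP_mP - half))]
  kd0 <- min(max(kd0, 1e-3), 1e9)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      FP_mP ~ eval_isotherm(titrant_nM, probe_nM, kd, fmin, fmax),
      data = df,
      start = list(kd = kd0, fmin = fmin0, fmax = fmax0),
      lower = c(kd = 1e-3, fmin = -Inf, fmax = -Inf),
      upper = c(kd = 1e9, fmin = Inf, fmax = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    return(list(kd = NA_real_, fmin = fmin0, fmax = fmax0, kd_se = NA_real_,
                converged = FALSE,
                residual_rms = stats::sd(df$FP_mP)))
  }
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["kd", "Std. Error"],
                 error = function(e) NA_real_)
  list(
    kd = unname(co["kd"]),
    fmin = unname(co["fmin"]),
    fmax = unname(co["fmax"]),
    kd_se = se,
    converged = isTRUE(fit$convInfo$isConv) || inherits(fit, "nls"),
    residual_rms = sqrt(mean(stats::resid(fit)^2))
  )
}

#' Classify whether a fitted affinity is determinable
#'
#' A binding fit is reported as not determinable ("too weak to be
#' determined") when any of three rules fires: (1) the optimiser failed to
#' converge, (2) the fitted \eqn{K_D} exceeds the highest titrant
#' concentration used, so the affinity is an extrapolation, or (3) the fitted
#' signal span \eqn{F_{max}-F_{min}} is smaller than three times the residual
#' root-mean-square, i.e. there is no significant binding signal.
#'
#' @param fit An `rs_binding_fit` object (or a compatible list).
#' @param top_titrant Highest titrant concentration of the design, nM.
#'
#' @return Logical flag; attribute `"rule"` names the rule that fired
#'   (`"converged"`, `"kd_above_top"`, `"low_signal"`) or `"ok"`.
#' @export
classify_determinability <- function(fit, top_titrant) {
  if (!isTRUE(fit$converged) || !is.finite(fit$kd)) {
    return(structure(FALSE, rule = "converged"))
  }
  if (fit$kd > top_titrant) {
    return(structure(FALSE, rule = "kd_above_top"))
  }
  span <- abs(fit$fmax - fit$fmin)
  if (span < 3 * fit$residual_rms) {
    return(structure(FALSE, rule = "low_signal"))
  }
  structure(TRUE, rule = "ok")
}

#' @export
print.rs_binding_fit <- function(x, ...) {
  cat("<rs_binding_fit>\n")
  if (isTRUE(x$determinable)) {
    cat(sprintf("  Kd      : %.4g nM (sd %.3g, %s)\n",
                x$kd, x$kd_sd, x$kd_sd_kind))
  } else {
    cat(sprintf("  Kd      : too weak to be determined [%s]\n",
                x$determinability_rule))
  }
  cat(sprintf("  Fmin    : %.4g mP\n  Fmax    : %.4g mP\n", x$fmin, x$fmax))
  cat(sprintf("  repl.   : %d, residual rms %.3g mP\n",
              x$n_replicates, x$residual_rms))
  invisible(x)
}
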