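INTERACTION_KINDS <- c("salt_bridge", "hbond", "pi_pi", "cation_pi",
                       "cation_cation")

#' Per-frame interaction census over an analysis window
#'
#' Runs all detectors on every frame of the analysis window and reports the
#' mean number of events per frame for each interaction kind, partitioned
#' into intrachain and interchain contacts. The default analysis window is
#' the trailing `window_ns` nanoseconds of the trajectory: at the standard
#' 150 ps snapshot interval a 150 ns window contains exactly 1000 frames.
#'
#' @param traj An `rs_trajectory`.
#' @param config A [geometry_config()].
#' @param window_ns Length of the trailing analysis window in ns, or `NULL`
#'   to use every frame.
#' @param hbonds Include hydrogen-bond detection.
#' @return A data frame of class `rs_frame_summary` with columns `kind`,
#'   `span` and `mean_per_frame`; attributes `n_frames` (window size) and
#'   `counts` (the per-frame count matrix).
#' @export
summarize_frames <- function(traj, config = geometry_config(),
                             window_ns = NULL, hbonds = TRUE) {
  stopifnot(inherits(traj, "rs_trajectory"))
  nf <- n_frames(traj)
  if (is.null(window_ns)) {
    idx <- seq_len(nf)
  } else {
    nw <- as.integer(round(window_ns * 1000 / traj$frame_interval_ps))
    if (nw < 1L) stop("empty analysis window", call. = FALSE)
    if (nw > nf) {
      stop(sprintf("window of %d frames exceeds trajectory length %d",
                   nw, nf), call. = FALSE)
    }
    idx <- seq.int(nf - nw + 1L, nf)
  }

  keys <- expand.grid(kind = INTERACTION_KINDS, span = c("intra", "inter"),
                      stringsAsFactors = FALSE)
  counts <- matrix(0, nrow = length(idx), ncol = nrow(keys),
                   dimnames = list(NULL, paste(keys$kind, keys$span)))
  for (w in seq_along(idx)) {
    ev <- detect_frame_events(frame_atoms(traj, idx[w]), config,
                              hbonds = hbonds)
    if (nrow(ev)) {
      tab <- table(paste(ev$kind, ev$span))
      counts[w, names(tab)] <- as.numeric(tab)
    }
  }
  out <- keys
  out$mean_per_frame <- colMeans(counts)
  class(out) <- c("rs_frame_summary", "data.frame")
  attr(out, "n_frames") <- length(idx)
  attr(out, "counts") <- counts
  out
}

#' Aggregate frame summaries across replicate simulations
#'
#' @param summaries A list of at least two [summarize_frames()] results with
#'   matching kind/span keys (e.g. three replicate simulations started from
#'   different conformations).
#' @return A data frame of class `rs_replicate_summary` with columns `kind`,
#'   `span`, `mean` and `sd` (standard deviation across replicates).
#' @export
aggregate_replicates <- function(summaries) {
  if (!is.list(summaries) || length(summaries) < 2L) {
    stop("need at least 2 replicate summaries", call. = FALSE)
  }
  key0 <- paste(summaries[[1]]$kind, summaries[[1]]$span)
  mat <- vapply(summaries, function(s) {
    if (!identical(paste(s$kind, s$span), key0)) {
      stop("replicate summaries have mismatched kind/span keys",
           call. = FALSE)
    }
    s$mean_per_frame
  }, numeric(length(key0)))
  out <- data.frame(kind = summaries[[1]]$kind, span = summaries[[1]]$span,
                    mean = rowMeans(mat), sd = apply(mat, 1, stats::sd),
                    stringsAsFactors = FALSE)
  class(out) <- c("rs_replicate_summary", "data.frame")
  out
}

#' Per-residue salt-bridge profile
#'
#' For each residue of the requested chain, the mean number of salt-bridge
#' events per frame in which that residue participates; an event within the
#' profiled chain increments both of its residues. The overall mean across
#' residues (the dashed-line average of per-residue plots) is returned in
#' the `overall_mean` attribute and equals `mean(mean_salt_bridges)` by
#' construction.
#'
#' @param traj An `rs_trajectory`.
#' @param chain Chain ID to profile.
#' @param config A [geometry_config()].
#' @param window_ns Trailing window in ns, or `NULL` for all frames.
#' @return Data frame of class `rs_residue_profile` with columns `resindex`,
#'   `resname`, `mean_salt_bridges`; attributes `overall_mean`, `n_frames`.
#' @export
per_residue_profile <- function(traj, chain, config = geometry_config(),
                                window_ns = NULL) {
  stopifnot(inherits(traj, "rs_trajectory"))
  if (!chain %in% traj$chain_ids) {
    stop("chain '", chain, "' not present in trajectory", call. = FALSE)
  }
  nf <- n_frames(traj)
  if (is.null(window_ns)) {
    idx <- seq_len(nf)
  } else {
    nw <- as.integer(round(window_ns * 1000 / traj$frame_interval_ps))
    if (nw < 1L || nw > nf) stop("invalid analysis window", call. = FALSE)
    idx <- seq.int(nf - nw + 1L, nf)
  }
  res <- unique(traj$atoms[traj$atoms$chain == chain,
                           c("resindex", "resname")])
  res <- res[order(res$resindex), , drop = FALSE]
  acc <- setNames(numeric(nrow(res)), res$resindex)
  for (f in idx) {
    ev <- detect_salt_bridges(frame_atoms(traj, f), config)
    if (!nrow(ev)) next
    for (k in seq_len(nrow(ev))) {
      if (ev$chain_a[k] == chain) {
        key <- as.character(ev$res_a[k])
        acc[key] <- acc[key] + 1
      }
      if (ev$chain_b[k] == chain) {
        key <- as.character(ev$res_b[k])
        acc[key] <- acc[key] + 1
      }
    }
  }
  out <- data.frame(resindex = res$resindex, resname = res$resname,
                    mean_salt_bridges = as.numeric(acc) / length(idx),
                    stringsAsFactors = FALSE)
  class(out) <- c("rs_residue_profile", "data.frame")
  attr(out, "overall_mean") <- mean(out$mean_salt_bridges)
  attr(out, "n_frames") <- length(idx)
  out
}

#' Backbone RMSD series with equilibration check
#'
#' Computes the per-frame backbone (N, CA, C, O) root-mean-square deviation
#' after optimal (Kabsch) superposition onto a reference frame, and flags
#' the trajectory as equilibrated when the magnitude of the best-fit linear
#' slope of RMSD versus time over the trailing window is below
#' `slope_threshold`.
#'
#' @param traj An `rs_trajectory`.
#' @param reference_frame Index of the reference frame (default 1).
#' @param trailing_frac Fraction of frames (from the end) used for the
#'   slope check.
#' @param slope_threshold Equilibration threshold in Angstrom/ns.
#' @return List with `rmsd` (Angstrom per frame), `time_ns`, `slope`
#'   (Angstrom/ns over the trailing window, NA when the window has fewer
#'   than 3 frames) and `equilibrated`.
#' @export
backbone_rmsd_series <- function(traj, reference_frame = 1L,
                                 trailing_frac = 0.5,
                                 slope_threshold = 0.002) {
  stopifnot(inherits(traj, "rs_trajectory"))
  bb <- which(traj$atoms$name %in% c("N", "CA", "C", "O"))
  if (length(bb) < 3L) {
    stop("need at least 3 backbone atoms for superposition", call. = FALSE)
  }
  nf <- n_frames(traj)
  if (reference_frame < 1L || reference_frame > nf) {
    stop("reference frame out of range", call. = FALSE)
  }
  to_xyz <- function(f) as.vector(t(traj$coords[bb, , f]))
  ref <- to_xyz(reference_frame)
  mat <- t(vapply(seq_len(nf), to_xyz, numeric(3L * length(bb))))
  inds <- seq_len(3L * length(bb))
  rmsd <- bio3d::rmsd(ref, mat, a.inds = inds, b.inds = inds, fit = TRUE)
  time_ns <- (seq_len(nf) - 1L) * traj$frame_interval_ps / 1000

  nw <- max(2L, ceiling(trailing_frac * nf))
  idx <- seq.int(nf - nw + 1L, nf)
  if (length(idx) >= 3L && diff(range(time_ns[idx])) > 0) {
    slope <- unname(stats::coef(stats::lm(rmsd[idx] ~ time_ns[idx]))[2])
    equilibrated <- abs(slope) < slope_threshold
  } else {
    slope <- NA_real_
    equilibrated <- NA
  }
  list(rmsd = as.numeric(rmsd), time_ns = time_ns, slope = slope,
       equilibrated = equilibrated)
}
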