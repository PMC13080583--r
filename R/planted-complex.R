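# Idealised residue geometry for planted-complex fixtures: a backbone trace
# (N, H, CA, C, O) plus one interaction site per functional group, with all
# planar groups parallel to the xy-plane so that planted stacks have exact
# 0-degree inter-plane angles. Offsets are relative to CA.
residue_template <- function(resname) {
  bb <- rbind(
    N = c(-1.46, 0.00, 0.00),
    H = c(-1.46, 1.00, 0.00),
    CA = c(0.00, 0.00, 0.00),
    C = c(1.52, 0.00, 0.00),
    O = c(2.15, 1.05, 0.00)
  )
  side <- switch(toupper(resname),
    ARG = rbind(NE = c(1.33, 0, 3.0), CZ = c(0, 0, 3.0),
                NH1 = c(-0.66, 1.15, 3.0), NH2 = c(-0.66, -1.15, 3.0),
                HE = c(2.33, 0, 3.0), HH11 = c(-1.16, 2.02, 3.0),
                HH21 = c(-1.16, -2.02, 3.0)),
    LYS = rbind(NZ = c(0, 0, 3.2), HZ1 = c(1.0, 0, 3.2)),
    ASP = rbind(CG = c(0, 0, 2.5), OD1 = c(1.1, 0, 3.1),
                OD2 = c(-1.1, 0, 3.1)),
    GLU = rbind(CD = c(0, 0, 3.0), OE1 = c(1.1, 0, 3.6),
                OE2 = c(-1.1, 0, 3.6)),
    SEP = rbind(OG = c(0, 0, 2.4), P = c(0, 0, 4.0),
                O1P = c(1.42, 0, 4.5), O2P = c(-0.71, 1.23, 4.5),
                O3P = c(-0.71, -1.23, 4.5)),
    SER = rbind(OG = c(0, 0, 2.4), HG = c(1.0, 0, 2.4)),
    THR = rbind(OG1 = c(0, 0, 2.4), HG1 = c(1.0, 0, 2.4)),
    ASN = rbind(CG = c(0, 0, 2.5), OD1 = c(1.1, 0, 3.1),
                ND2 = c(-1.1, 0, 3.1), HD21 = c(-1.1, 1.0, 3.1)),
    GLN = rbind(CD = c(0, 0, 3.0), OE1 = c(1.1, 0, 3.6),
                NE2 = c(-1.1, 0, 3.6), HE21 = c(-1.1, 1.0, 3.6)),
    PHE = ,
    TYR = {
      ang <- seq(0, 300, by = 60) * pi / 180
      m <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 3.5)
      rownames(m) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      m
    },
    TRP = {
      ang <- seq(0, 300, by = 60) * pi / 180
      m <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 3.5)
      rownames(m) <- c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
      m
    },
    HIS = {
      ang <- seq(90, 378, by = 72)[1:5] * pi / 180
      m <- cbind(1.16 * cos(ang), 1.16 * sin(ang), 3.3)
      rownames(m) <- c("CG", "ND1", "CE1", "NE2", "CD2")
      m
    },
    NULL
  )
  rbind(bb, side)
}

# key atoms used to anchor planted poses
sb_donor_key <- c(ARG = "NH1", LYS = "NZ")
sb_acceptor_key <- c(ASP = "OD1", GLU = "OE1", SEP = "O1P")
hb_donor_key <- c(SER = "OG", THR = "OG1")
hb_acceptor_key <- c(ASN = "OD1", GLN = "OE1")

plane_group_key <- function(resname) {
  switch(toupper(resname),
         ARG = PLANE_GROUPS$ARG$guanidinium,
         PHE = PLANE_GROUPS$PHE$ring, TYR = PLANE_GROUPS$TYR$ring,
         HIS = PLANE_GROUPS$HIS$ring, TRP = PLANE_GROUPS$TRP$ring6,
         NULL)
}

SB_DONOR_RES <- c("ARG", "LYS")
SB_ACCEPTOR_RES <- c("ASP", "GLU", "SEP")
HB_DONOR_RES <- c("SER", "THR")
HB_ACCEPTOR_RES <- c("ASN", "GLN")
STACK_RES <- c("ARG", "PHE", "TYR", "TRP", "HIS")

#' Specification of a two-chain complex with planted interactions
#'
#' Describes the ground truth for a synthetic coordinate ensemble: the
#' residue sequences of chains A and B and the lists of residue pairs that
#' must form salt bridges, hydrogen bonds or stacking interactions in every
#' frame. Pairs are given as 4-element vectors `c(chain1, resindex1,
#' chain2, resindex2)`; intra-chain pairs are allowed. Each residue may take
#' part in at most one planted interaction. Residue types must be
#' chemically compatible with the planted interaction: salt bridges pair an
#' Arg/Lys with an Asp/Glu/phosphoserine; hydrogen bonds pair a Ser/Thr
#' donor with an Asn/Gln acceptor; stacks pair residues from Arg and the
#' aromatics (classified pi-pi, cation-pi or cation-cation from the residue
#' types).
#'
#' @param chain_a_seq,chain_b_seq Character vectors of lower-case
#'   three-letter residue codes (`"sep"` = phosphoserine); `chain_b_seq` may
#'   be `NULL` for a single-chain system.
#' @param planted_salt_bridges,planted_hbonds,planted_stacks Lists of
#'   4-element pair vectors (possibly empty).
#' @param n_frames Number of frames to generate (>= 1).
#'
#' @return An object of class `planted_complex_spec`.
#' @export
planted_complex_spec <- function(chain_a_seq, chain_b_seq = NULL,
                                 planted_salt_bridges = list(),
                                 planted_hbonds = list(),
                                 planted_stacks = list(),
                                 n_frames = 10L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("'n_frames' must be >= 1", call. = FALSE)
  chains <- list(A = toupper(as.character(chain_a_seq)))
  if (!is.null(chain_b_seq)) chains$B <- toupper(as.character(chain_b_seq))
  for (cn in names(chains)) {
    bad <- setdiff(chains[[cn]], KNOWN_RESIDUES)
    if (length(bad)) {
      stop("unknown residue code(s) in chain ", cn, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  spec <- structure(
    list(chains = chains,
         planted = list(salt_bridge = normalize_pairs(planted_salt_bridges),
                        hbond = normalize_pairs(planted_hbonds),
                        stack = normalize_pairs(planted_stacks)),
         n_frames = n_frames),
    class = "planted_complex_spec"
  )
  validate_planted_spec(spec)
  spec
}

normalize_pairs <- function(pairs) {
  if (!length(pairs)) {
    return(data.frame(chain_1 = character(), res_1 = integer(),
                      chain_2 = character(), res_2 = integer(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(pairs, function(p) {
    if (length(p) != 4L) {
      stop("planted pairs must be c(chain1, res1, chain2, res2)",
           call. = FALSE)
    }
    data.frame(chain_1 = toupper(as.character(p[[1]])),
               res_1 = as.integer(p[[2]]),
               chain_2 = toupper(as.character(p[[3]])),
               res_2 = as.integer(p[[4]]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

validate_planted_spec <- function(spec) {
  resname_at <- function(chain, idx) {
    if (!chain %in% names(spec$chains)) {
      stop("planted pair references missing chain ", chain, call. = FALSE)
    }
    seqv <- spec$chains[[chain]]
    if (idx < 1L || idx > length(seqv)) {
      stop(sprintf("planted pair references residue %s%d beyond chain length %d",
                   chain, idx, length(seqv)), call. = FALSE)
    }
    seqv[idx]
  }
  used <- character()
  for (kind in names(spec$planted)) {
    pp <- spec$planted[[kind]]
    for (k in seq_len(nrow(pp))) {
      r1 <- resname_at(pp$chain_1[k], pp$res_1[k])
      r2 <- resname_at(pp$chain_2[k], pp$res_2[k])
      k1 <- res_key(pp$chain_1[k], pp$res_1[k])
      k2 <- res_key(pp$chain_2[k], pp$res_2[k])
      if (k1 == k2) stop("planted pair references the same residue twice",
                         call. = FALSE)
      if (any(c(k1, k2) %in% used)) {
        stop("infeasible placement: residue used in more than one planted ",
             "interaction", call. = FALSE)
      }
      used <- c(used, k1, k2)
      ok <- switch(kind,
        salt_bridge = (r1 %in% SB_DONOR_RES && r2 %in% SB_ACCEPTOR_RES) ||
                      (r2 %in% SB_DONOR_RES && r1 %in% SB_ACCEPTOR_RES),
        hbond = (r1 %in% HB_DONOR_RES && r2 %in% HB_ACCEPTOR_RES) ||
                (r2 %in% HB_DONOR_RES && r1 %in% HB_ACCEPTOR_RES),
        stack = r1 %in% STACK_RES && r2 %in% STACK_RES
      )
      if (!ok) {
        stop(sprintf("residue types %s/%s are incompatible with a planted %s",
                     r1, r2, kind), call. = FALSE)
      }
    }
  }
  invisible(spec)
}

# Margins between planted geometry and the detector thresholds (defaults):
# salt bridge 3.0 vs 4.0 A; H-bond 2.9 vs 3.5 A; stack 3.8 vs 4.5 A. The
# per-frame rigid-translation jitter of each residue is capped at 40% of
# the smallest margin (0.6 A), so a pairwise distance can change by at most
# 0.48 A and no planted or absent interaction can cross its threshold.
JITTER_BOUND <- 0.4 * 0.6

#' Build a coordinate ensemble with planted, exactly counted interactions
#'
#' Constructs an idealised multi-frame two-chain system in which every
#' planted interaction satisfies the detector criteria with a safety margin
#' and every non-planted residue pair violates them by a wide margin.
#' Backbone traces are laid out on a coarse grid (24 Angstrom residue
#' spacing, chains 40 Angstrom apart); the functional groups of planted
#' pairs are brought together at staggered anchor points well away from all
#' other sites. Per-frame Gaussian jitter (sd `gen$noise_sd` Angstrom,
#' truncated at 40% of the smallest geometry margin) translates each
#' residue rigidly, so detector labels never flip across frames. The
#' resulting per-frame ground truth is attached as attribute
#' `ground_truth`.
#'
#' @param spec A [planted_complex_spec()].
#' @param gen A [gen_config()]; `noise_sd` is the coordinate jitter in
#'   Angstrom.
#' @return An `rs_trajectory` with attributes `ground_truth` (event table
#'   with `kind`, `chain_a`, `res_a`, `chain_b`, `res_b`, `span`, constant
#'   across frames) and `ground_truth_counts` (per kind x span).
#' @examples
#' spec <- planted_complex_spec(
#'   chain_a_seq = c("arg", "ser", "arg"),
#'   chain_b_seq = c("sep", "ser", "glu"),
#'   planted_salt_bridges = list(c("A", 1, "B", 1), c("A", 3, "B", 3)),
#'   n_frames = 5
#' )
#' traj <- build_planted_complex(spec, gen_config(seed = 1, noise_sd = 0.05))
#' @export
build_planted_complex <- function(spec, gen = gen_config()) {
  stopifnot(inherits(spec, "planted_complex_spec"))
  gen <- as_gen_config(gen)

  chain_offsets <- c(A = 0, B = 40)
  ca_pos <- function(chain, idx) {
    c(24 * (idx - 1), unname(chain_offsets[chain]), 0)
  }

  # base atoms: default template pose at each CA
  atoms <- list()
  coords <- list()
  for (cn in names(spec$chains)) {
    seqv <- spec$chains[[cn]]
    for (i in seq_along(seqv)) {
      tmpl <- residue_template(seqv[i])
      pos <- sweep(tmpl, 2, ca_pos(cn, i), "+")
      atoms[[length(atoms) + 1L]] <- data.frame(
        name = rownames(tmpl), resname = toupper(seqv[i]),
        resindex = i, chain = cn, stringsAsFactors = FALSE
      )
      coords[[length(coords) + 1L]] <- pos
    }
  }
  atoms <- do.call(rbind, atoms)
  base <- do.call(rbind, coords)
  rownames(base) <- NULL

  # re-pose the functional groups of planted pairs at staggered anchors
  truth <- empty_events()
  k_ord <- 0L
  move_group <- function(chain, idx, atom_names, target, key_atom) {
    rows <- which(atoms$chain == chain & atoms$resindex == idx &
                  atoms$name %in% atom_names)
    key_row <- which(atoms$chain == chain & atoms$resindex == idx &
                     atoms$name == key_atom)
    shift <- target - base[key_row, ]
    base[rows, ] <<- sweep(base[rows, , drop = FALSE], 2, shift, "+")
  }
  side_chain_names <- function(chain, idx) {
    rn <- atoms$resname[atoms$chain == chain & atoms$resindex == idx][1]
    setdiff(rownames(residue_template(rn)), c("N", "H", "CA", "C", "O"))
  }

  for (kind in c("salt_bridge", "hbond", "stack")) {
    pp <- spec$planted[[kind]]
    for (k in seq_len(nrow(pp))) {
      k_ord <- k_ord + 1L
      c1 <- pp$chain_1[k]; r1 <- pp$res_1[k]
      c2 <- pp$chain_2[k]; r2 <- pp$res_2[k]
      rn1 <- spec$chains[[c1]][r1]
      rn2 <- spec$chains[[c2]][r2]
      p1 <- ca_pos(c1, r1); p2 <- ca_pos(c2, r2)
      anchor <- (p1 + p2) / 2 + c(0, 0, 15 * k_ord)
      u <- p2 - p1
      u[3] <- 0
      if (sqrt(sum(u^2)) < 1e-9) u <- c(1, 0, 0) else u <- u / sqrt(sum(u^2))

      if (kind == "salt_bridge") {
        if (!(rn1 %in% SB_DONOR_RES)) {
          tmp <- c1; c1 <- c2; c2 <- tmp
          tmp <- r1; r1 <- r2; r2 <- tmp
          tmp <- rn1; rn1 <- rn2; rn2 <- tmp
          u <- -u
        }
        move_group(c1, r1, side_chain_names(c1, r1), anchor - 1.5 * u,
                   sb_donor_key[[rn1]])
        move_group(c2, r2, side_chain_names(c2, r2), anchor + 1.5 * u,
                   sb_acceptor_key[[rn2]])
        ev_kind <- "salt_bridge"
      } else if (kind == "hbond") {
        if (!(rn1 %in% HB_DONOR_RES)) {
          tmp <- c1; c1 <- c2; c2 <- tmp
          tmp <- r1; r1 <- r2; r2 <- tmp
          tmp <- rn1; rn1 <- rn2; rn2 <- tmp
          u <- -u
        }
        # donor O at anchor, its H at anchor + 1 A along u, acceptor O at
        # 2.9 A: a perfectly linear D-H...A geometry
        okey <- hb_donor_key[[rn1]]
        hkey <- if (rn1 == "SER") "HG" else "HG1"
        rows_o <- which(atoms$chain == c1 & atoms$resindex == r1 &
                        atoms$name == okey)
        rows_h <- which(atoms$chain == c1 & atoms$resindex == r1 &
                        atoms$name == hkey)
        base[rows_o, ] <- anchor
        base[rows_h, ] <- anchor + 1.0 * u
        move_group(c2, r2, side_chain_names(c2, r2), anchor + 2.9 * u,
                   hb_acceptor_key[[rn2]])
        ev_kind <- "hbond"
      } else {
        g1 <- plane_group_key(rn1)
        g2 <- plane_group_key(rn2)
        move_centroid <- function(chain, idx, grp, target) {
          rows <- which(atoms$chain == chain & atoms$resindex == idx &
                        atoms$name %in% grp)
          cen <- colMeans(base[rows, , drop = FALSE])
          all_rows <- which(atoms$chain == chain & atoms$resindex == idx &
                            atoms$name %in% side_chain_names(chain, idx))
          base[all_rows, ] <<- sweep(base[all_rows, , drop = FALSE], 2,
                                     target - cen, "+")
        }
        move_centroid(c1, r1, g1, anchor)
        move_centroid(c2, r2, g2, anchor + c(0, 0, 3.8))
        ev_kind <- stacking_kind(rn1, rn2)
      }
      truth <- rbind(truth, make_events(ev_kind, c1, r1, c2, r2,
                                        NA_real_, NA_real_))
    }
  }

  # per-frame rigid-translation jitter, truncated so labels cannot flip
  natoms <- nrow(atoms)
  res_ids <- res_key(atoms$chain, atoms$resindex)
  res_levels <- unique(res_ids)
  coords <- array(NA_real_, dim = c(natoms, 3, spec$n_frames))
  sd_eff <- min(gen$noise_sd, JITTER_BOUND)
  withr::with_seed(gen$seed, {
    for (f in seq_len(spec$n_frames)) {
      frame <- base
      if (sd_eff > 0) {
        for (rk in res_levels) {
          g <- stats::rnorm(3, sd = sd_eff)
          nrm <- sqrt(sum(g^2))
          if (nrm > JITTER_BOUND) g <- g * JITTER_BOUND / nrm
          rows <- which(res_ids == rk)
          frame[rows, ] <- sweep(frame[rows, , drop = FALSE], 2, g, "+")
        }
      }
      coords[, , f] <- frame
    }
  })

  traj <- rs_trajectory(atoms, coords, frame_interval_ps = 150)
  truth <- truth[order(truth$kind, truth$chain_a, truth$res_a), , drop = FALSE]
  rownames(truth) <- NULL
  attr(traj, "ground_truth") <- truth
  attr(traj, "ground_truth_counts") <- truth_counts(truth)
  attr(traj, "gen_params") <- list(seed = gen$seed, noise_sd = gen$noise_sd,
                                   n_frames = spec$n_frames)
  traj
}

truth_counts <- function(truth) {
  keys <- expand.grid(kind = INTERACTION_KINDS, span = c("intra", "inter"),
                      stringsAsFactors = FALSE)
  cnt <- numeric(nrow(keys))
  if (nrow(truth)) {
    tab <- table(paste(truth$kind, truth$span))
    m <- match(paste(keys$kind, keys$span), names(tab))
    cnt[!is.na(m)] <- as.numeric(tab[m[!is.na(m)]])
  }
  keys$count <- cnt
  keys
}

#' Write / read a planted-complex ground truth sidecar
#'
#' @param truth Ground-truth event table (attribute `ground_truth` of
#'   [build_planted_complex()] output).
#' @param path JSON file path.
#' @return `path` invisibly (write); the event data frame (read).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  out <- jsonlite::fromJSON(path)
  if (!length(out)) return(empty_events()[, 1:6])
  out$res_a <- as.integer(out$res_a)
  out$res_b <- as.integer(out$res_b)
  out
}
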