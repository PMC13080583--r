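#' Geometric criteria for the interaction census
#'
#' Thresholds used by the detectors. Stacking uses a centroid distance
#' cutoff of 4.5 Angstrom and an inter-plane angle threshold of 20 degrees.
#' Salt bridges use a 4.0 Angstrom cutoff between donor side-chain nitrogens
#' (Arg NE/NH1/NH2, Lys NZ) and acceptor side-chain oxygens (Asp OD1/OD2,
#' Glu OE1/OE2, phosphoserine O1P/O2P/O3P/OG). Hydrogen bonds use a
#' heavy-atom donor-acceptor cutoff of 3.5 Angstrom and require the
#' donor-H-acceptor angle to be at least 180 minus `hbond_angle_cutoff`
#' degrees.
#'
#' @param stack_dist_cutoff Centroid-centroid cutoff, Angstrom.
#' @param stack_angle_cutoff Inter-plane angle threshold, degrees (0, 90].
#' @param saltbridge_cutoff Donor-N to acceptor-O cutoff, Angstrom.
#' @param hbond_dist_cutoff Donor to acceptor heavy-atom cutoff, Angstrom.
#' @param hbond_angle_cutoff Allowed deviation from linearity of the
#'   donor-H-acceptor angle, degrees (0, 90].
#'
#' @return An object of class `geometry_config`.
#' @export
geometry_config <- function(stack_dist_cutoff = 4.5,
                            stack_angle_cutoff = 20,
                            saltbridge_cutoff = 4.0,
                            hbond_dist_cutoff = 3.5,
                            hbond_angle_cutoff = 45) {
  vals <- c(stack_dist_cutoff, stack_angle_cutoff, saltbridge_cutoff,
            hbond_dist_cutoff, hbond_angle_cutoff)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry cutoffs must be positive", call. = FALSE)
  }
  if (stack_angle_cutoff > 90 || hbond_angle_cutoff > 90) {
    stop("angle cutoffs must lie in (0, 90]", call. = FALSE)
  }
  structure(
    list(stack_dist_cutoff = stack_dist_cutoff,
         stack_angle_cutoff = stack_angle_cutoff,
         saltbridge_cutoff = saltbridge_cutoff,
         hbond_dist_cutoff = hbond_dist_cutoff,
         hbond_angle_cutoff = hbond_angle_cutoff),
    class = "geometry_config"
  )
}

# --- site tables ------------------------------------------------------------

SALT_DONOR_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
SALT_ACCEPTOR_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                            SEP = c("O1P", "O2P", "O3P", "OG"))

# H-bond donor heavy atoms by residue; "*" applies to every residue
# (backbone amide nitrogen). Hydrogens are located by proximity (same
# residue, within 1.25 Angstrom of the donor heavy atom), which makes the
# detector independent of hydrogen naming conventions.
HBOND_DONOR_ATOMS <- list(
  "*" = "N",
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TYR = "OH", TRP = "NE1", ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2")
)

HBOND_ACCEPTOR_NAMES <- c("O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1",
                          "OH", "O1P", "O2P", "O3P")

# Planar groups for stacking: all listed atoms must be present. Trp carries
# two rings; events are deduplicated per residue pair, so a Trp partner is
# counted once even when both rings satisfy the criteria.
PLANE_GROUPS <- list(
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(ring5 = c("CG", "CD1", "NE1", "CE2", "CD2"),
             ring6 = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  ARG = list(guanidinium = c("NE", "CZ", "NH1", "NH2"))
)

# --- internal helpers -------------------------------------------------------

as_frame_df <- function(frame) {
  if (inherits(frame, "rs_trajectory")) frame <- frame_atoms(frame, 1L)
  req <- c("name", "resname", "resindex", "chain", "x", "y", "z")
  if (!is.data.frame(frame) || !all(req %in% names(frame))) {
    stop("a frame needs columns name, resname, resindex, chain, x, y, z",
         call. = FALSE)
  }
  frame$resname <- toupper(frame$resname)
  frame
}

res_key <- function(chain, resindex) paste0(chain, ":", resindex)

# canonical unordered residue-pair events table
empty_events <- function() {
  data.frame(kind = character(), chain_a = character(), res_a = integer(),
             chain_b = character(), res_b = integer(), span = character(),
             distance = numeric(), angle = numeric(),
             stringsAsFactors = FALSE)
}

make_events <- function(kind, c1, r1, c2, r2, distance, angle = NA_real_) {
  swap <- (c1 > c2) | (c1 == c2 & r1 > r2)
  ca <- ifelse(swap, c2, c1); ra <- ifelse(swap, r2, r1)
  cb <- ifelse(swap, c1, c2); rb <- ifelse(swap, r1, r2)
  data.frame(kind = kind, chain_a = ca, res_a = as.integer(ra),
             chain_b = cb, res_b = as.integer(rb),
             span = ifelse(ca == cb, "intra", "inter"),
             distance = distance, angle = angle, stringsAsFactors = FALSE)
}

# keep the closest contact for each residue pair
dedupe_events <- function(ev) {
  if (!nrow(ev)) return(ev)
  key <- paste(ev$kind, ev$chain_a, ev$res_a, ev$chain_b, ev$res_b)
  ev <- ev[order(key, ev$distance), , drop = FALSE]
  ev <- ev[!duplicated(paste(ev$kind, ev$chain_a, ev$res_a, ev$chain_b,
                             ev$res_b)), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

select_atoms <- function(frame, table) {
  idx <- logical(nrow(frame))
  for (rn in names(table)) {
    if (rn == "*") {
      idx <- idx | frame$name %in% table[[rn]]
    } else {
      idx <- idx | (frame$resname == rn & frame$name %in% table[[rn]])
    }
  }
  frame[idx, , drop = FALSE]
}

cross_dist <- function(a, b) {
  # a, b: data frames with x, y, z; returns |a| x |b| distance matrix
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

# --- salt bridges -----------------------------------------------------------

#' Detect salt bridges in a frame
#'
#' A salt bridge is scored at residue-pair granularity: one event per
#' (donor residue, acceptor residue) pair having at least one donor
#' side-chain nitrogen within `saltbridge_cutoff` of an acceptor side-chain
#' oxygen. Donors are Arg (NE/NH1/NH2) and Lys (NZ); acceptors are Asp
#' (OD1/OD2), Glu (OE1/OE2) and phosphoserine (O1P/O2P/O3P/OG). The reported
#' distance is the minimum atom-atom distance for the pair.
#'
#' @param frame Atom table (see [frame_atoms()]) or an `rs_trajectory`
#'   (first frame).
#' @param config A [geometry_config()].
#' @return Event data frame with columns `kind`, `chain_a`, `res_a`,
#'   `chain_b`, `res_b`, `span`, `distance`, `angle` (NA for salt bridges).
#' @export
detect_salt_bridges <- function(frame, config = geometry_config()) {
  frame <- as_frame_df(frame)
  don <- select_atoms(frame, SALT_DONOR_ATOMS)
  acc <- select_atoms(frame, SALT_ACCEPTOR_ATOMS)
  if (!nrow(don) || !nrow(acc)) return(empty_events())
  d <- cross_dist(don, acc)
  hit <- which(d <= config$saltbridge_cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty_events())
  i <- hit[, 1]; j <- hit[, 2]
  same <- don$chain[i] == acc$chain[j] & don$resindex[i] == acc$resindex[j]
  i <- i[!same]; j <- j[!same]
  if (!length(i)) return(empty_events())
  ev <- make_events("salt_bridge", don$chain[i], don$resindex[i],
                    acc$chain[j], acc$resindex[j], d[cbind(i, j)])
  dedupe_events(ev)
}

# --- hydrogen bonds ---------------------------------------------------------

#' Detect hydrogen bonds in a frame
#'
#' Scores donor-acceptor residue pairs where the donor-acceptor heavy-atom
#' distance is at most `hbond_dist_cutoff` and the donor-H-acceptor angle is
#' at least `180 - hbond_angle_cutoff` degrees. Donor hydrogens must be
#' explicit; they are assigned to a donor heavy atom by proximity (same
#' residue, within 1.25 Angstrom). Residue pairs already counted as salt
#' bridges in the same frame are excluded to avoid double counting.
#'
#' @inheritParams detect_salt_bridges
#' @return Event data frame (kind `"hbond"`); `angle` holds the
#'   donor-H-acceptor angle in degrees at the closest contact.
#' @export
detect_hbonds <- function(frame, config = geometry_config()) {
  frame <- as_frame_df(frame)
  hyd <- frame[grepl("^H", frame$name), , drop = FALSE]
  if (!nrow(hyd)) {
    stop("no hydrogen atoms in frame: hydrogen-bond detection requires ",
         "explicit hydrogens", call. = FALSE)
  }
  don <- select_atoms(frame, HBOND_DONOR_ATOMS)
  acc <- frame[frame$name %in% HBOND_ACCEPTOR_NAMES, , drop = FALSE]
  if (!nrow(don) || !nrow(acc)) return(empty_events())

  # attach hydrogens to donors by proximity within the same residue
  dh <- cross_dist(don, hyd)
  same_res <- outer(res_key(don$chain, don$resindex),
                    res_key(hyd$chain, hyd$resindex), "==")
  dh[!same_res] <- Inf
  pairs <- which(dh <= 1.25, arr.ind = TRUE)
  if (!nrow(pairs)) return(empty_events())

  sb <- detect_salt_bridges(frame, config)
  sb_keys <- if (nrow(sb)) paste(res_key(sb$chain_a, sb$res_a),
                                 res_key(sb$chain_b, sb$res_b)) else character()

  da <- cross_dist(don, acc)
  out <- empty_events()
  for (k in seq_len(nrow(pairs))) {
    di <- pairs[k, 1]; hi <- pairs[k, 2]
    cand <- which(da[di, ] <= config$hbond_dist_cutoff)
    if (!length(cand)) next
    cand <- cand[!(acc$chain[cand] == don$chain[di] &
                   acc$resindex[cand] == don$resindex[di])]
    if (!length(cand)) next
    dvec <- c(don$x[di], don$y[di], don$z[di])
    hvec <- c(hyd$x[hi], hyd$y[hi], hyd$z[hi])
    for (ai in cand) {
      avec <- c(acc$x[ai], acc$y[ai], acc$z[ai])
      ang <- vector_angle(dvec - hvec, avec - hvec)
      if (ang >= 180 - config$hbond_angle_cutoff) {
        k1 <- res_key(don$chain[di], don$resindex[di])
        k2 <- res_key(acc$chain[ai], acc$resindex[ai])
        pair_key <- paste(sort(c(k1, k2)), collapse = " ")
        if (pair_key %in% sb_keys) next
        out <- rbind(out, make_events("hbond", don$chain[di],
                                      don$resindex[di], acc$chain[ai],
                                      acc$resindex[ai], da[di, ai], ang))
      }
    }
  }
  dedupe_events(out)
}

vector_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(max(cosang, -1), 1)) * 180 / pi
}

# --- stacking ---------------------------------------------------------------

#' Detect stacking interactions in a frame
#'
#' Planar groups are the aromatic rings of Phe/Tyr/His/Trp and the arginine
#' guanidinium plane. A stacking event requires centroid-centroid distance
#' at most `stack_dist_cutoff` (default 4.5 Angstrom) and an angle between
#' the two group planes of at most `stack_angle_cutoff` (default 20
#' degrees). Events are classified `pi_pi` (aromatic-aromatic), `cation_pi`
#' (Arg-aromatic) or `cation_cation` (Arg-Arg) and deduplicated per residue
#' pair, so a tryptophan counts once per partner even when both of its rings
#' qualify.
#'
#' @inheritParams detect_salt_bridges
#' @return Event data frame; `angle` holds the inter-plane angle in degrees.
#' @export
detect_stacking <- function(frame, config = geometry_config()) {
  frame <- as_frame_df(frame)
  groups <- collect_plane_groups(frame)
  if (length(groups) < 2L) return(empty_events())
  out <- empty_events()
  for (i in seq_len(length(groups) - 1L)) {
    for (j in seq(i + 1L, length(groups))) {
      gi <- groups[[i]]; gj <- groups[[j]]
      if (gi$chain == gj$chain && gi$resindex == gj$resindex) next
      dist <- sqrt(sum((gi$centroid - gj$centroid)^2))
      if (dist > config$stack_dist_cutoff) next
      ang <- plane_angle(gi$normal, gj$normal)
      if (ang > config$stack_angle_cutoff) next
      kind <- stacking_kind(gi$resname, gj$resname)
      out <- rbind(out, make_events(kind, gi$chain, gi$resindex,
                                    gj$chain, gj$resindex, dist, ang))
    }
  }
  dedupe_events(out)
}

stacking_kind <- function(rn1, rn2) {
  arg1 <- rn1 == "ARG"; arg2 <- rn2 == "ARG"
  if (arg1 && arg2) "cation_cation" else if (arg1 || arg2) "cation_pi" else "pi_pi"
}

# angle between planes via their normals, folded to [0, 90]
plane_angle <- function(n1, n2) {
  a <- vector_angle(n1, n2)
  min(a, 180 - a)
}

collect_plane_groups <- function(frame) {
  out <- list()
  rframe <- frame[frame$resname %in% names(PLANE_GROUPS), , drop = FALSE]
  if (!nrow(rframe)) return(out)
  keys <- unique(rframe[, c("chain", "resindex", "resname")])
  for (k in seq_len(nrow(keys))) {
    rn <- keys$resname[k]
    sub <- rframe[rframe$chain == keys$chain[k] &
                  rframe$resindex == keys$resindex[k], , drop = FALSE]
    for (gname in names(PLANE_GROUPS[[rn]])) {
      want <- PLANE_GROUPS[[rn]][[gname]]
      rows <- match(want, sub$name)
      if (anyNA(rows)) next
      xyz <- as.matrix(sub[rows, c("x", "y", "z")])
      pl <- fit_plane(xyz)
      if (is.null(pl)) {
        stop(sprintf("degenerate (collinear) planar group %s in %s %s%d",
                     gname, rn, keys$chain[k], keys$resindex[k]),
             call. = FALSE)
      }
      out[[length(out) + 1L]] <- list(
        chain = keys$chain[k], resindex = keys$resindex[k], resname = rn,
        group = gname, centroid = pl$centroid, normal = pl$normal
      )
    }
  }
  out
}

# least-squares plane; NULL if the atoms are (near-)collinear
fit_plane <- function(xyz) {
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2, centroid)
  sv <- svd(centered)
  if (sv$d[2] < 1e-6 * max(sv$d[1], 1e-12)) return(NULL)
  list(centroid = centroid, normal = sv$v[, 3])
}

#' Detect all interaction kinds in a frame
#'
#' Convenience wrapper running [detect_salt_bridges()], [detect_hbonds()]
#' and [detect_stacking()] and binding the event tables. If the frame
#' contains no hydrogens, hydrogen bonds are skipped with `hbonds = FALSE`.
#'
#' @inheritParams detect_salt_bridges
#' @param hbonds Include hydrogen-bond detection (requires explicit
#'   hydrogens).
#' @return Combined event data frame.
#' @export
detect_frame_events <- function(frame, config = geometry_config(),
                                hbonds = TRUE) {
  frame <- as_frame_df(frame)
  ev <- rbind(detect_salt_bridges(frame, config),
              if (hbonds) detect_hbonds(frame, config) else empty_events(),
              detect_stacking(frame, config))
  rownames(ev) <- NULL
  ev
}
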