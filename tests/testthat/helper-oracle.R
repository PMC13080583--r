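# Independent brute-force detectors used as oracles: plain nested loops over
# atoms/groups, no shared code with the package implementation. Each returns
# a sorted character vector of "kind chainA:resA chainB:resB" keys.

oracle_pair_key <- function(kind, c1, r1, c2, r2) {
  a <- paste0(c1, ":", r1)
  b <- paste0(c2, ":", r2)
  if (a > b) {
    tmp <- a
    a <- b
    b <- tmp
  }
  paste(kind, a, b)
}

oracle_salt_bridges <- function(frame, cutoff = 4.0) {
  is_don <- (frame$resname == "ARG" & frame$name %in% c("NE", "NH1", "NH2")) |
            (frame$resname == "LYS" & frame$name == "NZ")
  is_acc <- (frame$resname == "ASP" & frame$name %in% c("OD1", "OD2")) |
            (frame$resname == "GLU" & frame$name %in% c("OE1", "OE2")) |
            (frame$resname == "SEP" & frame$name %in% c("O1P", "O2P", "O3P", "OG"))
  keys <- character()
  for (i in which(is_don)) {
    for (j in which(is_acc)) {
      if (frame$chain[i] == frame$chain[j] &&
          frame$resindex[i] == frame$resindex[j]) next
      d <- sqrt((frame$x[i] - frame$x[j])^2 + (frame$y[i] - frame$y[j])^2 +
                (frame$z[i] - frame$z[j])^2)
      if (d <= cutoff) {
        keys <- c(keys, oracle_pair_key("salt_bridge", frame$chain[i],
                                        frame$resindex[i], frame$chain[j],
                                        frame$resindex[j]))
      }
    }
  }
  sort(unique(keys))
}

oracle_hbonds <- function(frame, dist_cutoff = 3.5, angle_dev = 45) {
  don_tab <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ", SER = "OG",
                  THR = "OG1", TYR = "OH", TRP = "NE1", ASN = "ND2",
                  GLN = "NE2", HIS = c("ND1", "NE2"))
  acc_names <- c("O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH",
                 "O1P", "O2P", "O3P")
  sb <- oracle_salt_bridges(frame)
  sb_pairs <- sub("^salt_bridge ", "", sb)
  keys <- character()
  for (i in seq_len(nrow(frame))) {
    dn <- don_tab[[frame$resname[i]]]
    is_donor <- frame$name[i] == "N" ||
      (!is.null(dn) && frame$name[i] %in% dn)
    if (!is_donor) next
    for (h in seq_len(nrow(frame))) {
      if (!startsWith(frame$name[h], "H")) next
      if (frame$chain[h] != frame$chain[i] ||
          frame$resindex[h] != frame$resindex[i]) next
      dh <- sqrt((frame$x[i] - frame$x[h])^2 + (frame$y[i] - frame$y[h])^2 +
                 (frame$z[i] - frame$z[h])^2)
      if (dh > 1.25) next
      for (j in seq_len(nrow(frame))) {
        if (!(frame$name[j] %in% acc_names)) next
        if (frame$chain[j] == frame$chain[i] &&
            frame$resindex[j] == frame$resindex[i]) next
        da <- sqrt((frame$x[i] - frame$x[j])^2 +
                   (frame$y[i] - frame$y[j])^2 +
                   (frame$z[i] - frame$z[j])^2)
        if (da > dist_cutoff) next
        u <- c(frame$x[i] - frame$x[h], frame$y[i] - frame$y[h],
               frame$z[i] - frame$z[h])
        v <- c(frame$x[j] - frame$x[h], frame$y[j] - frame$y[h],
               frame$z[j] - frame$z[h])
        ang <- acos(min(max(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1)) *
          180 / pi
        if (ang < 180 - angle_dev) next
        key <- oracle_pair_key("hbond", frame$chain[i], frame$resindex[i],
                               frame$chain[j], frame$resindex[j])
        if (sub("^hbond ", "", key) %in% sb_pairs) next
        keys <- c(keys, key)
      }
    }
  }
  sort(unique(keys))
}

oracle_stacking <- function(frame, dist_cutoff = 4.5, angle_cutoff = 20) {
  group_tab <- list(
    PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
    TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
               c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
    ARG = list(c("NE", "CZ", "NH1", "NH2"))
  )
  groups <- list()
  ids <- unique(frame[, c("chain", "resindex", "resname")])
  for (k in seq_len(nrow(ids))) {
    gl <- group_tab[[ids$resname[k]]]
    if (is.null(gl)) next
    sub <- frame[frame$chain == ids$chain[k] &
                 frame$resindex == ids$resindex[k], ]
    for (g in gl) {
      rows <- match(g, sub$name)
      if (anyNA(rows)) next
      m <- as.matrix(sub[rows, c("x", "y", "z")])
      cen <- colMeans(m)
      # normal from the cross product of two in-plane edges
      nrm <- c(
        (m[2, 2] - m[1, 2]) * (m[3, 3] - m[1, 3]) -
          (m[2, 3] - m[1, 3]) * (m[3, 2] - m[1, 2]),
        (m[2, 3] - m[1, 3]) * (m[3, 1] - m[1, 1]) -
          (m[2, 1] - m[1, 1]) * (m[3, 3] - m[1, 3]),
        (m[2, 1] - m[1, 1]) * (m[3, 2] - m[1, 2]) -
          (m[2, 2] - m[1, 2]) * (m[3, 1] - m[1, 1])
      )
      groups[[length(groups) + 1L]] <- list(
        chain = ids$chain[k], res = ids$resindex[k],
        resname = ids$resname[k], cen = cen, nrm = nrm
      )
    }
  }
  keys <- character()
  if (length(groups) < 2L) return(keys)
  for (i in seq_len(length(groups) - 1L)) {
    for (j in seq(i + 1L, length(groups))) {
      gi <- groups[[i]]
      gj <- groups[[j]]
      if (gi$chain == gj$chain && gi$res == gj$res) next
      d <- sqrt(sum((gi$cen - gj$cen)^2))
      if (d > dist_cutoff) next
      ca <- acos(min(max(abs(sum(gi$nrm * gj$nrm)) /
                           sqrt(sum(gi$nrm^2) * sum(gj$nrm^2)), -1), 1)) *
        180 / pi
      if (ca > angle_cutoff) next
      kind <- if (gi$resname == "ARG" && gj$resname == "ARG") {
        "cation_cation"
      } else if (gi$resname == "ARG" || gj$resname == "ARG") {
        "cation_pi"
      } else "pi_pi"
      keys <- c(keys, oracle_pair_key(kind, gi$chain, gi$res,
                                      gj$chain, gj$res))
    }
  }
  sort(unique(keys))
}

event_keys <- function(ev) {
  if (!nrow(ev)) return(character())
  sort(mapply(oracle_pair_key, ev$kind, ev$chain_a, ev$res_a, ev$chain_b,
              ev$res_b, USE.NAMES = FALSE))
}
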