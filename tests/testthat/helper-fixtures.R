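# Fixture builders used across test files.

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# A random frame: residues with full idealised side chains dropped at random
# positions/orientations inside a cubic box, two chains. Dense enough that
# many pairs land near the detector cutoffs.
random_frame <- function(n_res = 10, box = 14) {
  pool <- c("ARG", "LYS", "ASP", "GLU", "SEP", "SER", "ASN", "GLN",
            "PHE", "TYR", "TRP", "HIS", "GLY")
  rows <- list()
  for (i in seq_len(n_res)) {
    rn <- sample(pool, 1)
    tmpl <- rsdomain:::residue_template(rn)
    rot <- random_rotation()
    pos <- tmpl %*% t(rot)
    shift <- stats::runif(3, 0, box)
    pos <- sweep(pos, 2, shift, "+")
    chain <- if (i <= ceiling(n_res / 2)) "A" else "B"
    ridx <- if (chain == "A") i else i - ceiling(n_res / 2)
    rows[[i]] <- data.frame(name = rownames(tmpl), resname = rn,
                            resindex = ridx, chain = chain,
                            x = pos[, 1], y = pos[, 2], z = pos[, 3],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# A random planted-complex spec with a random mix of salt bridges, H-bonds
# and stacks on two 8-residue chains.
random_planted_spec <- function(n_frames = 4) {
  len <- 8L
  chains <- list(A = rep("gly", len), B = rep("gly", len))
  free <- list(A = seq_len(len), B = seq_len(len))
  take <- function(chain) {
    pos <- sample(free[[chain]], 1)
    free[[chain]] <<- setdiff(free[[chain]], pos)
    pos
  }
  pair_of <- function(res1_pool, res2_pool) {
    c1 <- sample(c("A", "B"), 1)
    c2 <- sample(c("A", "B"), 1)
    if (!length(free[[c1]])) return(NULL)
    p1 <- take(c1)
    if (!length(free[[c2]])) return(NULL)
    p2 <- take(c2)
    chains[[c1]][p1] <<- sample(res1_pool, 1)
    chains[[c2]][p2] <<- sample(res2_pool, 1)
    c(c1, p1, c2, p2)
  }
  n_sb <- sample(0:3, 1)
  n_hb <- sample(0:2, 1)
  n_st <- sample(0:2, 1)
  sb <- Filter(Negate(is.null),
               lapply(seq_len(n_sb), function(k) {
                 pair_of(c("arg", "lys"), c("asp", "glu", "sep"))
               }))
  hb <- Filter(Negate(is.null),
               lapply(seq_len(n_hb), function(k) {
                 pair_of(c("ser", "thr"), c("asn", "gln"))
               }))
  st <- Filter(Negate(is.null),
               lapply(seq_len(n_st), function(k) {
                 pair_of(c("arg", "phe", "tyr", "trp", "his"),
                         c("arg", "phe", "tyr", "trp", "his"))
               }))
  planted_complex_spec(chains$A, chains$B, planted_salt_bridges = sb,
                       planted_hbonds = hb, planted_stacks = st,
                       n_frames = n_frames)
}

# canonical "kind chain:res chain:res" keys for a spec's planted truth
truth_keys <- function(traj) {
  event_keys(attr(traj, "ground_truth"))
}

# rigid motion of a frame data frame
transform_frame <- function(frame, rot, shift) {
  xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  frame$x <- xyz[, 1]
  frame$y <- xyz[, 2]
  frame$z <- xyz[, 3]
  frame
}
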