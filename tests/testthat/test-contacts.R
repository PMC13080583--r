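# hand-built minimal frames -------------------------------------------------

atom_row <- function(name, resname, resindex, chain, x, y, z) {
  data.frame(name = name, resname = resname, resindex = resindex,
             chain = chain, x = x, y = y, z = z, stringsAsFactors = FALSE)
}

test_that("salt-bridge detector fires on constructed geometry only", {
  frame <- rbind(
    atom_row("NH1", "ARG", 1, "A", 0, 0, 0),
    atom_row("OD1", "ASP", 2, "A", 3, 0, 0)
  )
  ev <- detect_salt_bridges(frame)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "salt_bridge")
  expect_identical(ev$span, "intra")
  expect_equal(ev$distance, 3)
  # beyond cutoff
  frame2 <- frame
  frame2$x[2] <- 5.5
  expect_identical(nrow(detect_salt_bridges(frame2,
                                            geometry_config(saltbridge_cutoff = 4))),
                   0L)
  # residue-pair deduplication: two close atom contacts, one event
  frame3 <- rbind(frame, atom_row("NH2", "ARG", 1, "A", 0.5, 1, 0),
                  atom_row("OD2", "ASP", 2, "A", 2.8, 1, 0))
  expect_identical(nrow(detect_salt_bridges(frame3)), 1L)
  # phosphoserine is an acceptor
  frame4 <- rbind(atom_row("NZ", "LYS", 1, "A", 0, 0, 0),
                  atom_row("O1P", "SEP", 1, "B", 3.5, 0, 0),
                  atom_row("H", "GLY", 2, "A", 50, 50, 50))
  ev4 <- detect_salt_bridges(frame4)
  expect_identical(ev4$span, "inter")
})

test_that("hydrogen-bond detector respects distance, angle and exclusions", {
  lin <- rbind(
    atom_row("N", "GLY", 1, "A", 0, 0, 0),
    atom_row("H", "GLY", 1, "A", 1, 0, 0),
    atom_row("O", "GLY", 2, "A", 2.9, 0, 0)
  )
  ev <- detect_hbonds(lin)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$distance, 2.9)
  expect_equal(ev$angle, 180)
  # 90-degree bent geometry rejected
  bent <- lin
  bent$x[3] <- 1
  bent$y[3] <- 2.9
  expect_identical(nrow(detect_hbonds(bent)), 0L)
  # no hydrogens at all -> capability error
  noh <- lin[c(1, 3), ]
  expect_error(detect_hbonds(noh), "hydrogen")
  # a salt-bridged residue pair is not double counted as an H-bond
  sb <- rbind(
    atom_row("NH1", "ARG", 1, "A", 0, 0, 0),
    atom_row("HH11", "ARG", 1, "A", 1, 0, 0),
    atom_row("OD1", "ASP", 2, "A", 2.9, 0, 0)
  )
  expect_identical(nrow(detect_salt_bridges(sb)), 1L)
  expect_identical(nrow(detect_hbonds(sb)), 0L)
})

ring_atoms <- function(resname, resindex, chain, center, tilt_deg = 0) {
  names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  ang <- seq(0, 300, by = 60) * pi / 180
  xyz <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  t <- tilt_deg * pi / 180
  rot <- rbind(c(1, 0, 0), c(0, cos(t), -sin(t)), c(0, sin(t), cos(t)))
  xyz <- xyz %*% t(rot)
  xyz <- sweep(xyz, 2, center, "+")
  atom_row(names, resname, resindex, chain, xyz[, 1], xyz[, 2], xyz[, 3])
}

test_that("stacking detector applies the 4.5 A / 20 degree criteria", {
  # parallel Phe rings at 3.8 A -> one pi-pi event
  fr <- rbind(ring_atoms("PHE", 1, "A", c(0, 0, 0)),
              ring_atoms("PHE", 2, "A", c(0, 0, 3.8)))
  ev <- detect_stacking(fr)
  expect_identical(ev$kind, "pi_pi")
  expect_equal(ev$distance, 3.8)
  expect_equal(ev$angle, 0, tolerance = 1e-9)
  # 30-degree tilt exceeds the plane-angle threshold
  fr30 <- rbind(ring_atoms("PHE", 1, "A", c(0, 0, 0)),
                ring_atoms("PHE", 2, "A", c(0, 0, 3.8), tilt = 30))
  expect_identical(nrow(detect_stacking(fr30)), 0L)
  # Arg guanidinium over Tyr ring at 4.0 A / 10 degrees -> cation-pi
  gua <- atom_row(c("NE", "CZ", "NH1", "NH2"), "ARG", 2, "B",
                  c(1.33, 0, -0.66, -0.66), c(0, 0, 1.15, -1.15), rep(0, 4))
  t <- 10 * pi / 180
  rot <- rbind(c(1, 0, 0), c(0, cos(t), -sin(t)), c(0, sin(t), cos(t)))
  xyz <- as.matrix(gua[, c("x", "y", "z")]) %*% t(rot)
  gua$x <- xyz[, 1] - colMeans(xyz)[1]
  gua$y <- xyz[, 2] - colMeans(xyz)[2]
  gua$z <- xyz[, 3] - colMeans(xyz)[3] + 4.0
  fr2 <- rbind(ring_atoms("TYR", 1, "A", c(0, 0, 0)), gua)
  ev2 <- detect_stacking(fr2)
  expect_identical(ev2$kind, "cation_pi")
  expect_equal(ev2$distance, 4.0, tolerance = 1e-9)
  expect_equal(ev2$angle, 10, tolerance = 1e-6)
  # collinear "ring" -> geometry error
  degen <- atom_row(c("NE", "CZ", "NH1", "NH2"), "ARG", 1, "A",
                    1:4, rep(0, 4), rep(0, 4))
  expect_error(detect_stacking(degen), "collinear")
})

test_that("detectors agree with the brute-force oracle on random frames", {
  set.seed(202)
  for (rep in 1:60) {
    frame <- random_frame(n_res = sample(6:12, 1))
    cfg <- geometry_config()
    expect_identical(event_keys(detect_salt_bridges(frame, cfg)),
                     oracle_salt_bridges(frame))
    expect_identical(event_keys(detect_hbonds(frame, cfg)),
                     oracle_hbonds(frame))
    expect_identical(event_keys(detect_stacking(frame, cfg)),
                     oracle_stacking(frame))
  }
})

test_that("detector output is invariant under rigid motions", {
  set.seed(77)
  for (rep in 1:5) {
    frame <- random_frame(n_res = 10)
    moved <- transform_frame(frame, random_rotation(),
                             stats::runif(3, -30, 30))
    for (det in list(detect_salt_bridges, detect_hbonds, detect_stacking)) {
      a <- det(frame)
      b <- det(moved)
      expect_identical(event_keys(a), event_keys(b))
      if (nrow(a)) {
        expect_equal(sort(a$distance), sort(b$distance), tolerance = 1e-9)
      }
    }
  }
})
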