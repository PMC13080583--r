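census_traj <- function(n_frames = 5, seed = 9) {
  spec <- planted_complex_spec(
    chain_a_seq = c("arg", "ser", "arg", "asp", "arg"),
    chain_b_seq = c("sep", "asn", "tyr", "gly", "glu"),
    planted_salt_bridges = list(c("A", 1, "B", 1), c("A", 3, "B", 5),
                                c("A", 5, "A", 4)),
    planted_hbonds = list(c("A", 2, "B", 2)),
    n_frames = n_frames
  )
  build_planted_complex(spec, gen_config(seed = seed, noise_sd = 0.06))
}

test_that("frame summary means equal planted ground truth exactly", {
  traj <- census_traj()
  smry <- summarize_frames(traj)
  truth <- attr(traj, "ground_truth_counts")
  m <- merge(as.data.frame(smry), truth, by = c("kind", "span"))
  expect_equal(m$mean_per_frame, m$count)
  expect_identical(attr(smry, "n_frames"), 5L)
  # per-frame variance of an identical-truth trajectory is zero
  expect_true(all(apply(attr(smry, "counts"), 2, stats::sd) == 0))
})

test_that("intra + inter = total for every kind on every frame", {
  set.seed(11)
  traj <- census_traj(4)
  for (f in seq_len(n_frames(traj))) {
    ev <- detect_frame_events(frame_atoms(traj, f))
    for (kind in unique(ev$kind)) {
      sub <- ev[ev$kind == kind, ]
      expect_identical(sum(sub$span == "intra") + sum(sub$span == "inter"),
                       nrow(sub))
    }
  }
  # and at the summary level
  smry <- summarize_frames(traj)
  tot <- tapply(smry$mean_per_frame, smry$kind, sum)
  truth <- attr(traj, "ground_truth_counts")
  tru_tot <- tapply(truth$count, truth$kind, sum)
  expect_equal(as.numeric(tot[names(tru_tot)]), as.numeric(tru_tot))
})

test_that("analysis window accounting follows the snapshot interval", {
  spec <- planted_complex_spec(c("gly", "gly"), NULL, n_frames = 30)
  traj <- build_planted_complex(spec, gen_config(seed = 2, noise_sd = 0.02))
  expect_identical(traj$frame_interval_ps, 150)
  # 3 ns at 150 ps -> 20 frames
  s <- summarize_frames(traj, window_ns = 3)
  expect_identical(attr(s, "n_frames"), 20L)
  expect_error(summarize_frames(traj, window_ns = 10), "exceeds")
  expect_error(summarize_frames(traj, window_ns = 0.01), "empty")
})

test_that("replicate aggregation computes mean and SD per kind/span", {
  traj <- census_traj()
  s1 <- summarize_frames(traj)
  # identical replicates -> SD exactly 0
  agg0 <- aggregate_replicates(list(s1, s1, s1))
  expect_true(all(agg0$sd == 0))
  expect_equal(agg0$mean, s1$mean_per_frame)
  # hand-built {2, 4, 6}: mean 4, SD 2
  mk <- function(v) {
    s <- s1
    s$mean_per_frame <- ifelse(s$kind == "salt_bridge" & s$span == "inter",
                               v, s$mean_per_frame)
    s
  }
  agg <- aggregate_replicates(list(mk(2), mk(4), mk(6)))
  row <- agg[agg$kind == "salt_bridge" & agg$span == "inter", ]
  expect_equal(row$mean, 4)
  expect_equal(row$sd, 2)
  # independent two-pass mean/SD on random values
  set.seed(33)
  vals <- lapply(1:3, function(i) {
    s <- s1
    s$mean_per_frame <- stats::runif(nrow(s))
    s
  })
  agg2 <- aggregate_replicates(vals)
  m <- sapply(vals, function(s) s$mean_per_frame)
  expect_equal(agg2$mean, rowSums(m) / 3)
  expect_equal(agg2$sd, apply(m, 1, function(v) {
    sqrt(sum((v - mean(v))^2) / 2)
  }))
  # mismatched keys
  s_bad <- s1[rev(seq_len(nrow(s1))), ]
  expect_error(aggregate_replicates(list(s1, s_bad)), "mismatched")
  expect_error(aggregate_replicates(list(s1)), "at least 2")
})

test_that("per-residue profile accounting matches the event lists", {
  # single planted interchain salt bridge on A5 (with A4-A5 intra pair too)
  traj <- census_traj(6)
  prof <- per_residue_profile(traj, "A")
  expect_identical(nrow(prof), 5L)
  # A1 and A3 each carry one interchain bridge every frame; A4/A5 share an
  # intrachain bridge, so both are credited
  expect_equal(prof$mean_salt_bridges[prof$resindex == 1], 1)
  expect_equal(prof$mean_salt_bridges[prof$resindex == 3], 1)
  expect_equal(prof$mean_salt_bridges[prof$resindex == 4], 1)
  expect_equal(prof$mean_salt_bridges[prof$resindex == 5], 1)
  expect_equal(prof$mean_salt_bridges[prof$resindex == 2], 0)
  # overall mean equals the mean of per-residue entries by construction
  expect_equal(attr(prof, "overall_mean"), mean(prof$mean_salt_bridges))
  # accounting identity against the event list: per-frame sum over the
  # profile equals 2x intra + once per inter event touching the chain
  ev <- detect_salt_bridges(frame_atoms(traj, 1))
  touches <- sum(ev$span == "intra" & ev$chain_a == "A" & ev$chain_b == "A") * 2 +
    sum(ev$span == "inter" & (ev$chain_a == "A" | ev$chain_b == "A"))
  expect_equal(sum(prof$mean_salt_bridges), touches)
  expect_error(per_residue_profile(traj, "Z"), "not present")
})

test_that("interchain totals rank with partner net charge", {
  cplx <- generate_rank_complexes(gen_config(seed = 21, noise_sd = 0.06),
                                  n_frames = 3)
  q <- vapply(cplx, attr, numeric(1), "partner_net_charge")
  expect_true(q[["bad1_like"]] > q[["u2af1_like"]] &&
                q[["u2af1_like"]] > q[["srsf1_like"]])
  inter <- vapply(cplx, function(tr) {
    s <- summarize_frames(tr, hbonds = FALSE)
    sum(s$mean_per_frame[s$span == "inter"])
  }, numeric(1))
  expect_true(inter[["bad1_like"]] > inter[["u2af1_like"]])
  expect_true(inter[["u2af1_like"]] > inter[["srsf1_like"]])
  # recovered counts equal the planted counts
  planted <- vapply(cplx, attr, numeric(1), "n_planted_interchain")
  expect_equal(unname(inter), unname(planted))
})
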