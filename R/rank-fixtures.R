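#' Net-charge-ordered complex fixtures for rank comparisons
#'
#' Builds three planted two-chain complexes that mimic the comparison of a
#' fully phosphorylated SRSF1-like RS chain (chain A, identical in all
#' three) bound to partner chains of decreasing net positive charge:
#' BAD1-like > U2AF1-RS-like > SRSF1-RS-like. The number of planted
#' interchain salt bridges scales with the partner's net charge
#' (`round(charge / 2)`, at least 1), capped by the available Arg donors
#' and phosphoserine acceptors, so detector-recovered interchain totals
#' reproduce the charge ordering on synthetic data.
#'
#' @param gen A [gen_config()]; `noise_sd` is coordinate jitter in
#'   Angstrom.
#' @param n_frames Frames per complex.
#' @return Named list (`bad1_like`, `u2af1_like`, `srsf1_like`) of
#'   `rs_trajectory` objects; each carries attributes `partner_net_charge`
#'   and `n_planted_interchain`.
#' @export
generate_rank_complexes <- function(gen = gen_config(), n_frames = 5L) {
  gen <- as_gen_config(gen)
  pi_rs <- generate_rs_sequence(10, phospho_fraction = 1, "srsf1-like",
                                gen = gen)
  partners <- list(
    bad1_like = generate_rs_sequence(4, 0, "bad1-like", gen = gen),
    u2af1_like = generate_rs_sequence(4, 0, "u2af1-like", gen = gen),
    srsf1_like = generate_rs_sequence(3, 0, "srsf1-like", gen = gen)
  )
  sep_idx <- which(pi_rs == "sep")
  out <- list()
  for (nm in names(partners)) {
    partner <- partners[[nm]]
    q <- sequence_net_charge(partner)
    arg_idx <- which(partner == "arg")
    n_sb <- max(1L, round(q / 2))
    n_sb <- min(n_sb, length(arg_idx), length(sep_idx))
    pairs <- lapply(seq_len(n_sb), function(k) {
      c("A", sep_idx[k], "B", arg_idx[k])
    })
    spec <- planted_complex_spec(chain_a_seq = pi_rs, chain_b_seq = partner,
                                 planted_salt_bridges = pairs,
                                 n_frames = n_frames)
    traj <- build_planted_complex(spec, gen)
    attr(traj, "partner_net_charge") <- q
    attr(traj, "n_planted_interchain") <- n_sb
    out[[nm]] <- traj
  }
  out
}
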