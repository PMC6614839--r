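#' Simulate stochastic single-step photobleaching
#'
#' Each of `S` fluorophores bleaches independently, once and irreversibly,
#' with probability `bleach_prob` per frame. The returned trace gives the
#' number of unbleached molecules at frames 0, 1, ..., n_frames - 1; frame 0
#' always carries all `S` molecules.
#'
#' @param S integer number of fluorophores (>= 0).
#' @param bleach_prob per-frame bleach probability in \[0, 1\].
#' @param n_frames trace length.
#' @param seed optional integer seed.
#' @return integer vector of surviving-molecule counts (non-increasing).
#' @export
simulate_bleaching <- function(S, bleach_prob, n_frames, seed = NULL) {
  abort_if(!is_count(S), "S must be a non-negative integer")
  abort_if(bleach_prob < 0 || bleach_prob > 1, "bleach_prob must lie in [0, 1]")
  abort_if(!is_count(n_frames) || n_frames < 1, "n_frames must be >= 1")
  run <- function() {
    bf <- bleach_frames(S, bleach_prob)
    vapply(0:(n_frames - 1), function(t) sum(bf > t), integer(1))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Frame index at which each molecule first appears bleached (molecule is
# present at frames < bleach_frame). Geometric with support {1, 2, ...};
# Inf when bleach_prob = 0.
bleach_frames <- function(S, bleach_prob) {
  if (S == 0) return(integer(0))
  if (bleach_prob == 0) return(rep(Inf, S))
  stats::rgeom(S, bleach_prob) + 1
}
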