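# Shared builders for value-choice sets and small pools.

nf_uniform <- function(hh = 100, eco = 100, res = 100, id = "nf-test") {
  normalization_set(id, "test", 2000, hh, eco, res)
}

hnf_of <- function(factor, id = "hnf-test") {
  handprint_normalization_set(id, 2000, factor)
}

wf_of <- function(hh, eco, res, id = "wf-test", main = "EI99") {
  weighting_set(id, main, hh, eco, res)
}

random_wf <- function(id = "wf-rand", main = "EI99") {
  g <- rgamma(3, 1)
  w <- g / sum(g)
  weighting_set(id, main, w[1], w[2], w[3])
}

random_nf <- function(id = "nf-rand") {
  f <- exp(runif(3, log(1e3), log(1e12)))
  normalization_set(id, "test", 2000, f[1], f[2], f[3])
}

# A pool with given group sizes; factor values vary with the current RNG
# stream so callers seed before building it.
small_pools <- function(n_fnf = 2, n_hnf = 3, wf_sizes = c(EI99 = 2, ITSUBO = 3),
                        variants = "base") {
  fps <- lapply(seq_len(n_fnf), function(i) random_nf(sprintf("fnf-%d", i)))
  hps <- lapply(seq_len(n_hnf), function(i) {
    hnf_of(exp(runif(1, log(1e6), log(1e10))), sprintf("hnf-%d", i))
  })
  wfs <- lapply(names(wf_sizes), function(lbl) {
    lapply(seq_len(wf_sizes[[lbl]]), function(j) {
      random_wf(sprintf("wf-%s-%d", lbl, j), lbl)
    })
  })
  names(wfs) <- names(wf_sizes)
  factor_pools(fps, hps, wfs, variants = variants)
}

# Degenerate single-combination pools around the reference factors of a case.
singleton_pools <- function(f, variants = "base") {
  factor_pools(list(f$nf), list(f$hnf),
               stats::setNames(list(list(f$wf)), f$wf$main_set),
               variants = variants)
}
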