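# Shared scenario builders. The canonical motif is a fixed, documented
# aperiodic 5-site pattern in a 10000-position repeat (no two offsets
# nearly coincide modulo 10000/k): regression tests stay stable while the
# generators themselves remain general.
canonical_motif <- function() c(3279, 4944, 6384, 7672, 8748)

canonical_train <- function(repeats = 8, period = 10000) {
  motif_train(canonical_motif(), period, repeats)
}

# Two-train mixture on [0, 80000): repeat distances 7270 and 10000,
# three aperiodic offsets each.
canonical_mixture <- function(seed = 101) {
  o1 <- draw_motif_offsets(3, 7270, seed)
  o2 <- draw_motif_offsets(3, 10000, seed + 1)
  t1 <- motif_train(o1, 7270, 12, L = 80000)
  t2 <- motif_train(o2, 10000, 8, L = 80000)
  mixture(t1, t2, labels = c("p7270", "p10000"))
}

# One null ensemble per (N, J, R, seed): the null score law is
# period-independent, so replicated scenarios of the same size share it.
.null_cache <- new.env(parent = emptyenv())
cached_null <- function(N, J, R = 1000, seed = 7) {
  key <- paste(N, J, R, seed, sep = "_")
  if (is.null(.null_cache[[key]]))
    .null_cache[[key]] <- null_ensemble(N, J, R = R, seed = seed)
  .null_cache[[key]]
}

# Fundamental period of the most significant harmonic group.
top_fundamental <- function(spectrum, ...) {
  fundamental_periods(spectrum, n = 1, ...)
}
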