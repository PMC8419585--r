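# Independent oracles and small fixture builders used across the suite.

# Exhaustive enumeration of all monotone warping paths (diagonal /
# horizontal / vertical unit moves), subject to the same path-length bound
# as the dynamic programme; returns the maximum path-mean similarity.
# Tractable for sequence lengths <= 8.
brute_dtw <- function(a, b, max_warp = 3) {
  n <- length(a); m <- length(b)
  Lmax <- min(n + m - 1, max(max(n, m), ceiling(max_warp * min(n, m))))
  sim <- outer(a, b, function(x, y) 100 * pmin(x, y) / pmax(x, y))
  best <- -Inf
  rec <- function(i, j, len, tot) {
    tot <- tot + sim[i, j]
    if (len > Lmax) return()
    if (i == n && j == m) { best <<- max(best, tot / len); return() }
    if (i < n && j < m) rec(i + 1, j + 1, len + 1, tot)
    if (i < n) rec(i + 1, j, len + 1, tot)
    if (j < m) rec(i, j + 1, len + 1, tot)
  }
  rec(1, 1, 1, 0)
  best
}

# adjusted Rand index between two labelings (independent implementation)
ari <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# two-sided Fisher p for a 2x2 table by direct hypergeometric enumeration
fisher_p_enum <- function(tab) {
  m <- tab[1, 1] + tab[1, 2]
  n <- tab[2, 1] + tab[2, 2]
  k <- tab[1, 1] + tab[2, 1]
  x <- tab[1, 1]
  probs <- dhyper(max(0, k - n):min(k, m), m, n, k)
  p_obs <- dhyper(x, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# direct enumeration of strict interior extrema of a sampled sequence
find_extrema_oracle <- function(f) {
  n <- length(f)
  i <- 2:(n - 1)
  is_max <- f[i] > f[i - 1] & f[i] > f[i + 1]
  is_min <- f[i] < f[i - 1] & f[i] < f[i + 1]
  keep <- is_max | is_min
  data.frame(index = i[keep], is_max = is_max[keep])
}

make_contour <- function(id, t, f, ...) {
  whistle_contour(whistle_id = id, time_s = t, freq_hz = f, ...)
}

make_sweep <- function(id, f0, f1, dur = 1, n = 101, ...) {
  t <- seq(0, dur, length.out = n)
  make_contour(id, t, f0 + (f1 - f0) * t / dur, ...)
}

make_sine <- function(id, carrier, amp, cycles, dur = 1, coverage = 1, ...) {
  generate_contour("oscillatory_sine",
                   list(carrier_hz = carrier, amplitude_hz = amp,
                        n_cycles = cycles, coverage = coverage,
                        duration_s = dur),
                   whistle_id = id, ...)
}

# a small repertoire config shared by recovery-style tests
small_repertoire <- function(seed, n_enc = c(2, 2), wpe = c(25, 25),
                             shared = 6, specific = 2, high = 0, ...) {
  repertoire_config(seed = seed, n_encounters_per_species = n_enc,
                    whistles_per_encounter = wpe, n_shared_types = shared,
                    n_specific_types_per_species = specific,
                    n_high_band_types = high, ...)
}

# ground-truth type membership table for a generated repertoire
gt_membership <- function(rep) {
  meta <- contour_metadata(rep$whistles)
  data.frame(whistle_id = rep$ground_truth$whistle_id,
             type_id = rep$ground_truth$template_type_id,
             species = rep$ground_truth$species,
             encounter_id = meta$encounter_id[match(rep$ground_truth$whistle_id,
                                                    meta$whistle_id)],
             stringsAsFactors = FALSE)
}
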