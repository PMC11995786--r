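# Semi-empirical (histogram) distributions for spell lengths and
# wet-day amounts, in the style of histogram-based weather generators.
#
# Spell lengths are positive integers: if there are at most `n_bins`
# distinct lengths each gets its own unit-width bin (the histogram is then
# exactly the empirical distribution); otherwise `n_bins` equal-width bins
# cover the range. Sampling picks a bin by its probability mass, draws
# uniformly within the bin and rounds back to an integer.

fit_spell_dist <- function(lengths, n_bins = 23L) {
  lengths <- as.integer(lengths[lengths >= 1L])
  if (!length(lengths))
    return(structure(list(breaks = numeric(0), probs = numeric(0), n = 0L),
                     class = "semiempirical"))
  vals <- sort(unique(lengths))
  if (length(vals) <= n_bins) {
    breaks <- c(vals[1L] - 0.5, vals + 0.5)
    counts <- tabulate(match(lengths, vals), nbins = length(vals))
  } else {
    breaks <- seq(min(lengths) - 0.5, max(lengths) + 0.5,
                  length.out = n_bins + 1L)
    counts <- tabulate(findInterval(lengths, breaks, rightmost.closed = TRUE),
                       nbins = n_bins)
  }
  structure(list(breaks = breaks, probs = counts / sum(counts),
                 n = length(lengths)),
            class = "semiempirical")
}

sample_spell_dist <- function(dist, n) {
  if (dist$n == 0L || n == 0L) return(integer(0))
  k <- length(dist$probs)
  bins <- sample.int(k, n, replace = TRUE, prob = dist$probs)
  lo <- dist$breaks[bins]; hi <- dist$breaks[bins + 1L]
  pmax(1L, as.integer(round(lo + stats::runif(n) * (hi - lo))))
}

# Wet-day precipitation amounts: empirical quantile function with linear
# interpolation between order statistics (plotting positions (i-0.5)/n).
# A constant sample collapses to a point mass at that value.
fit_amount_dist <- function(amounts) {
  amounts <- sort(as.numeric(amounts))
  structure(list(q = amounts, n = length(amounts)), class = "empquant")
}

sample_amount_dist <- function(dist, n) {
  if (dist$n == 0L || n == 0L) return(numeric(0))
  if (dist$n == 1L) return(rep(dist$q, n))
  p <- (seq_len(dist$n) - 0.5) / dist$n
  stats::approx(p, dist$q, xout = stats::runif(n), rule = 2)$y
}

dist_mean <- function(dist) {
  if (inherits(dist, "empquant")) {
    if (dist$n == 0L) return(NA_real_)
    return(mean(dist$q))
  }
  if (dist$n == 0L) return(NA_real_)
  mids <- (dist$breaks[-1L] + dist$breaks[-length(dist$breaks)]) / 2
  sum(mids * dist$probs)
}
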