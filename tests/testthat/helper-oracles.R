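# Shared fixtures and independent oracles, built in code at test time.

# A small synthetic cohort reused across tests (20 tiles, study defaults).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_cohort(cohort_spec(n_images = 20L,
                                                          seed = 42L))
    cache
  }
})

cohort_images <- function(co) {
  stats::setNames(lapply(co, `[[`, "image"), vapply(co, `[[`, "", "id"))
}

# Exact 1-D optimal transport cost between two histograms on shared uniform
# edges, by the north-west-corner rule on bin-center supports. For costs
# |x_i - y_j| (convex in i - j) the NW greedy allocation attains the
# linear-program optimum, so this is an exact independent oracle for
# wasserstein1().
nw_transport_cost <- function(counts_a, counts_b, edges) {
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  a <- counts_a / sum(counts_a)
  b <- counts_b / sum(counts_b)
  i <- j <- 1L
  cost <- 0
  while (i <= length(a) && j <= length(b)) {
    m <- min(a[i], b[j])
    cost <- cost + m * abs(centers[i] - centers[j])
    a[i] <- a[i] - m
    b[j] <- b[j] - m
    if (a[i] <= 1e-15) i <- i + 1L else j <- j + 1L
  }
  cost
}

# Textbook two-group Levene statistic (Levene 1960), written independently
# of the package implementation.
levene_oracle <- function(a, b, center = mean) {
  za <- abs(a - center(a))
  zb <- abs(b - center(b))
  z <- c(za, zb)
  ni <- c(length(za), length(zb))
  nn <- sum(ni)
  zi <- c(mean(za), mean(zb))
  zbar <- sum(ni * zi) / nn
  num <- (nn - 2) * sum(ni * (zi - zbar)^2)
  den <- (2 - 1) * (sum((za - zi[1])^2) + sum((zb - zi[2])^2))
  w <- num / den
  list(statistic = w, p_value = pf(w, 1, nn - 2, lower.tail = FALSE))
}

# Knuth log-posterior computed directly from hist() occupancies; used as a
# brute-force argmax oracle for knuth_bins().
knuth_logp_oracle <- function(x, m) {
  edges <- seq(min(x), max(x), length.out = m + 1)
  cnt <- graphics::hist(x, breaks = edges, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)$counts
  n <- length(x)
  n * log(m) + lgamma(m / 2) - m * lgamma(0.5) - lgamma(n + m / 2) +
    sum(lgamma(cnt + 0.5))
}

# Build a density_histogram directly from raw bin counts (synthesizing one
# sample per count unit at each bin center).
hist_from_counts <- function(counts, edges, c_const = 1, stain = "H") {
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  build_density_histogram(rep(centers, counts), edges, c_const = c_const,
                          stain = stain)
}
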