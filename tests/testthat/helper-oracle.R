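# Independent moment oracle: builds each distribution's density (plus any
# boundary atoms) from first principles and integrates on a fine grid.
# Deliberately avoids the closed forms and integrate() calls used by
# analytic_moments().
oracle_moments <- function(spec) {
  grid <- seq(0, 1, length.out = 200001)
  dens <- switch(
    spec$kind,
    uniform = rep(1, length(grid)),
    # X = u^(1/s) has cdf x^s, density s x^(s-1)
    left_skew = spec$skewness * grid^(spec$skewness - 1),
    right_skew = spec$skewness * (1 - grid)^(spec$skewness - 1),
    normal = dnorm(grid, spec$mean, spec$sd),
    bimodal = spec$weight1 * dnorm(grid, spec$mean1, spec$sd1) +
      (1 - spec$weight1) * dnorm(grid, spec$mean2, spec$sd2)
  )
  atom0 <- 0
  atom1 <- 0
  if (spec$kind %in% c("normal", "bimodal")) {
    if (spec$truncation == "clip") {
      lower_mass <- switch(spec$kind,
        normal = pnorm(0, spec$mean, spec$sd),
        bimodal = spec$weight1 * pnorm(0, spec$mean1, spec$sd1) +
          (1 - spec$weight1) * pnorm(0, spec$mean2, spec$sd2))
      upper_mass <- switch(spec$kind,
        normal = pnorm(1, spec$mean, spec$sd, lower.tail = FALSE),
        bimodal = spec$weight1 * pnorm(1, spec$mean1, spec$sd1, lower.tail = FALSE) +
          (1 - spec$weight1) * pnorm(1, spec$mean2, spec$sd2, lower.tail = FALSE))
      atom0 <- lower_mass
      atom1 <- upper_mass
    } else {
      dens <- dens / trapz01(dens, grid)
    }
  }
  m1 <- trapz01(grid * dens, grid) + atom1
  m2 <- trapz01(grid^2 * dens, grid) + atom1
  list(mean = m1, sd = sqrt(m2 - m1^2))
}

trapz01 <- function(y, x) {
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

default_kinds <- c("normal", "bimodal", "uniform", "left_skew", "right_skew")

# Exhaustive best size-k subset sum (oracle for top-k selection).
brute_force_best_subset <- function(values, k) {
  max(combn(values, k, sum))
}
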