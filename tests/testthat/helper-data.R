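# Shared fixtures, built in code. Callers set the RNG seed.

# a random meta-analysis under the generating model, mu = 0
random_dataset <- function(n, tau2 = 0.25, vmin = 0.1, vmax = 1) {
  v <- runif(n, vmin, vmax)
  y <- rnorm(n, 0, sqrt(v + tau2))
  meta_dataset(y, v)
}

# a random equal-variance dataset
random_equal_variance_dataset <- function(n, tau2 = 1, sigma2 = NULL) {
  if (is.null(sigma2)) sigma2 <- runif(1, 0.1, 1)
  meta_dataset(rnorm(n, 0, sqrt(sigma2 + tau2)), rep(sigma2, n))
}

# the worked two-study example used throughout the documentation
toy_dataset <- function() meta_dataset(y = c(0, 1), v = c(0.25, 0.25))

write_effects_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
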