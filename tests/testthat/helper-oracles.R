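# shared fixtures and independent oracles (kept deliberately separate from
# the package implementations they check)

small_config <- function(seed = 42, ...) {
  scenario_config(years = 2003:2008, n_pixels = 60, n_broods_per_year = 8,
                  n_juveniles_per_year = 12, n_stations = 10, seed = seed, ...)
}

# binary snow table simulated directly from the asymmetric-Gaussian model
gen_binary_from_curve <- function(par, n_pixels, seed, days = 60:273) {
  set.seed(seed)
  p_snow <- 1 - snow_curve(days, par)
  data.frame(pixel = rep(seq_len(n_pixels), each = length(days)),
             day = rep(days, n_pixels),
             snow = rbinom(length(days) * n_pixels, 1,
                           rep(p_snow, n_pixels)))
}

# dense-grid posterior mean of source proportions for 2 or 3 sources,
# marginalizing the residual SD over its half-normal prior
grid_posterior_mean <- function(delta, mu, sd, D, Dsd, sres_scale = 0.5,
                                np = 400, ns = 120) {
  K <- length(mu)
  sig <- seq(1e-3, 4 * sres_scale, length.out = ns)
  w_sig <- exp(-sig^2 / (2 * sres_scale^2))
  if (K == 2) {
    p1 <- seq(1e-4, 1 - 1e-4, length.out = np)
    P <- cbind(p1, 1 - p1)
  } else if (K == 3) {
    gr <- seq(1e-4, 1 - 1e-4, length.out = np)
    P <- as.matrix(expand.grid(p1 = gr, p2 = gr))
    P <- P[rowSums(P) < 1, ]
    P <- cbind(P, 1 - rowSums(P))
  } else stop("grid oracle supports 2-3 sources")
  m <- P %*% (mu + D)
  v0 <- P^2 %*% (sd^2 + Dsd^2)
  post <- sapply(seq_along(sig), function(j) {
    v <- v0 + sig[j]^2
    exp(-0.5 * log(2 * pi * v) - (delta - m)^2 / (2 * v)) * w_sig[j]
  })
  w <- rowSums(post)
  w <- w / sum(w)
  as.numeric(t(P) %*% w)
}
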