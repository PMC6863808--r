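# Independent oracles and tiny model constructors used across test files.
# Everything here is written in plain R against the model definition itself
# and deliberately shares no code path with the package internals.

# adjacent-category category probabilities from first principles
oracle_catprob <- function(db_gi, disc_i, theta) {
  cum <- c(0, cumsum(db_gi + disc_i * theta))
  e <- exp(cum - max(cum))
  e / sum(e)
}

# marginal log-likelihood via brute-force trapezoid integration of the
# class-conditional trait on a dense grid
oracle_loglik <- function(params, y, n_grid = 10001, half_width = 8) {
  z <- seq(-half_width, half_width, length.out = n_grid)
  dz <- z[2] - z[1]
  w <- stats::dnorm(z) * dz
  w[c(1, n_grid)] <- w[c(1, n_grid)] / 2     # trapezoid end corrections
  G <- dim(params$delta_beta)[1]
  I <- dim(params$delta_beta)[2]
  sd_g <- if (isTRUE(params$trait_scale_is_variance))
    sqrt(params$trait_scale) else params$trait_scale
  pi_g <- exp(params$class_logit) / sum(exp(params$class_logit))
  ll <- 0
  for (v in seq_len(nrow(y))) {
    lv <- 0
    for (g in seq_len(G)) {
      lik_z <- rep(1, n_grid)
      for (i in seq_len(I)) {
        p_zi <- vapply(z, function(zz)
          oracle_catprob(params$delta_beta[g, i, ],
                         params$item_discrimination[i],
                         sd_g[g] * zz)[y[v, i] + 1L], numeric(1))
        lik_z <- lik_z * p_zi
      }
      lv <- lv + pi_g[g] * sum(w * lik_z)
    }
    ll <- ll + log(lv)
  }
  ll
}

# small random parameter sets for property-style tests
toy_params <- function(G = 2, I = 2, C = 4, seed = 1, scale_max = 0.8) {
  set.seed(seed)
  parameter_set(
    delta_beta = array(stats::runif(G * I * (C - 1), -1.5, 1.5),
                       c(G, I, C - 1)),
    item_discrimination = c(1, if (I > 1) stats::runif(I - 1, 0.6, 1.8)),
    trait_scale = stats::runif(G, 0.1, scale_max),
    class_logit = c(0, if (G > 1) stats::runif(G - 1, -0.8, 0.8)))
}

# permute the class labels of a parameter set (logits re-referenced)
permute_classes <- function(params, perm) {
  pi_g <- exp(params$class_logit) / sum(exp(params$class_logit))
  pi_p <- pi_g[perm]
  parameter_set(params$delta_beta[perm, , , drop = FALSE],
                params$item_discrimination,
                params$trait_scale[perm],
                log(pi_p / pi_p[1]),
                params$trait_scale_is_variance)
}

# quick fit settings for small test models
toy_fit_config <- function(...) {
  defaults <- list(n_quadrature = 21L, n_starts = 2L, start_em_iter = 30L,
                   em_max_iter = 300L)
  do.call(fit_config, utils::modifyList(defaults, list(...)))
}
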