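#' Estimation settings
#'
#' Defaults mirror the simulation study's estimation protocol: EM capped at
#' 10,000 iterations with an absolute log-likelihood-change criterion of 0.01,
#' Newton refinement capped at 600 iterations with a gradient criterion of
#' 1e-8 (scaled by `1 + |loglik|`), 100 start sets of 200 EM iterations each,
#' and 80 Gauss-Hermite quadrature points.
#'
#' @param em_max_iter EM iteration cap
#' @param em_tol absolute change in marginal log-likelihood below which EM
#'   stops
#' @param nr_max_iter Newton-stage iteration cap
#' @param nr_tol gradient max-norm tolerance for the Newton stage, scaled by
#'   `1 + |loglik|`
#' @param nr_factr L-BFGS-B `factr` for the Newton stage (objective-change
#'   stop in units of machine epsilon); lower it for near-exact optima
#' @param n_starts number of random start sets in [multi_start_fit()]
#' @param start_em_iter EM iterations run within each start set
#' @param n_quadrature number of Gauss-Hermite quadrature points
#' @param bayes_categorical optional Dirichlet pseudo-count mass per item,
#'   spread over the class x category x node cells proportional to the
#'   item's observed marginal category distribution; stabilizes sparse
#'   tables at the cost of shrinking genuinely extreme step parameters.
#'   The default 0 gives plain marginal maximum likelihood
#' @param bayes_class optional Dirichlet pseudo-count mass spread over the
#'   latent class sizes
#' @param warm_start optional [parameter_set()] added to the start sets
#' @param se_method `"observed_information"` (finite differences of the
#'   analytic score) or `"opg"` (outer product of per-respondent scores)
#' @param bound_delta_beta clamp on |delta-beta| during estimation; a
#'   parameter at the clamp is flagged as a boundary value
#' @param bound_trait_scale lower/upper clamp for trait scales
#' @param bound_discrimination lower/upper clamp for discriminations
#' @param bound_class_logit clamp on |class logit|
#' @return list of class `mixirt_fit_config`
#' @export
fit_config <- function(em_max_iter = 10000L, em_tol = 0.01,
                       nr_max_iter = 600L, nr_tol = 1e-8, nr_factr = 1e7,
                       n_starts = 100L, start_em_iter = 200L,
                       n_quadrature = 80L,
                       bayes_categorical = 0, bayes_class = 0,
                       warm_start = NULL,
                       se_method = c("observed_information", "opg"),
                       bound_delta_beta = 50,
                       bound_trait_scale = c(1e-4, 10),
                       bound_discrimination = c(1e-2, 100),
                       bound_class_logit = 20) {
  stopifnot(em_tol > 0, nr_tol > 0, em_max_iter >= 1, nr_max_iter >= 1,
            n_starts >= 1, start_em_iter >= 1, n_quadrature >= 2)
  structure(list(em_max_iter = as.integer(em_max_iter), em_tol = em_tol,
                 nr_max_iter = as.integer(nr_max_iter), nr_tol = nr_tol,
                 nr_factr = nr_factr,
                 n_starts = as.integer(n_starts),
                 start_em_iter = as.integer(start_em_iter),
                 n_quadrature = as.integer(n_quadrature),
                 bayes_categorical = bayes_categorical,
                 bayes_class = bayes_class,
                 warm_start = warm_start,
                 se_method = match.arg(se_method),
                 bound_delta_beta = bound_delta_beta,
                 bound_trait_scale = bound_trait_scale,
                 bound_discrimination = bound_discrimination,
                 bound_class_logit = bound_class_logit),
            class = "mixirt_fit_config")
}

# ---- free-parameter vectorization --------------------------------------

# Free coordinates, in a fixed order: all delta-betas (array order), then
# discriminations of items 2..I (rmGPCM only), then trait scales, then class
# logits of classes 2..G.
free_par_info <- function(params) {
  d <- dim(params$delta_beta)
  G <- d[1]; I <- d[2]; S <- d[3]
  equal <- params_spec(params)$equal_discrimination
  n_disc <- if (equal) 0L else I - 1L
  list(G = G, I = I, S = S, equal = equal,
       i_db = seq_len(G * I * S),
       i_disc = if (n_disc) G * I * S + seq_len(n_disc) else integer(),
       i_scale = G * I * S + n_disc + seq_len(G),
       i_logit = if (G > 1) G * I * S + n_disc + G + seq_len(G - 1L)
                 else integer(),
       n = G * I * S + n_disc + G + (G - 1L))
}

free_par <- function(params) {
  fp <- free_par_info(params)
  v <- c(as.numeric(params$delta_beta),
         if (!fp$equal) params$item_discrimination[-1],
         params$trait_scale,
         if (fp$G > 1) params$class_logit[-1])
  names(v) <- free_par_names(fp)
  v
}

free_par_names <- function(fp) {
  gis <- expand.grid(g = seq_len(fp$G), i = seq_len(fp$I), s = seq_len(fp$S))
  c(sprintf("db_g%d_i%d_s%d", gis$g, gis$i, gis$s),
    if (!fp$equal) sprintf("disc_i%d", 2:fp$I),
    sprintf("scale_g%d", seq_len(fp$G)),
    if (fp$G > 1) sprintf("logit_g%d", 2:fp$G))
}

set_free_par <- function(params, v) {
  fp <- free_par_info(params)
  params$delta_beta[] <- v[fp$i_db]
  if (!fp$equal) params$item_discrimination <- c(1, v[fp$i_disc])
  params$trait_scale <- v[fp$i_scale]
  if (fp$G > 1) params$class_logit <- c(0, v[fp$i_logit])
  params
}

free_par_bounds <- function(params, config) {
  fp <- free_par_info(params)
  lower <- upper <- numeric(fp$n)
  lower[fp$i_db] <- -config$bound_delta_beta
  upper[fp$i_db] <- config$bound_delta_beta
  if (length(fp$i_disc)) {
    lower[fp$i_disc] <- config$bound_discrimination[1]
    upper[fp$i_disc] <- config$bound_discrimination[2]
  }
  lower[fp$i_scale] <- config$bound_trait_scale[1]
  upper[fp$i_scale] <- config$bound_trait_scale[2]
  if (length(fp$i_logit)) {
    lower[fp$i_logit] <- -config$bound_class_logit
    upper[fp$i_logit] <- config$bound_class_logit
  }
  list(lower = lower, upper = upper)
}

# ---- score via Fisher's identity ----------------------------------------

# Gradient of the marginal log-likelihood at the parameters the E-step
# statistics were computed at: expected complete-data gradient (Fisher's
# identity). st comes from estep().
score_from_stats <- function(params, st, grid) {
  fp <- free_par_info(params)
  G <- fp$G; I <- fp$I; S <- fp$S; C <- S + 1L
  cats <- 0:(C - 1L)
  sd_g <- trait_sd(params)
  dsd <- if (isTRUE(params$trait_scale_is_variance))
    1 / (2 * pmax(sd_g, 1e-12)) else rep(1, G)
  g_db <- array(0, c(G, I, S))
  g_disc <- numeric(I)
  g_scale <- numeric(G)
  for (g in seq_len(G)) {
    t_q <- sd_g[g] * grid$nodes
    n_q <- st$n_item[g, ]
    for (i in seq_len(I)) {
      P <- matrix(st$prob[, i, g, ], C)
      Wm <- matrix(st$W[, i, g, ], C)
      # survivor functions P(X >= s), s = 1..S, by node
      Ssur <- apply(P[C:1, , drop = FALSE], 2, cumsum)[C:1, , drop = FALSE][-1, , drop = FALSE]
      Usur <- apply(Wm[C:1, , drop = FALSE], 2, cumsum)[C:1, , drop = FALSE][-1, , drop = FALSE]
      g_db[g, i, ] <- rowSums(Usur - sweep(Ssur, 2, n_q, `*`))
      mu <- colSums(P * cats)
      ybar <- colSums(Wm * cats)
      resid <- ybar - n_q * mu
      g_disc[i] <- g_disc[i] + sum(t_q * resid)
      g_scale[g] <- g_scale[g] +
        sum(grid$nodes * params$item_discrimination[i] * resid)
    }
  }
  g_scale <- g_scale * dsd
  alpha <- st$bayes_class %||% 0
  N_g <- rowSums(st$n_gq) + alpha / G
  pi_g <- class_proportions(params$class_logit)
  g_logit <- N_g - sum(N_g) * pi_g
  v <- c(as.numeric(g_db),
         if (!fp$equal) g_disc[-1],
         g_scale,
         if (G > 1) g_logit[-1])
  names(v) <- free_par_names(fp)
  v
}

# ---- EM ------------------------------------------------------------------

# One generalized M-step: closed-form class logits plus one damped Newton step
# per parameter block on the expected complete-data log-likelihood.
mstep <- function(params, st, grid, config) {
  fp <- free_par_info(params)
  G <- fp$G; I <- fp$I; S <- fp$S; C <- S + 1L
  cats <- 0:(C - 1L)
  sd_g <- trait_sd(params)

  N_g <- rowSums(st$n_gq) + (st$bayes_class %||% 0) / G
  N <- sum(N_g)
  pi_new <- pmax(N_g / N, 1e-12)
  logit_new <- log(pi_new / pi_new[1])
  logit_new <- pmin(pmax(logit_new, -config$bound_class_logit),
                    config$bound_class_logit)
  logit_new[1] <- 0

  db_step <- array(0, c(G, I, S))
  disc_step <- numeric(I)
  scale_step <- numeric(G)
  h_disc <- numeric(I)
  g_disc <- numeric(I)
  h_scale <- numeric(G)
  g_scale <- numeric(G)

  for (g in seq_len(G)) {
    t_q <- sd_g[g] * grid$nodes
    n_q <- st$n_item[g, ]
    for (i in seq_len(I)) {
      P <- matrix(st$prob[, i, g, ], C)
      Wm <- matrix(st$W[, i, g, ], C)
      Ssur <- apply(P[C:1, , drop = FALSE], 2, cumsum)[C:1, , drop = FALSE][-1, , drop = FALSE]
      Usur <- apply(Wm[C:1, , drop = FALSE], 2, cumsum)[C:1, , drop = FALSE][-1, , drop = FALSE]
      grad <- rowSums(Usur - sweep(Ssur, 2, n_q, `*`))
      # negative Hessian of the expected complete-data loglik in delta-beta:
      # H[s, r] = sum_q n_q (S_max(s,r) - S_s S_r)
      b <- as.numeric(Ssur %*% n_q)
      Hneg <- outer(seq_len(S), seq_len(S),
                    function(s, r) b[pmax(s, r)]) -
        sweep(Ssur, 2, n_q, `*`) %*% t(Ssur)
      ridge <- 1e-6 * max(diag(Hneg), 1)
      step_gi <- tryCatch(
        solve(Hneg + diag(ridge, S), grad),
        error = function(e) grad / pmax(diag(Hneg), 1e-8))
      # trust region: along data-poor (near-null) directions the Newton step
      # is unbounded while the gradient is flat; cap the per-iteration move
      # so such coordinates drift instead of escaping
      big <- max(abs(step_gi))
      if (big > 1) step_gi <- step_gi / big
      db_step[g, i, ] <- step_gi
      mu <- colSums(P * cats)
      v2 <- colSums(P * cats^2) - mu^2
      ybar <- colSums(Wm * cats)
      resid <- ybar - n_q * mu
      g_disc[i] <- g_disc[i] + sum(t_q * resid)
      h_disc[i] <- h_disc[i] + sum(n_q * t_q^2 * v2)
      a_i <- params$item_discrimination[i]
      g_scale[g] <- g_scale[g] + sum(grid$nodes * a_i * resid)
      h_scale[g] <- h_scale[g] + sum(n_q * grid$nodes^2 * a_i^2 * v2)
    }
  }
  if (!fp$equal)
    disc_step <- pmin(pmax(g_disc / pmax(h_disc, 1e-10), -0.5), 0.5)
  scale_sd_step <- pmin(pmax(g_scale / pmax(h_scale, 1e-10), -0.25), 0.25)

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  candidate <- function(step_scale) {
    p <- params
    p$delta_beta <- clamp(params$delta_beta + step_scale * db_step,
                          -config$bound_delta_beta, config$bound_delta_beta)
    if (!fp$equal)
      p$item_discrimination <-
        c(1, clamp(params$item_discrimination[-1] +
                     step_scale * disc_step[-1],
                   config$bound_discrimination[1],
                   config$bound_discrimination[2]))
    sd_new <- clamp(sd_g + step_scale * scale_sd_step,
                    config$bound_trait_scale[1], config$bound_trait_scale[2])
    p$trait_scale <- if (isTRUE(params$trait_scale_is_variance)) sd_new^2
                     else sd_new
    p$class_logit <- logit_new
    p
  }
  qfun <- function(p) {
    sum(st$W * item_logprob_table(p, grid)) +
      sum(N_g * log(pmax(class_proportions(p$class_logit), 1e-300)))
  }
  q0 <- qfun(params)
  step <- 1
  for (k in 1:30) {
    cand <- candidate(step)
    if (qfun(cand) >= q0 - 1e-10) return(cand)
    step <- step / 2
  }
  # no ascent step found in the item blocks; keep them, update class sizes only
  cand <- params
  cand$class_logit <- logit_new
  cand
}

#' Fit a mixture adjacent-category model by EM from one start
#'
#' Marginal maximum likelihood via a generalized EM algorithm: the E-step
#' computes joint posteriors over (class, quadrature node); the M-step updates
#' class logits in closed form and the item and trait-scale parameters by one
#' damped Newton step per block on the expected complete-data log-likelihood
#' (step-halved until the expected complete-data criterion does not decrease,
#' so the marginal log-likelihood is non-decreasing across iterations).
#'
#' @param data a [response_matrix()] or response matrix
#' @param start starting [parameter_set()] (identification constraints must
#'   hold: first discrimination 1, first class logit 0)
#' @param config a [fit_config()]
#' @return object of class `mixirt_fit`: estimates, log-likelihood,
#'   iteration counts and convergence flags, posterior class probabilities,
#'   mean assignment probability, per-parameter boundary flags
#' @export
fit_em <- function(data, start, config = fit_config()) {
  y <- response_codes(data, start)
  grid <- build_quadrature(config$n_quadrature)
  params <- start
  st <- estep(params, y, grid,
              bayes_categorical = config$bayes_categorical,
              bayes_class = config$bayes_class)
  if (!is.finite(st$loglik))
    stop("non-finite marginal log-likelihood at the starting values")
  converged <- FALSE
  iter <- 0L
  trace <- st$objective
  while (iter < config$em_max_iter) {
    params_new <- mstep(params, st, grid, config)
    st_new <- estep(params_new, y, grid,
                    bayes_categorical = config$bayes_categorical,
                    bayes_class = config$bayes_class)
    iter <- iter + 1L
    if (!is.finite(st_new$loglik))
      stop("non-finite marginal log-likelihood during EM")
    delta <- st_new$objective - st$objective
    params <- params_new
    st <- st_new
    trace <- c(trace, st$objective)
    if (abs(delta) < config$em_tol) { converged <- TRUE; break }
  }
  fit <- finalize_fit(params, y, grid, config,
                      em_iterations = iter, em_converged = converged)
  fit$loglik_trace <- trace
  fit
}

# assemble a mixirt_fit from final parameters
finalize_fit <- function(params, y, grid, config, em_iterations = NA_integer_,
                         em_converged = NA, nr_iterations = 0L,
                         nr_converged = NA) {
  st <- estep(params, y, grid, want_posterior = TRUE,
              bayes_categorical = config$bayes_categorical,
              bayes_class = config$bayes_class)
  post <- st$posterior
  post <- post / rowSums(post)
  spec <- params_spec(params)
  bounds <- free_par_bounds(params, config)
  v <- free_par(params)
  at_bound <- v <= bounds$lower + 1e-8 | v >= bounds$upper - 1e-8
  class_mass <- colSums(post)
  structure(
    list(spec = spec, estimates = params, loglik = st$loglik,
         objective = st$objective,
         n_free_parameters = count_free_parameters(spec),
         em_iterations = em_iterations, em_converged = em_converged,
         nr_iterations = nr_iterations, nr_converged = nr_converged,
         posterior = post,
         mean_assignment_probability = mean(apply(post, 1, max)),
         boundary_par = at_bound,
         posterior_degenerate = any(class_mass < 1e-8),
         standard_errors = NULL, boundary_se = NULL, improper = NA,
         grid = grid, config = config),
    class = "mixirt_fit")
}

#' @export
print.mixirt_fit <- function(x, ...) {
  cat(sprintf(paste0("%s fit: loglik %.3f, %d free parameters, EM %s in %d ",
                     "iterations%s\n"),
              if (x$spec$equal_discrimination) "mPCM" else "rmGPCM",
              x$loglik, x$n_free_parameters,
              if (isTRUE(x$em_converged)) "converged" else "stopped",
              x$em_iterations,
              if (is.na(x$nr_converged)) "" else
                sprintf(", NR %s", if (isTRUE(x$nr_converged)) "converged"
                        else "not converged")))
  invisible(x)
}

#' Newton-stage refinement of an EM solution
#'
#' Quasi-Newton (L-BFGS-B) ascent on the marginal log-likelihood over the
#' free parameters, with the analytic score obtained from E-step statistics
#' by Fisher's identity. Never returns a solution with a lower
#' log-likelihood than its input; on failure the EM solution is returned with
#' `nr_converged = FALSE`.
#'
#' @param fit a `mixirt_fit` from [fit_em()]
#' @param data the data the fit was computed on
#' @param config a [fit_config()]
#' @return the refined `mixirt_fit`
#' @export
refine_newton <- function(fit, data, config = fit_config()) {
  y <- response_codes(data, fit$estimates)
  grid <- fit$grid
  params0 <- fit$estimates
  v0 <- free_par(params0)
  bounds <- free_par_bounds(params0, config)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(v) {
    key <- paste(v, collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    p <- set_free_par(params0, v)
    st <- estep(p, y, grid,
                bayes_categorical = config$bayes_categorical,
                bayes_class = config$bayes_class)
    val <- list(ll = st$objective, grad = score_from_stats(p, st, grid))
    cache$key <- key
    cache$val <- val
    val
  }
  objective0 <- fit$objective %||% fit$loglik
  scaled_tol <- config$nr_tol * (1 + abs(objective0))
  opt <- tryCatch(
    stats::optim(v0, fn = function(v) -evaluate(v)$ll,
                 gr = function(v) -evaluate(v)$grad,
                 method = "L-BFGS-B",
                 lower = bounds$lower, upper = bounds$upper,
                 control = list(maxit = config$nr_max_iter,
                                pgtol = scaled_tol,
                                factr = config$nr_factr %||% 1e7)),
    error = function(e) NULL)
  if (is.null(opt) || -opt$value < objective0 - 1e-10) {
    out <- fit
    out$nr_converged <- FALSE
    out$nr_iterations <- if (is.null(opt)) 0L else unname(opt$counts[2])
    return(out)
  }
  params1 <- set_free_par(params0, opt$par)
  final <- evaluate(opt$par)
  out <- finalize_fit(params1, y, grid, config,
                      em_iterations = fit$em_iterations,
                      em_converged = fit$em_converged,
                      nr_iterations = unname(opt$counts[2]),
                      nr_converged = max(abs(final$grad)) < scaled_tol * 1.001)
  if (out$objective < objective0) { out <- fit; out$nr_converged <- FALSE }
  out
}

#' Random starting values
#'
#' Delta-betas uniform on (-2, 2), discriminations log-uniform on (0.5, 2)
#' (free items of an rmGPCM only), class logits uniform on (-1, 1), trait
#' scales uniform on (0.1, 1); spans the range of the bundled generating
#' parameters.
#'
#' @param spec a [model_spec()]
#' @param seed integer seed
#' @return a [parameter_set()]
#' @export
random_start <- function(spec, seed) {
  set.seed(as.integer(seed))
  G <- spec$n_classes; I <- spec$n_items; S <- spec$n_categories - 1L
  db <- array(stats::runif(G * I * S, -2, 2), c(G, I, S))
  disc <- if (spec$equal_discrimination) rep(1, I)
          else c(1, exp(stats::runif(I - 1L, log(0.5), log(2))))
  parameter_set(db, disc, stats::runif(G, 0.1, 1),
                c(0, stats::runif(G - 1L, -1, 1)))
}

#' Multiple-start estimation
#'
#' Runs a capped number of EM iterations from each start set (random starts
#' plus an optional warm start at supplied values), continues the best
#' candidate by log-likelihood to full EM convergence, and finishes with the
#' Newton refinement stage. Deterministic given `seed`.
#'
#' @param data a [response_matrix()] or response matrix
#' @param spec a [model_spec()]
#' @param config a [fit_config()]; `config$warm_start` joins the start sets
#' @param seed integer seed for the random starts
#' @return the best `mixirt_fit`
#' @export
multi_start_fit <- function(data, spec, config = fit_config(), seed = 1L) {
  starts <- lapply(seq_len(config$n_starts), function(k)
    random_start(spec, seed = as.integer(seed) + 7L * k))
  if (!is.null(config$warm_start))
    starts <- c(list(config$warm_start), starts)
  short_cfg <- config
  short_cfg$em_max_iter <- config$start_em_iter
  candidates <- lapply(starts, function(s)
    tryCatch(fit_em(data, s, short_cfg), error = function(e) NULL))
  lls <- vapply(candidates, function(f)
    if (is.null(f)) -Inf else f$loglik, numeric(1))
  if (all(!is.finite(lls)))
    stop("no start set produced a finite log-likelihood")
  best <- candidates[[which.max(lls)]]
  full <- fit_em(data, best$estimates, config)
  refine_newton(full, data, config)
}

# ---- standard errors ----------------------------------------------------

#' Standard errors for a fitted model
#'
#' `observed_information`: the Hessian of the marginal log-likelihood is
#' approximated by central finite differences of the analytic score; standard
#' errors are square roots of the diagonal of the inverse of the negative
#' Hessian over the free parameters. `opg`: the information matrix is the sum
#' of outer products of per-respondent scores.
#'
#' A standard error is flagged as a boundary value when the information
#' matrix is not positive definite along that coordinate, the standard error
#' exceeds 1e4, or the parameter itself sits at its clamp.
#'
#' @param fit a `mixirt_fit`
#' @param data the fitted data
#' @param config a [fit_config()]
#' @return the fit with `standard_errors`, `boundary_se` (both shaped like
#'   the parameter set) and `improper` filled in
#' @export
compute_standard_errors <- function(fit, data, config = fit_config()) {
  y <- response_codes(data, fit$estimates)
  grid <- fit$grid
  params <- fit$estimates
  v <- free_par(params)
  p <- length(v)
  flags <- rep(FALSE, p)
  if (config$se_method == "observed_information") {
    H <- matrix(0, p, p)
    for (j in seq_len(p)) {
      h <- 1e-4 * max(1, abs(v[j]))
      vp <- v; vp[j] <- v[j] + h
      vm <- v; vm[j] <- v[j] - h
      sp <- score_at(params, vp, y, grid, config)
      sm <- score_at(params, vm, y, grid, config)
      H[, j] <- (sp - sm) / (2 * h)
    }
    info <- -(H + t(H)) / 2
  } else {
    sc <- per_respondent_scores(params, y, grid)
    info <- crossprod(sc)
  }
  # parameters sitting at their clamp are not interior free coordinates:
  # drop them from the inversion (their ~zero information otherwise
  # contaminates the other standard errors through the inverse)
  active <- !fit$boundary_par
  se <- rep(NA_real_, p)
  info_a <- info[active, active, drop = FALSE]
  if (!any(active)) {
    fit$standard_errors <- shape_like_params(params, se)
    fit$boundary_se <- shape_like_params(params, rep(TRUE, p))
    return(diagnose_solution(fit))
  }
  # spectrally truncated inverse: eigendirections whose information is below
  # 1e-9 of the largest are zero up to the accuracy of the finite-difference
  # Hessian, and inverting them would let numerical noise in the cross-terms
  # contaminate every other standard error. Coordinates living mostly in the
  # truncated space get their marginal standard error 1/sqrt(info_jj)
  # instead (typically enormous, so the SE > 50 trimming rule eliminates
  # them); coordinates in genuinely negative-curvature directions are
  # flagged as boundary values.
  eg <- eigen(info_a, symmetric = TRUE)
  scale_ev <- max(abs(eg$values))
  pos <- eg$values > scale_ev * 1e-9
  inv_vals <- ifelse(pos, 1 / eg$values, 0)
  cov <- eg$vectors %*% (inv_vals * t(eg$vectors))
  se_a <- sqrt(pmax(diag(cov), 0))
  if (!all(pos)) {
    weak <- rowSums(eg$vectors[, !pos, drop = FALSE]^2) > 0.5
    se_a[weak] <- 1 / sqrt(pmax(diag(info_a)[weak], 1e-300))
    neg <- eg$values < -scale_ev * 1e-9
    if (any(neg)) {
      neg_load <- rowSums(eg$vectors[, neg, drop = FALSE]^2)
      flags[active] <- flags[active] | neg_load > 0.5
    }
  }
  se[active] <- se_a
  flags <- flags | !is.finite(se) | se > 1e4 | fit$boundary_par
  fit$standard_errors <- shape_like_params(params, se)
  fit$boundary_se <- shape_like_params(params, flags)
  diagnose_solution(fit)
}

score_at <- function(params, v, y, grid, config) {
  p <- set_free_par(params, v)
  st <- estep(p, y, grid,
              bayes_categorical = config$bayes_categorical,
              bayes_class = config$bayes_class)
  score_from_stats(p, st, grid)
}

# map a free-parameter vector back into parameter-set shaped blocks; fixed
# coordinates (first discrimination, first class logit) become NA
shape_like_params <- function(params, v) {
  fp <- free_par_info(params)
  db <- array(v[fp$i_db], c(fp$G, fp$I, fp$S))
  disc <- if (fp$equal) rep(NA, fp$I) else c(NA, v[fp$i_disc])
  logit <- if (fp$G > 1) c(NA, v[fp$i_logit]) else NA
  list(delta_beta = db, item_discrimination = disc,
       trait_scale = v[fp$i_scale], class_logit = logit)
}

# per-respondent score vectors (N x p), used by the OPG information estimate
per_respondent_scores <- function(params, y, grid) {
  fp <- free_par_info(params)
  G <- fp$G; I <- fp$I; S <- fp$S; C <- S + 1L
  N <- nrow(y)
  st <- estep(params, y, grid, want_joint = TRUE)
  joint <- st$joint                      # N x (G*Q)
  Q <- length(grid$nodes)
  sd_g <- trait_sd(params)
  dsd <- if (isTRUE(params$trait_scale_is_variance))
    1 / (2 * pmax(sd_g, 1e-12)) else rep(1, G)
  sc <- matrix(0, N, fp$n)
  colnames(sc) <- free_par_names(fp)
  pi_g <- class_proportions(params$class_logit)
  post_class <- sapply(seq_len(G), function(g)
    rowSums(joint[, g + G * (seq_len(Q) - 1L), drop = FALSE]))
  for (g in seq_len(G)) {
    Pg <- joint[, g + G * (seq_len(Q) - 1L), drop = FALSE]  # N x Q
    t_q <- sd_g[g] * grid$nodes
    for (i in seq_len(I)) {
      P <- matrix(st$prob[, i, g, ], C)
      Ssur <- apply(P[C:1, , drop = FALSE], 2, cumsum)[C:1, , drop = FALSE][-1, , drop = FALSE]
      mu <- colSums(P * (0:(C - 1L)))
      ind <- outer(y[, i], seq_len(S), `>=`)          # N x S
      term <- ind * rowSums(Pg) - Pg %*% t(Ssur)      # N x S
      idx <- fp$i_db[(seq_len(S) - 1L) * G * I + (i - 1L) * G + g]
      sc[, idx] <- sc[, idx] + term
      disc_term <- y[, i] * as.numeric(Pg %*% t_q) -
        as.numeric(Pg %*% (t_q * mu))
      if (!fp$equal && i > 1)
        sc[, fp$i_disc[i - 1L]] <- sc[, fp$i_disc[i - 1L]] + disc_term
      a_i <- params$item_discrimination[i]
      node_term <- y[, i] * as.numeric(Pg %*% (a_i * grid$nodes)) -
        as.numeric(Pg %*% (a_i * grid$nodes * mu))
      sc[, fp$i_scale[g]] <- sc[, fp$i_scale[g]] + node_term * dsd[g]
    }
  }
  if (G > 1)
    sc[, fp$i_logit] <- post_class[, -1, drop = FALSE] -
      matrix(pi_g[-1], N, G - 1L, byrow = TRUE)
  sc
}

#' Posterior class membership
#'
#' Bayes-rule posteriors from class-weighted, quadrature-integrated pattern
#' likelihoods, plus the mean over respondents of the maximum posterior entry
#' (the mean classification probability).
#'
#' @param fit a `mixirt_fit`
#' @param data the fitted data
#' @return list with `posterior` (N x G) and `mean_assignment_probability`
#' @export
posterior_classification <- function(fit, data) {
  y <- response_codes(data, fit$estimates)
  st <- estep(fit$estimates, y, fit$grid, want_posterior = TRUE)
  post <- st$posterior / rowSums(st$posterior)
  list(posterior = post,
       mean_assignment_probability = mean(apply(post, 1, max)))
}

#' Improper-solution diagnosis
#'
#' A solution is improper when strictly more than 10% of its standard errors
#' are boundary values.
#'
#' @param fit a `mixirt_fit` with computed standard errors
#' @return the fit with `improper` set and a `boundary_summary` table
#'   (counts by parameter type and class)
#' @export
diagnose_solution <- function(fit) {
  if (is.null(fit$boundary_se))
    stop("compute_standard_errors() must be run before diagnosis")
  b <- fit$boundary_se
  flags <- c(as.logical(b$delta_beta),
             b$item_discrimination[!is.na(b$item_discrimination)],
             b$trait_scale,
             b$class_logit[!is.na(b$class_logit)])
  fit$improper <- mean(flags) > 0.10
  G <- fit$spec$n_classes
  fit$boundary_summary <- data.frame(
    parameter_type = c(rep("delta_beta", G), "discrimination",
                       rep("trait_scale", G), rep("class_logit", G)),
    class = c(seq_len(G), NA, seq_len(G), seq_len(G)),
    n_boundary = c(vapply(seq_len(G), function(g)
      sum(b$delta_beta[g, , ]), numeric(1)),
      sum(b$item_discrimination, na.rm = TRUE),
      as.numeric(b$trait_scale),
      vapply(seq_len(G), function(g)
        sum(b$class_logit[g], na.rm = TRUE), numeric(1))))
  fit
}
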