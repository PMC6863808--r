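#' Model dimensions for a mixture adjacent-category model
#'
#' A model specification holds the dimensions of a mixture partial credit
#' family model: number of items, number of ordered response categories
#' (coded `0 .. n_categories - 1`), number of latent classes, and whether all
#' item discriminations are constrained to one (mixed PCM) or vary freely over
#' items while staying equal across classes (restricted mixed GPCM).
#'
#' @param n_items number of items (>= 1)
#' @param n_categories number of ordered response categories (>= 2)
#' @param n_classes number of latent classes (>= 1)
#' @param equal_discrimination if `TRUE` the model is a mixed PCM (all item
#'   discriminations fixed at 1); if `FALSE` a restricted mixed GPCM (first
#'   item discrimination fixed at 1 for identification, the rest free).
#' @return an object of class `mixirt_spec`
#' @export
model_spec <- function(n_items, n_categories, n_classes,
                       equal_discrimination = FALSE) {
  stopifnot(n_items >= 1, n_categories >= 2, n_classes >= 1)
  structure(
    list(n_items = as.integer(n_items),
         n_categories = as.integer(n_categories),
         n_classes = as.integer(n_classes),
         equal_discrimination = isTRUE(equal_discrimination)),
    class = "mixirt_spec")
}

#' @export
print.mixirt_spec <- function(x, ...) {
  cat(sprintf("%s: %d classes, %d items, %d categories\n",
              if (x$equal_discrimination) "mPCM" else "rmGPCM",
              x$n_classes, x$n_items, x$n_categories))
  invisible(x)
}

#' Parameter set of a mixture adjacent-category model
#'
#' Container for the full generating or estimated parameter vector in the
#' logistic (adjacent-category) parameterization: class- and item-specific
#' delta-beta step parameters, item discriminations, class-specific latent
#' trait scales, and multinomial-logit class-size parameters.
#'
#' The adjacent-category logit of step `s` for item `i` in class `g` at trait
#' value `theta` is `delta_beta[g, i, s] + discrimination[i] * theta`, and the
#' trait of a class-`g` respondent is `trait_scale[g] * z` with `z` standard
#' normal (or `sqrt(trait_scale[g]) * z` when `trait_scale_is_variance`).
#'
#' @param delta_beta numeric array `[class, item, step]` of adjacent-category
#'   step parameters (`step = 1 .. n_categories - 1`), logit units
#' @param item_discrimination positive numeric vector per item; first entry
#'   must be 1 (identification constraint); all 1 for an mPCM
#' @param trait_scale non-negative numeric vector per class: scale of the
#'   standard-normal latent trait within each class
#' @param class_logit numeric vector per class of multinomial-logit class-size
#'   parameters; first entry must be 0 (reference class)
#' @param trait_scale_is_variance interpret `trait_scale` as the within-class
#'   trait variance rather than its standard deviation
#' @return an object of class `mixirt_params`
#' @export
parameter_set <- function(delta_beta, item_discrimination, trait_scale,
                          class_logit, trait_scale_is_variance = FALSE) {
  delta_beta <- as.array(delta_beta)
  stopifnot(length(dim(delta_beta)) == 3)
  G <- dim(delta_beta)[1]; I <- dim(delta_beta)[2]
  if (length(item_discrimination) != I)
    stop("item_discrimination must have one entry per item")
  if (any(item_discrimination <= 0))
    stop("item discriminations must be strictly positive")
  if (abs(item_discrimination[1] - 1) > 1e-12)
    stop("first item discrimination must be fixed at 1")
  if (length(trait_scale) != G || length(class_logit) != G)
    stop("trait_scale and class_logit must have one entry per class")
  if (abs(class_logit[1]) > 1e-12)
    stop("first class logit must be fixed at 0")
  if (any(trait_scale < 0)) stop("trait_scale must be non-negative")
  structure(
    list(delta_beta = delta_beta,
         item_discrimination = as.numeric(item_discrimination),
         trait_scale = as.numeric(trait_scale),
         class_logit = as.numeric(class_logit),
         trait_scale_is_variance = isTRUE(trait_scale_is_variance)),
    class = "mixirt_params")
}

#' @export
print.mixirt_params <- function(x, ...) {
  d <- dim(x$delta_beta)
  cat(sprintf(paste0("mixture adjacent-category parameter set: ",
                     "%d classes, %d items, %d categories\n"),
              d[1], d[2], d[3] + 1))
  cat("class proportions:",
      paste(sprintf("%.3f", class_proportions(x$class_logit)), collapse = " "),
      "\n")
  invisible(x)
}

# dimensions implied by a parameter set
params_spec <- function(params) {
  d <- dim(params$delta_beta)
  equal <- all(abs(params$item_discrimination - 1) < 1e-12)
  model_spec(d[2], d[3] + 1L, d[1], equal)
}

# within-class trait standard deviations under either reading of trait_scale
trait_sd <- function(params) {
  if (isTRUE(params$trait_scale_is_variance)) sqrt(params$trait_scale)
  else params$trait_scale
}

#' Class proportions from multinomial-logit class-size parameters
#'
#' @param class_logit numeric vector of class-size logits, first entry 0
#'   (reference class)
#' @return vector of positive class proportions summing to 1 (softmax)
#' @examples
#' class_proportions(c(0, 0.20, -0.18))  # approx 0.33, 0.40, 0.27
#' @export
class_proportions <- function(class_logit) {
  if (abs(class_logit[1]) > 1e-12)
    stop("first class logit must be 0 (reference class constraint)")
  e <- exp(class_logit - max(class_logit))
  e / sum(e)
}

#' Category response probabilities for one class, item and trait value
#'
#' Evaluates the adjacent-category logit model: the log odds of category `x`
#' against `x - 1` equals `delta_beta[g, i, x] + discrimination[i] * trait`.
#' Probabilities are computed by log-sum-exp over cumulative step logits.
#'
#' @param params a [parameter_set()]
#' @param class latent class index
#' @param item item index
#' @param trait realized latent trait value (finite); note this is the trait
#'   value itself, the class trait scale is applied by the caller
#' @return probability vector over categories `0 .. n_categories - 1`
#' @export
category_probabilities <- function(params, class, item, trait) {
  d <- dim(params$delta_beta)
  if (class < 1 || class > d[1]) stop("class index out of range")
  if (item < 1 || item > d[2]) stop("item index out of range")
  if (!is.finite(trait)) stop("trait must be finite")
  eta <- params$delta_beta[class, item, ] +
    params$item_discrimination[item] * trait
  cum <- c(0, cumsum(eta))
  p <- exp(cum - max(cum))
  p / sum(p)
}

#' Convert between the logistic and the IRT threshold parameterization
#'
#' The IRT form writes the adjacent-category logit as
#' `discrimination[i] * (trait - threshold[g, i, s])`, so
#' `threshold = -delta_beta / discrimination`. The two parameterizations give
#' identical response probabilities.
#'
#' @param params a [parameter_set()]
#' @return list with `threshold` (array `[class, item, step]`) and
#'   `discrimination` (per item)
#' @export
to_irt_parameters <- function(params) {
  if (any(params$item_discrimination <= 0))
    stop("discriminations must be strictly positive")
  tau <- params$delta_beta
  for (i in seq_along(params$item_discrimination))
    tau[, i, ] <- -params$delta_beta[, i, ] / params$item_discrimination[i]
  list(threshold = tau, discrimination = params$item_discrimination)
}

#' @rdname to_irt_parameters
#' @param threshold threshold array `[class, item, step]`
#' @param discrimination item discrimination vector
#' @param trait_scale,class_logit,trait_scale_is_variance passed through to
#'   [parameter_set()]
#' @export
from_irt_parameters <- function(threshold, discrimination, trait_scale,
                                class_logit, trait_scale_is_variance = FALSE) {
  db <- as.array(threshold)
  for (i in seq_along(discrimination))
    db[, i, ] <- -threshold[, i, ] * discrimination[i]
  parameter_set(db, discrimination, trait_scale, class_logit,
                trait_scale_is_variance)
}

#' Quadrature grid for integrating the latent trait
#'
#' Builds a grid of abscissae and weights approximating a standard-normal
#' integral. `gauss_hermite` converts physicists' Gauss-Hermite rules to the
#' probabilists' normalized form; `rectangular` places equally spaced nodes on
#' `[-range, range]` with renormalized normal-density weights (useful as an
#' independent cross-check of the quadrature error).
#'
#' @param n_points number of quadrature points (>= 2); 80 in the simulation
#'   study defaults
#' @param kind `"gauss_hermite"` (default) or `"rectangular"`
#' @param range half-width of the rectangular grid
#' @return object of class `mixirt_quadrature`: list with `nodes` (increasing)
#'   and `weights` (positive, summing to 1)
#' @export
build_quadrature <- function(n_points, kind = c("gauss_hermite", "rectangular"),
                             range = 6) {
  kind <- match.arg(kind)
  if (n_points < 2) stop("n_points must be at least 2")
  if (kind == "gauss_hermite") {
    gh <- pracma::gaussHermite(n_points)
    nodes <- gh$x * sqrt(2)
    weights <- gh$w / sqrt(pi)
  } else {
    nodes <- seq(-range, range, length.out = n_points)
    weights <- stats::dnorm(nodes)
    weights <- weights / sum(weights)
  }
  o <- order(nodes)
  structure(list(nodes = nodes[o], weights = weights[o] / sum(weights)),
            class = "mixirt_quadrature")
}

#' @export
print.mixirt_quadrature <- function(x, ...) {
  cat(sprintf("quadrature grid: %d nodes on [%.3f, %.3f]\n",
              length(x$nodes), min(x$nodes), max(x$nodes)))
  invisible(x)
}

#' Marginal log-likelihood of a mixture adjacent-category model
#'
#' Sums, over respondents, the log of the class-weighted response-pattern
#' probability with the latent trait integrated over the quadrature grid. The
#' trait of class `g` at node `z` enters as `trait_scale[g] * z`.
#'
#' @param params a [parameter_set()]
#' @param data a [response_matrix()] or integer matrix of responses coded
#'   `0 .. n_categories - 1`
#' @param grid a [build_quadrature()] grid
#' @return the marginal log-likelihood (finite scalar)
#' @export
marginal_loglik <- function(params, data, grid) {
  y <- response_codes(data, params)
  st <- estep(params, y, grid, want_posterior = FALSE)
  st$loglik
}

# validate and extract the integer response matrix (0-based category codes)
response_codes <- function(data, params) {
  y <- if (inherits(data, "mixirt_data")) data$responses else data
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  C <- dim(params$delta_beta)[3] + 1L
  if (ncol(y) != dim(params$delta_beta)[2])
    stop("number of response columns does not match the parameter set")
  if (any(y < 0L | y >= C))
    stop(sprintf("responses must lie in 0..%d", C - 1L))
  y
}

# E-step wrapper around the compiled kernel: returns the data log-likelihood,
# per-(class, node) posterior mass n_gq, weighted response counts
# W[category, item, class, node], the item-category probability table, and
# optionally posteriors.
#
# bayes_categorical / bayes_class add Dirichlet pseudo-counts to the
# complete-data sufficient statistics: per item, a total mass of
# bayes_categorical observations distributed over the class x category x
# node cells proportional to the observed marginal category distribution of
# that item (classes equally, nodes by quadrature weight), so the observed
# item margins are left unchanged by the prior; and bayes_class observations
# spread over the class sizes. Downstream M-steps, scores and information
# matrices are then exactly those of the penalized (posterior-mode)
# objective `objective = loglik + penalty`. Zero gives plain MML.
estep <- function(params, y, grid, want_posterior = FALSE,
                  want_joint = FALSE, bayes_categorical = 0,
                  bayes_class = 0) {
  G <- dim(params$delta_beta)[1]
  Q <- length(grid$nodes)
  C <- dim(params$delta_beta)[3] + 1L
  I <- dim(params$delta_beta)[2]
  pi_g <- class_proportions(params$class_logit)
  lp <- log(pmax(pi_g, 1e-300))
  res <- mix_estep_cpp(y, as.numeric(params$delta_beta),
                       params$item_discrimination, trait_sd(params), lp,
                       grid$nodes, log(grid$weights), C,
                       want_posterior, want_joint)
  dim(res$n_gq) <- c(G, Q)
  dim(res$W) <- c(C, I, G, Q)
  dim(res$prob) <- c(C, I, G, Q)
  res$n_item <- res$n_gq
  res$penalty <- 0
  res$bayes_class <- bayes_class
  if (bayes_categorical > 0) {
    # observed marginal category distribution per item (C x I)
    margin <- vapply(seq_len(I), function(i)
      tabulate(y[, i] + 1L, C) / nrow(y), numeric(C))
    aug <- (bayes_categorical / G) *
      outer(margin, matrix(grid$weights, G, Q, byrow = TRUE))
    res$W <- res$W + aug
    res$n_item <- res$n_gq +
      matrix(grid$weights * (bayes_categorical / G), G, Q, byrow = TRUE)
    res$penalty <- sum(aug * log(pmax(res$prob, 1e-300)))
  }
  if (bayes_class > 0)
    res$penalty <- res$penalty +
      (bayes_class / G) * sum(log(pmax(pi_g, 1e-300)))
  res$objective <- res$loglik + res$penalty
  res
}

# item-category log-probability table logp[category, item, class, node],
# computed in R (used by the M-step line search on candidate parameters)
item_logprob_table <- function(params, grid) {
  d <- dim(params$delta_beta)
  G <- d[1]; I <- d[2]; S <- d[3]; C <- S + 1L; Q <- length(grid$nodes)
  sd_g <- trait_sd(params)
  logp <- array(0, c(C, I, G, Q))
  for (g in seq_len(G)) {
    t_q <- sd_g[g] * grid$nodes
    for (i in seq_len(I)) {
      # cumulative step logits: rows categories 0..C-1, columns nodes
      eta <- outer(params$delta_beta[g, i, ],
                   params$item_discrimination[i] * t_q, `+`)
      cum <- rbind(0, apply(eta, 2, cumsum))
      m <- apply(cum, 2, max)
      lse <- m + log(colSums(exp(sweep(cum, 2, m))))
      logp[, i, g, ] <- sweep(cum, 2, lse)
    }
  }
  logp
}
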