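#' Synthetic response matrix
#'
#' @param responses N x I integer matrix of category codes `0 .. C - 1`
#' @param true_class integer vector of generating class memberships (1-based)
#' @param seed seed the data were generated from
#' @param condition optional [condition_config()] the data belong to
#' @return object of class `mixirt_data`
#' @export
response_matrix <- function(responses, true_class, seed = NA_integer_,
                            condition = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  stopifnot(nrow(responses) == length(true_class), all(responses >= 0L))
  structure(list(responses = responses,
                 true_class = as.integer(true_class),
                 seed = as.integer(seed), condition = condition),
            class = "mixirt_data")
}

#' @export
print.mixirt_data <- function(x, ...) {
  cat(sprintf("synthetic responses: %d respondents x %d items, seed %s\n",
              nrow(x$responses), ncol(x$responses), x$seed))
  invisible(x)
}

#' Simulate rating-scale responses from a mixture adjacent-category model
#'
#' For each respondent a latent class is drawn from the class proportions, a
#' standard-normal trait `z` is drawn and scaled by the class trait scale, and
#' each item response is drawn from the class- and trait-conditional category
#' probabilities. Fully reproducible given `(params, N, seed)`.
#'
#' @param params generating [parameter_set()]
#' @param N number of respondents
#' @param seed integer seed
#' @return a [response_matrix()] with the true class labels attached
#' @export
generate_dataset <- function(params, N, seed) {
  stopifnot(N >= 1)
  d <- dim(params$delta_beta)
  G <- d[1]; I <- d[2]; C <- d[3] + 1L
  set.seed(as.integer(seed))
  cls <- sample.int(G, N, replace = TRUE,
                    prob = class_proportions(params$class_logit))
  theta <- trait_sd(params)[cls] * stats::rnorm(N)
  y <- matrix(0L, N, I)
  S <- C - 1L
  cum_step <- 1 * outer(seq_len(S), seq_len(S), `<=`)   # row-wise cumsum
  cum_cat <- 1 * outer(seq_len(C), seq_len(C), `<=`)
  for (i in seq_len(I)) {
    # cumulative step logits per respondent: N x C
    eta <- params$delta_beta[cls, i, , drop = FALSE]
    dim(eta) <- c(N, S)
    eta <- eta + params$item_discrimination[i] * theta
    cum <- cbind(0, eta %*% cum_step)
    p <- exp(cum - apply(cum, 1, max))
    p <- p / rowSums(p)
    u <- stats::runif(N)
    y[, i] <- as.integer(rowSums((p %*% cum_cat) < u))
  }
  response_matrix(y, cls, seed = seed)
}

#' Model-implied marginal category distribution
#'
#' Class-weighted, quadrature-integrated category probabilities per item;
#' useful for checking simulated data against the generating model.
#'
#' @param params a [parameter_set()]
#' @param grid a [build_quadrature()] grid
#' @param by_class return the class-conditional distributions (item x category
#'   x class) instead of the mixture marginal (item x category)
#' @return array of category probabilities
#' @export
implied_category_distribution <- function(params, grid, by_class = FALSE) {
  d <- dim(params$delta_beta)
  G <- d[1]; I <- d[2]; C <- d[3] + 1L
  logp <- item_logprob_table(params, grid)
  out <- array(0, c(I, C, G))
  for (g in seq_len(G)) for (i in seq_len(I))
    out[i, , g] <- exp(logp[, i, g, , drop = FALSE][, 1, 1, ]) %*% grid$weights
  if (by_class) return(out)
  pi_g <- class_proportions(params$class_logit)
  marg <- matrix(0, I, C)
  for (g in seq_len(G)) marg <- marg + pi_g[g] * out[, , g]
  marg
}

#' Write or read a synthetic data set as CSV
#'
#' One row per respondent: `id`, `true_class`, then one `item<k>` column per
#' item of 0-based category codes. The generating seed is stored in a header
#' comment line.
#'
#' @param data a [response_matrix()]
#' @param path CSV path
#' @return `write_dataset`: the path, invisibly; `read_dataset`: a
#'   [response_matrix()]
#' @export
write_dataset <- function(data, path) {
  df <- data.frame(id = seq_len(nrow(data$responses)),
                   true_class = data$true_class,
                   data$responses)
  names(df)[-(1:2)] <- paste0("item", seq_len(ncol(data$responses)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", data$seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  header <- readLines(path, n = 1)
  seed <- if (grepl("^# seed:", header))
    as.integer(sub("^# seed: *", "", header)) else NA_integer_
  df <- utils::read.csv(path, comment.char = "#")
  m <- as.matrix(df[, grep("^item", names(df)), drop = FALSE])
  dimnames(m) <- NULL
  response_matrix(m, df$true_class, seed = seed)
}

#' Per-replication seed derivation
#'
#' Deterministic seed for one replication of one condition, mixing the base
#' seed, a hash of the condition id and the replication index, kept within the
#' 32-bit integer range.
#'
#' @param base_seed integer base seed
#' @param cond_id condition identifier string
#' @param replication replication index (1-based)
#' @return integer seed
#' @export
replication_seed <- function(base_seed, cond_id, replication) {
  h <- sum(utf8ToInt(cond_id) * (seq_len(nchar(cond_id)) %% 31 + 1))
  as.integer((as.double(base_seed) * 7919 + h * 104729 +
                replication * 15485863) %% 2147483587)
}
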