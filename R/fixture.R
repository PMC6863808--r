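#' Bundled generating parameters of the three-class population models
#'
#' The package ships the full generating parameter tables of the two
#' three-class population models used throughout the simulation study: a
#' restricted mixed GPCM (`"rmGPCM"`) and a mixed PCM (`"mPCM"`), each with 5
#' items and 11 response categories. The parameters were estimated from a
#' large panel-survey application of a 5-item job-satisfaction scale with an
#' 11-point rating scale and describe three latent classes with distinct
#' category-use patterns (extreme, ordinary, and partial-extreme response
#' styles). Extreme delta-beta estimates were substituted by |4| in the
#' population tables (flagged `substituted` in the fixture file).
#'
#' Each item additionally carries a marked subset of 5 of its 10 delta-beta
#' step parameters; those subsets define the 6-category study conditions (see
#' [derive_condition()]).
#'
#' @param model_type `"rmGPCM"` or `"mPCM"`
#' @return a [parameter_set()] with 3 classes, 5 items, 11 categories, plus
#'   attributes `subset_mask` (logical `[class, item, step]`, the marked
#'   steps), `substituted` and `low_confidence` (same shape)
#' @export
load_generating_fixture <- function(model_type = c("rmGPCM", "mPCM")) {
  model_type <- match.arg(model_type)
  path <- fixture_path()
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, FIXTURE_MD5))
    stop("generating-parameter fixture checksum mismatch: ", md5)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$model == model_type, ]
  db <- array(NA_real_, c(3, 5, 10))
  mask <- sub <- low <- array(FALSE, c(3, 5, 10))
  dd <- df[df$parameter_type == "delta_beta", ]
  idx <- cbind(dd$class, dd$item, dd$step)
  db[idx] <- dd$value
  mask[idx] <- dd$italic == 1
  sub[idx] <- dd$substituted == 1
  low[idx] <- dd$low_confidence == 1
  stopifnot(!anyNA(db))
  params <- parameter_set(
    delta_beta = db,
    item_discrimination =
      df$value[df$parameter_type == "discrimination"][order(
        df$item[df$parameter_type == "discrimination"])],
    trait_scale = df$value[df$parameter_type == "trait_scale"][order(
      df$class[df$parameter_type == "trait_scale"])],
    class_logit = df$value[df$parameter_type == "class_logit"][order(
      df$class[df$parameter_type == "class_logit"])])
  attr(params, "subset_mask") <- mask
  attr(params, "substituted") <- sub
  attr(params, "low_confidence") <- low
  attr(params, "model_type") <- model_type
  params
}

fixture_path <- function() {
  system.file("extdata", "generating_parameters.csv", package = "mixirtsim",
              mustWork = TRUE)
}

# md5 of the shipped fixture file; load_generating_fixture() refuses to read a
# silently edited transcription
FIXTURE_MD5 <- "bc6e2bc84696d39f7a939cf790fc22bb"

#' Simulation condition description
#'
#' @param model_type `"rmGPCM"` or `"mPCM"`
#' @param n_items 5 or 15 (15-item conditions replicate the 5 base items
#'   three times)
#' @param n_categories 11 or 6 (6-category conditions use the marked subset
#'   of 5 step parameters per item)
#' @param true_classes 2 or 3 (2-class conditions keep classes 1 and 2 with
#'   class logits `(0, 0.75)`)
#' @param sample_size number of respondents (>= 100)
#' @param n_replications Monte Carlo replications for this condition
#' @param base_seed base seed; per-replication seeds are derived from it, the
#'   condition id and the replication index
#' @param trait_scale_is_variance read the class trait-scale parameters as
#'   within-class trait variances instead of standard deviations
#' @return an object of class `mixirt_condition`
#' @export
condition_config <- function(model_type = c("rmGPCM", "mPCM"), n_items = 5,
                             n_categories = 11, true_classes = 3,
                             sample_size = 500, n_replications = 50,
                             base_seed = 1L,
                             trait_scale_is_variance = FALSE) {
  model_type <- match.arg(model_type)
  stopifnot(n_items %in% c(5L, 15L), n_categories %in% c(6L, 11L),
            true_classes %in% c(2L, 3L), sample_size >= 100)
  structure(
    list(model_type = model_type, n_items = as.integer(n_items),
         n_categories = as.integer(n_categories),
         true_classes = as.integer(true_classes),
         sample_size = as.integer(sample_size),
         n_replications = as.integer(n_replications),
         base_seed = as.integer(base_seed),
         trait_scale_is_variance = isTRUE(trait_scale_is_variance)),
    class = "mixirt_condition")
}

condition_id <- function(config) {
  sprintf("%s-%d_%di_%dc_N%d", config$model_type, config$true_classes,
          config$n_items, config$n_categories, config$sample_size)
}

#' @export
print.mixirt_condition <- function(x, ...) {
  cat(sprintf("condition %s: %d replications, base seed %d\n",
              condition_id(x), x$n_replications, x$base_seed))
  invisible(x)
}

#' Derive the generating parameters of a design condition
#'
#' Starting from a bundled three-class 5-item, 11-category fixture, builds the
#' generating [parameter_set()] of any design cell:
#' * 15-item conditions replicate the five base items three times in order
#'   (items 6 and 11 are copies of item 1, and so on);
#' * 6-category conditions keep, per item and class, only the 5 marked step
#'   parameters, in their original order;
#' * 2-class conditions keep classes 1 and 2 and set the class logits to
#'   `(0, 0.75)` (about a one-third / two-thirds split).
#'
#' The fixture itself is never modified.
#'
#' @param fixture a fixture from [load_generating_fixture()] (loaded from
#'   `config$model_type` when omitted)
#' @param config a [condition_config()]
#' @return the generating [parameter_set()] for the condition
#' @export
derive_condition <- function(fixture = NULL, config) {
  if (is.null(fixture)) fixture <- load_generating_fixture(config$model_type)
  db <- fixture$delta_beta
  disc <- fixture$item_discrimination
  scale <- fixture$trait_scale
  logit <- fixture$class_logit
  mask <- attr(fixture, "subset_mask")

  if (config$n_categories == 6L) {
    S <- 5L
    db6 <- array(NA_real_, c(dim(db)[1], dim(db)[2], S))
    for (g in seq_len(dim(db)[1])) for (i in seq_len(dim(db)[2]))
      db6[g, i, ] <- db[g, i, mask[g, i, ]]
    db <- db6
  }
  if (config$n_items == 15L) {
    db <- db[, rep(1:5, 3), , drop = FALSE]
    disc <- rep(disc, 3)
  }
  if (config$true_classes == 2L) {
    db <- db[1:2, , , drop = FALSE]
    scale <- scale[1:2]
    logit <- c(0, 0.75)
  }
  parameter_set(db, disc, scale, logit,
                trait_scale_is_variance =
                  isTRUE(config$trait_scale_is_variance) ||
                  isTRUE(fixture$trait_scale_is_variance))
}
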