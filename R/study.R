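# Condition orchestration: label alignment, replication loops, summary tables.

#' Align estimated class labels to the generating model
#'
#' Finds, by exhaustive search over the `G!` class permutations, the
#' relabeling of the fitted solution that minimizes the sum over classes of
#' squared differences between generating and estimated delta-beta vectors,
#' and applies it to every class-indexed block (delta-betas, trait scales,
#' class sizes, posteriors, standard errors).
#'
#' Class-size logits are re-referenced from the permuted proportions. When
#' the permutation moves the reference class their standard errors are no
#' longer transformable from per-parameter standard errors and are set to
#' `NA`; with warm starts at the generating values the identity permutation
#' is recovered in practice.
#'
#' @param fit a `mixirt_fit`
#' @param truth the generating [parameter_set()] with the same class count
#' @return list with `permutation` (index vector: aligned class `g` is
#'   fitted class `permutation[g]`) and `fit` (the relabeled fit)
#' @export
align_labels <- function(fit, truth) {
  G <- dim(truth$delta_beta)[1]
  stopifnot(dim(fit$estimates$delta_beta)[1] == G)
  perms <- permutations(G)
  cost <- vapply(seq_len(nrow(perms)), function(k) {
    p <- perms[k, ]
    sum((truth$delta_beta - fit$estimates$delta_beta[p, , , drop = FALSE])^2)
  }, numeric(1))
  p <- perms[which.min(cost), ]
  if (all(p == seq_len(G)))
    return(list(permutation = p, fit = fit))

  est <- fit$estimates
  est$delta_beta <- est$delta_beta[p, , , drop = FALSE]
  est$trait_scale <- est$trait_scale[p]
  pi_p <- class_proportions(fit$estimates$class_logit)[p]
  est$class_logit <- log(pi_p / pi_p[1])
  est$class_logit[1] <- 0
  fit$estimates <- est
  fit$posterior <- fit$posterior[, p, drop = FALSE]
  keeps_reference <- p[1] == 1L
  if (!is.null(fit$standard_errors)) {
    se <- fit$standard_errors
    se$delta_beta <- se$delta_beta[p, , , drop = FALSE]
    se$trait_scale <- se$trait_scale[p]
    se$class_logit <- if (keeps_reference) se$class_logit[p]
                      else rep(NA_real_, G)
    fit$standard_errors <- se
    b <- fit$boundary_se
    b$delta_beta <- b$delta_beta[p, , , drop = FALSE]
    b$trait_scale <- b$trait_scale[p]
    b$class_logit <- if (keeps_reference) b$class_logit[p]
                     else c(NA, rep(TRUE, G - 1L))
    fit$boundary_se <- b
  }
  list(permutation = p, fit = fit)
}

permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
  dimnames(out) <- NULL
  out
}

#' Label-separation certificate across replications
#'
#' Trains a multinomial logistic classifier on per-replication class-wise
#' delta-beta vectors (class identity as the label) and reports whether the
#' classification reproduces the labels without error -- the "no label
#' switching" certificate used after aligning a condition's replications.
#'
#' @param stack an aligned [replication_stack()]
#' @return list with `error_free` (logical), `n_misclassified` and the
#'   confusion table
#' @export
check_label_separation <- function(stack) {
  db <- stack$est$delta_beta
  R <- dim(db)[1]; G <- dim(db)[2]
  if (G < 2) stop("label separation needs at least two classes")
  if (R < 2) stop("label separation needs at least two replications")
  X <- do.call(rbind, lapply(seq_len(R), function(r)
    t(vapply(seq_len(G), function(g) as.numeric(db[r, g, , ]),
             numeric(prod(dim(db)[3:4]))))))
  lab <- factor(rep(seq_len(G), times = R))
  df <- data.frame(lab = lab, X)
  # a touch of weight decay keeps the classifier from interpolating a
  # mislabeled replication when features outnumber rows
  fit <- suppressWarnings(
    nnet::multinom(lab ~ ., data = df, trace = FALSE, maxit = 500,
                   MaxNWts = 100000, decay = 0.1))
  pred <- stats::predict(fit, df)
  list(error_free = all(pred == lab),
       n_misclassified = sum(pred != lab),
       confusion = table(truth = lab, predicted = pred))
}

#' Parameter recovery study for one design cell
#'
#' Runs the replication loop of one condition for the generating class count
#' only: generate data, fit by EM warm-started at the generating values,
#' refine by the Newton stage, compute standard errors, diagnose and drop
#' improper solutions, align labels, stack, trim, and summarize. This is the
#' accuracy arm of the study (convergence and accuracy tables); class
#' enumeration lives in [run_condition()].
#'
#' @param config a [condition_config()]
#' @param fit_cfg a [fit_config()]; the warm start at the generating values
#'   is set internally
#' @param newton_refine run the Newton refinement stage after EM; the
#'   recovery arm of the study follows the EM solution by default (the rapid
#'   Newton stage frequently fails to converge on sparse 11-category data
#'   and chiefly perturbs information-poor step parameters)
#' @param verbose print one line per replication
#' @return list of class `mixirt_recovery`: `truth`, trimmed `stack`,
#'   `summary` (accuracy table), `mean_assignment_probability`,
#'   per-replication bookkeeping (`loglik`, `em_iterations`, `em_converged`,
#'   `nr_converged`, `improper`, `seeds`), and `n_improper`
#' @export
run_recovery_study <- function(config, fit_cfg = fit_config(),
                               newton_refine = FALSE, verbose = FALSE) {
  truth <- derive_condition(config = config)
  cid <- condition_id(config)
  R <- config$n_replications
  fits <- vector("list", R)
  info <- data.frame(replication = seq_len(R), seed = NA_integer_,
                     loglik = NA_real_, em_iterations = NA_integer_,
                     em_converged = NA, nr_converged = NA, improper = NA,
                     mean_assignment_probability = NA_real_)
  for (r in seq_len(R)) {
    seed <- replication_seed(config$base_seed, cid, r)
    dat <- generate_dataset(truth, config$sample_size, seed)
    fit <- fit_em(dat, truth, fit_cfg)
    if (newton_refine) fit <- refine_newton(fit, dat, fit_cfg)
    fit <- compute_standard_errors(fit, dat, fit_cfg)
    fit <- align_labels(fit, truth)$fit
    fits[[r]] <- fit
    info$seed[r] <- seed
    info$loglik[r] <- fit$loglik
    info$em_iterations[r] <- fit$em_iterations
    info$em_converged[r] <- fit$em_converged
    info$nr_converged[r] <- fit$nr_converged
    info$improper[r] <- fit$improper
    info$mean_assignment_probability[r] <- fit$mean_assignment_probability
    if (verbose)
      message(sprintf("%s replication %d/%d: loglik %.2f%s", cid, r, R,
                      fit$loglik, if (isTRUE(fit$improper)) " [improper]"
                      else ""))
  }
  keep <- !vapply(fits, function(f) isTRUE(f$improper), logical(1))
  stack <- trim_estimates(replication_stack(fits[keep]))
  structure(
    list(condition = config, truth = truth, stack = stack,
         summary = summarize_accuracy(stack, truth),
         mean_assignment_probability =
           mean(info$mean_assignment_probability[keep]),
         replications = info, n_improper = sum(!keep), fits = fits[keep]),
    class = "mixirt_recovery")
}

#' @export
print.mixirt_recovery <- function(x, ...) {
  cat(sprintf(paste0("recovery study %s: %d replications (%d improper ",
                     "dropped), mean classification probability %.3f\n"),
              condition_id(x$condition), x$condition$n_replications,
              x$n_improper, x$mean_assignment_probability))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Run one simulation condition with class enumeration
#'
#' Per replication: generate data from the condition's generating model, fit
#' every candidate class count (warm start at the generating values for the
#' true class count, random starts otherwise), compute information criteria,
#' diagnose the true-class solution, align labels, and record the selected
#' class count per criterion. Improper true-class replications are dropped
#' from accuracy and selection, following the study's elimination rule;
#' improper non-true candidates are excluded from that replication's argmin.
#'
#' @param config a [condition_config()]
#' @param fit_cfg a [fit_config()]; for desk-scale runs reduce `n_starts`
#' @param candidates candidate class counts (defaults to `2:4` for a
#'   three-class and `1:3` for a two-class generating model)
#' @param compute_se compute standard errors (and improper diagnoses) for
#'   the true-class fits
#' @param verbose print progress lines
#' @return list of class `mixirt_condition_result`: `recovery` (aligned
#'   stack + accuracy summary), `selection` (selection-rate table),
#'   `convergence` (per-replication fit bookkeeping), `ic_records`
#' @export
run_condition <- function(config, fit_cfg = fit_config(), candidates = NULL,
                          compute_se = TRUE, verbose = FALSE) {
  truth <- derive_condition(config = config)
  if (is.null(candidates))
    candidates <- if (config$true_classes == 3L) 2:4 else 1:3
  stopifnot(config$true_classes %in% candidates)
  cid <- condition_id(config)
  R <- config$n_replications
  crits <- c("AIC", "BIC", "CAIC", "AIC3", "SABIC")
  sel_records <- list()
  conv_records <- list()
  ic_records <- list()
  true_fits <- vector("list", R)
  improper <- logical(R)

  for (r in seq_len(R)) {
    seed <- replication_seed(config$base_seed, cid, r)
    dat <- generate_dataset(truth, config$sample_size, seed)
    ics <- matrix(NA_real_, length(candidates), length(crits),
                  dimnames = list(NULL, crits))
    usable <- rep(TRUE, length(candidates))
    for (k in seq_along(candidates)) {
      gk <- candidates[k]
      spec_k <- model_spec(config$n_items, config$n_categories, gk,
                           equal_discrimination =
                             config$model_type == "mPCM")
      cfg_k <- fit_cfg
      cfg_k$warm_start <- if (gk == config$true_classes) truth else NULL
      fit <- tryCatch(
        multi_start_fit(dat, spec_k, cfg_k, seed = seed + k),
        error = function(e) NULL)
      if (is.null(fit)) { usable[k] <- FALSE; next }
      ics[k, ] <- information_criteria(fit$loglik, fit$n_free_parameters,
                                       config$sample_size)
      if (gk == config$true_classes) {
        if (compute_se) {
          fit <- compute_standard_errors(fit, dat, fit_cfg)
          improper[r] <- isTRUE(fit$improper)
          usable[k] <- !improper[r]
        }
        fit <- align_labels(fit, truth)$fit
        true_fits[[r]] <- fit
        conv_records[[r]] <- data.frame(
          condition = cid, replication = r, seed = seed,
          loglik = fit$loglik, em_iterations = fit$em_iterations,
          em_converged = fit$em_converged, nr_converged = fit$nr_converged,
          improper = improper[r],
          mean_assignment_probability = fit$mean_assignment_probability)
      }
      if (verbose)
        message(sprintf("%s rep %d G=%d: ll %.2f", cid, r, gk,
                        if (is.null(fit)) NA else fit$loglik))
    }
    if (improper[r]) next  # eliminated wholesale
    for (cr in crits) {
      sel_records[[length(sel_records) + 1L]] <- data.frame(
        condition = cid, replication = r, criterion = cr,
        selected = select_best(ics[, cr], candidates, usable))
    }
    ic_records[[length(ic_records) + 1L]] <-
      data.frame(condition = cid, replication = r,
                 class_count = candidates, usable = usable, ics)
  }

  keep <- !improper & !vapply(true_fits, is.null, logical(1))
  stack <- trim_estimates(replication_stack(true_fits[keep]))
  sel <- do.call(rbind, sel_records)
  structure(
    list(condition = config,
         recovery = list(
           truth = truth, stack = stack,
           summary = summarize_accuracy(stack, truth),
           mean_assignment_probability = mean(vapply(
             true_fits[keep], function(f) f$mean_assignment_probability,
             numeric(1)))),
         selection = tabulate_selection(sel, candidates,
                                        config$true_classes),
         selection_records = sel,
         convergence = do.call(rbind, conv_records),
         ic_records = do.call(rbind, ic_records),
         n_improper = sum(improper)),
    class = "mixirt_condition_result")
}

#' Write the result tables of a condition run
#'
#' Writes tidy CSVs mirroring the study's reporting layout: the convergence
#' table, the accuracy summary, the selection-rate table (percentages
#' rounded to integers at export only) and a combined long-format selection
#' record file.
#'
#' @param result a `mixirt_condition_result` from [run_condition()]
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
export_tables <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cid <- condition_id(result$condition)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(dir, sprintf("%s_%s.csv", cid, name))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  conv <- result$convergence
  conv$improper[is.na(conv$improper)] <- FALSE
  w(conv, "convergence")
  acc <- result$recovery$summary
  acc$condition <- cid
  acc$N <- result$condition$sample_size
  acc$model <- result$condition$model_type
  w(acc, "accuracy")
  sel <- result$selection
  pct_cols <- grep("^pct_g", names(sel))
  sel[pct_cols] <- lapply(sel[pct_cols], function(x) as.integer(round(x)))
  sel$condition <- cid
  sel$N <- result$condition$sample_size
  w(sel, "selection")
  w(result$selection_records, "selection_long")
  invisible(paths)
}

# ---- parameter serialization -------------------------------------------

#' Flat-table serialization of a parameter set
#'
#' `params_to_df()` flattens a [parameter_set()] into a long data.frame with
#' columns `(model, class, item, step, parameter_type, value)`;
#' `df_to_params()` inverts it exactly. `write_params()` / `read_params()`
#' do the same through a CSV file, writing 17 significant digits so the
#' round trip is bit-exact.
#'
#' @param params a [parameter_set()]
#' @param model optional model label stored in the `model` column
#' @return `params_to_df`: a data.frame; `df_to_params`: a
#'   [parameter_set()]
#' @export
params_to_df <- function(params, model = "") {
  d <- dim(params$delta_beta)
  G <- d[1]; I <- d[2]; S <- d[3]
  gis <- expand.grid(class = seq_len(G), item = seq_len(I), step = seq_len(S))
  rbind(
    data.frame(model = model, class = gis$class, item = gis$item,
               step = gis$step, parameter_type = "delta_beta",
               value = as.numeric(params$delta_beta)),
    data.frame(model = model, class = NA_integer_, item = seq_len(I),
               step = NA_integer_, parameter_type = "discrimination",
               value = params$item_discrimination),
    data.frame(model = model, class = seq_len(G), item = NA_integer_,
               step = NA_integer_, parameter_type = "trait_scale",
               value = params$trait_scale),
    data.frame(model = model, class = seq_len(G), item = NA_integer_,
               step = NA_integer_, parameter_type = "class_logit",
               value = params$class_logit))
}

#' @rdname params_to_df
#' @param df a data.frame in the `params_to_df()` layout
#' @param trait_scale_is_variance passed to [parameter_set()]
#' @export
df_to_params <- function(df, trait_scale_is_variance = FALSE) {
  dd <- df[df$parameter_type == "delta_beta", ]
  G <- max(dd$class); I <- max(dd$item); S <- max(dd$step)
  db <- array(NA_real_, c(G, I, S))
  db[cbind(dd$class, dd$item, dd$step)] <- dd$value
  disc <- df[df$parameter_type == "discrimination", ]
  ts <- df[df$parameter_type == "trait_scale", ]
  lg <- df[df$parameter_type == "class_logit", ]
  parameter_set(db, disc$value[order(disc$item)], ts$value[order(ts$class)],
                lg$value[order(lg$class)], trait_scale_is_variance)
}

#' @rdname params_to_df
#' @param path CSV path
#' @export
write_params <- function(params, path, model = "") {
  df <- params_to_df(params, model)
  df$value <- sprintf("%.17g", df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname params_to_df
#' @export
read_params <- function(path, trait_scale_is_variance = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df_to_params(df, trait_scale_is_variance)
}

#' Serialize a fit to JSON and CSV
#'
#' Writes scalar results and flags to `<stem>.json` and the parameter table
#' (estimate, standard error, boundary flag per coordinate) to
#' `<stem>_parameters.csv`.
#'
#' @param fit a `mixirt_fit`
#' @param stem output path stem
#' @return invisibly, the two paths
#' @export
write_fit <- function(fit, stem) {
  js <- list(loglik = fit$loglik,
             n_free_parameters = fit$n_free_parameters,
             em_iterations = fit$em_iterations,
             em_converged = fit$em_converged,
             nr_iterations = fit$nr_iterations,
             nr_converged = fit$nr_converged,
             improper = fit$improper,
             mean_assignment_probability = fit$mean_assignment_probability)
  jsonlite::write_json(js, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  df <- params_to_df(fit$estimates)
  if (!is.null(fit$standard_errors)) {
    df$se <- NA_real_
    # params_to_df flattens delta-betas in column-major array order
    df$se[df$parameter_type == "delta_beta"] <-
      as.numeric(fit$standard_errors$delta_beta)
    df$se[df$parameter_type == "discrimination"] <-
      fit$standard_errors$item_discrimination
    df$se[df$parameter_type == "trait_scale"] <-
      fit$standard_errors$trait_scale
    df$se[df$parameter_type == "class_logit"] <-
      fit$standard_errors$class_logit
    df$boundary <- FALSE
    df$boundary[df$parameter_type == "delta_beta"] <-
      as.logical(fit$boundary_se$delta_beta)
    df$boundary[df$parameter_type == "discrimination"] <-
      fit$boundary_se$item_discrimination %in% TRUE
    df$boundary[df$parameter_type == "trait_scale"] <-
      as.logical(fit$boundary_se$trait_scale)
    df$boundary[df$parameter_type == "class_logit"] <-
      fit$boundary_se$class_logit %in% TRUE
  }
  utils::write.csv(df, paste0(stem, "_parameters.csv"), row.names = FALSE)
  invisible(c(paste0(stem, ".json"), paste0(stem, "_parameters.csv")))
}
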