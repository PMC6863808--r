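# Replication-level accuracy battery: trimming, root median squared error,
# standard error bias, confidence interval width, coverage and Spearman
# concordance, median-aggregated the way the simulation study reports them.

Z975 <- 1.959964  # fixed 97.5% normal quantile for bit-stable CI widths

#' Build a replication stack
#'
#' Collects label-aligned estimates and standard errors from a list of fits
#' into per-parameter-type arrays with a replication dimension, ready for
#' trimming and accuracy summaries.
#'
#' @param fits list of `mixirt_fit` objects (aligned to the generating model,
#'   with standard errors computed); improper fits should be dropped before
#'   stacking
#' @return object of class `mixirt_stack`: arrays `est`/`se` for
#'   `delta_beta` `[rep, class, item, step]`, `discrimination` `[rep, item]`,
#'   `trait_scale` `[rep, class]`, `class_logit` `[rep, class]`, and logical
#'   exclusion arrays `excl` of the same shapes (boundary SEs pre-marked)
#' @export
replication_stack <- function(fits) {
  stopifnot(length(fits) >= 1)
  d <- dim(fits[[1]]$estimates$delta_beta)
  R <- length(fits)
  db_est <- array(NA_real_, c(R, d))
  db_se <- array(NA_real_, c(R, d))
  db_bnd <- array(FALSE, c(R, d))
  disc_est <- disc_se <- matrix(NA_real_, R, d[2])
  disc_bnd <- matrix(FALSE, R, d[2])
  sc_est <- sc_se <- lg_est <- lg_se <- matrix(NA_real_, R, d[1])
  sc_bnd <- lg_bnd <- matrix(FALSE, R, d[1])
  for (r in seq_len(R)) {
    f <- fits[[r]]
    db_est[r, , , ] <- f$estimates$delta_beta
    disc_est[r, ] <- f$estimates$item_discrimination
    sc_est[r, ] <- f$estimates$trait_scale
    lg_est[r, ] <- f$estimates$class_logit
    if (!is.null(f$standard_errors)) {
      db_se[r, , , ] <- f$standard_errors$delta_beta
      disc_se[r, ] <- f$standard_errors$item_discrimination
      sc_se[r, ] <- f$standard_errors$trait_scale
      lg_se[r, ] <- f$standard_errors$class_logit
      db_bnd[r, , , ] <- f$boundary_se$delta_beta
      disc_bnd[r, ] <- f$boundary_se$item_discrimination %in% TRUE
      sc_bnd[r, ] <- f$boundary_se$trait_scale
      lg_bnd[r, ] <- f$boundary_se$class_logit %in% TRUE
    }
  }
  structure(list(
    est = list(delta_beta = db_est, discrimination = disc_est,
               trait_scale = sc_est, class_logit = lg_est),
    se = list(delta_beta = db_se, discrimination = disc_se,
              trait_scale = sc_se, class_logit = lg_se),
    excl = list(delta_beta = db_bnd, discrimination = disc_bnd,
                trait_scale = sc_bnd, class_logit = lg_bnd),
    n_replications = R), class = "mixirt_stack")
}

#' @export
print.mixirt_stack <- function(x, ...) {
  cat(sprintf("replication stack: %d replications\n", x$n_replications))
  invisible(x)
}

#' Trim extreme and boundary estimates
#'
#' Marks for exclusion, pairwise (a parameter together with its standard
#' error), every entry with an extreme parameter estimate (absolute value
#' above `est_cutoff`), an extreme standard error (above `se_cutoff`), or a
#' boundary-flagged standard error. Improper replications are expected to be
#' dropped wholesale before stacking.
#'
#' @param stack a [replication_stack()]
#' @param est_cutoff extreme-estimate cutoff (default |10|)
#' @param se_cutoff extreme-standard-error cutoff (default 50)
#' @return the stack with updated exclusion flags
#' @export
trim_estimates <- function(stack, est_cutoff = 10, se_cutoff = 50) {
  for (k in names(stack$est)) {
    e <- stack$est[[k]]
    s <- stack$se[[k]]
    bad <- (!is.na(e) & abs(e) > est_cutoff) |
      (!is.na(s) & s > se_cutoff) | stack$excl[[k]]
    stack$excl[[k]] <- bad
  }
  stack
}

#' Root median squared error
#'
#' Square root of the median of squared deviations of per-replication
#' estimates from the generating value; a robust absolute accuracy measure.
#'
#' @param estimates per-replication estimates (excluded entries already
#'   removed or `NA`)
#' @param truth generating parameter value
#' @return RMdSE, or `NA` if no estimate remains
#' @export
rmdse <- function(estimates, truth) {
  x <- estimates[!is.na(estimates)]
  if (!length(x)) return(NA_real_)
  sqrt(stats::median((x - truth)^2))
}

#' Standard error bias
#'
#' Median of absolute deviations of per-replication standard error estimates
#' from the empirical standard deviation of the parameter estimates across
#' replications.
#'
#' @param se_estimates per-replication standard error estimates
#' @param empirical_sd empirical SD of the parameter estimates across all
#'   non-excluded replications (n - 1 denominator)
#' @return the bias index, `NA` when nothing remains or the SD is missing
#' @export
bias_se <- function(se_estimates, empirical_sd) {
  s <- se_estimates[!is.na(se_estimates)]
  if (!length(s) || is.na(empirical_sd)) return(NA_real_)
  stats::median(abs(s - empirical_sd))
}

#' Median width of the 95% confidence interval
#'
#' @param se_estimates per-replication standard error estimates
#' @return `median(2 * z(.975) * se)` with `z(.975) = 1.959964`
#' @export
md_width_ci <- function(se_estimates) {
  s <- se_estimates[!is.na(se_estimates)]
  if (!length(s)) return(NA_real_)
  stats::median(2 * Z975 * s)
}

#' 95% confidence interval coverage
#'
#' Share of replications whose Wald 95% interval
#' `estimate +/- 1.959964 * se` contains the generating value. Entries where
#' either the estimate or the standard error is missing are dropped pairwise.
#'
#' @param estimates per-replication estimates
#' @param se_estimates matching standard error estimates
#' @param truth generating value
#' @return coverage proportion in `[0, 1]`, `NA` if nothing remains
#' @export
coverage <- function(estimates, se_estimates, truth) {
  ok <- !is.na(estimates) & !is.na(se_estimates)
  if (!any(ok)) return(NA_real_)
  e <- estimates[ok]; s <- se_estimates[ok]
  mean(truth >= e - Z975 * s & truth <= e + Z975 * s)
}

#' Spearman concordance of delta-beta profiles
#'
#' Rank correlation between the generating and estimated delta-beta step
#' parameters of each item within each class, computed per replication, then
#' averaged over items and finally over replications. Ties are handled by
#' average ranks. High values mean the estimated step pattern reproduces the
#' class's generating category-use pattern.
#'
#' Excluded (trimmed) coordinates are dropped pairwise from each item's rank
#' vectors, mirroring the elimination step that precedes all accuracy
#' indices.
#'
#' @param stack a [replication_stack()]
#' @param truth the generating [parameter_set()]
#' @param respect_exclusions drop trimmed coordinates before correlating
#' @return named numeric vector, one mean correlation per class
#' @export
spearman_concordance <- function(stack, truth, respect_exclusions = TRUE) {
  db <- stack$est$delta_beta
  if (respect_exclusions && length(stack$excl))
    db[stack$excl$delta_beta] <- NA_real_
  R <- dim(db)[1]; G <- dim(db)[2]; I <- dim(db)[3]
  out <- numeric(G)
  for (g in seq_len(G)) {
    per_rep <- vapply(seq_len(R), function(r) {
      rs <- vapply(seq_len(I), function(i) {
        ok <- !is.na(db[r, g, i, ])
        x <- db[r, g, i, ok]
        tr <- truth$delta_beta[g, i, ok]
        # degenerate rank vectors (all ties) carry no order information
        if (sum(ok) < 2 || length(unique(x)) < 2 || length(unique(tr)) < 2)
          return(NA_real_)
        stats::cor(tr, x, method = "spearman")
      }, numeric(1))
      mean(rs, na.rm = TRUE)
    }, numeric(1))
    out[g] <- mean(per_rep, na.rm = TRUE)
  }
  names(out) <- paste0("class", seq_len(G))
  out
}

#' Accuracy summary across replications
#'
#' Applies the exclusion flags, computes per-coordinate RMdSE, standard error
#' bias, CI width and coverage, and aggregates them per parameter type and
#' class: median over coordinates for the median-based indices, mean for
#' coverage. Spearman concordance is reported for delta-betas. Class-size
#' accuracy is computed on the multinomial-logit scale by default (reference
#' class excluded); `class_size_on_proportion_scale` switches to softmax
#' proportions (without standard errors).
#'
#' @param stack a trimmed, label-aligned [replication_stack()]
#' @param truth the generating [parameter_set()]
#' @param class_size_on_proportion_scale report class-size accuracy on the
#'   proportion rather than the logit scale
#' @return data.frame with one row per (parameter type, class):
#'   `rmdse`, `bias_se`, `md_width_ci`, `coverage`, `spearman`, `n_used`,
#'   `n_excluded`
#' @export
summarize_accuracy <- function(stack, truth,
                               class_size_on_proportion_scale = FALSE) {
  G <- dim(truth$delta_beta)[1]
  I <- dim(truth$delta_beta)[2]
  S <- dim(truth$delta_beta)[3]
  rows <- list()

  coord_indices <- function(est, se, tru) {
    sd_emp <- if (sum(!is.na(est)) >= 2) stats::sd(est, na.rm = TRUE)
              else NA_real_
    c(rmdse = rmdse(est, tru),
      bias_se = bias_se(se, sd_emp),
      md_width_ci = md_width_ci(se),
      coverage = coverage(est, se, tru))
  }
  masked <- function(kind) {
    e <- stack$est[[kind]]
    s <- stack$se[[kind]]
    x <- stack$excl[[kind]]
    e[x] <- NA; s[x] <- NA
    list(e = e, s = s)
  }

  db <- masked("delta_beta")
  sp <- spearman_concordance(stack, truth)
  for (g in seq_len(G)) {
    idx <- vapply(seq_len(I * S), function(k) {
      i <- (k - 1L) %% I + 1L
      s <- (k - 1L) %/% I + 1L
      coord_indices(db$e[, g, i, s], db$s[, g, i, s],
                    truth$delta_beta[g, i, s])
    }, numeric(4))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter_type = "delta_beta", class = g,
      rmdse = stats::median(idx["rmdse", ], na.rm = TRUE),
      bias_se = stats::median(idx["bias_se", ], na.rm = TRUE),
      md_width_ci = stats::median(idx["md_width_ci", ], na.rm = TRUE),
      coverage = mean(idx["coverage", ], na.rm = TRUE),
      spearman = sp[g],
      n_used = sum(!is.na(db$e[, g, , ])),
      n_excluded = sum(stack$excl$delta_beta[, g, , ]))
  }

  if (!params_spec(truth)$equal_discrimination) {
    dd <- masked("discrimination")
    free_items <- 2:I
    idx <- vapply(free_items, function(i)
      coord_indices(dd$e[, i], dd$s[, i], truth$item_discrimination[i]),
      numeric(4))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter_type = "discrimination", class = NA_integer_,
      rmdse = stats::median(idx["rmdse", ], na.rm = TRUE),
      bias_se = stats::median(idx["bias_se", ], na.rm = TRUE),
      md_width_ci = stats::median(idx["md_width_ci", ], na.rm = TRUE),
      coverage = mean(idx["coverage", ], na.rm = TRUE),
      spearman = NA_real_,
      n_used = sum(!is.na(dd$e[, free_items])),
      n_excluded = sum(stack$excl$discrimination[, free_items]))
  }

  ts <- masked("trait_scale")
  for (g in seq_len(G)) {
    idx <- coord_indices(ts$e[, g], ts$s[, g], truth$trait_scale[g])
    rows[[length(rows) + 1L]] <- data.frame(
      parameter_type = "trait_scale", class = g,
      rmdse = idx["rmdse"], bias_se = idx["bias_se"],
      md_width_ci = idx["md_width_ci"], coverage = idx["coverage"],
      spearman = NA_real_, n_used = sum(!is.na(ts$e[, g])),
      n_excluded = sum(stack$excl$trait_scale[, g]))
  }

  lg <- masked("class_logit")
  if (class_size_on_proportion_scale) {
    prop_est <- t(apply(stack$est$class_logit, 1, function(v)
      if (anyNA(v)) rep(NA_real_, G) else class_proportions(v)))
    prop_true <- class_proportions(truth$class_logit)
    for (g in seq_len(G)) {
      rows[[length(rows) + 1L]] <- data.frame(
        parameter_type = "class_size", class = g,
        rmdse = rmdse(prop_est[, g], prop_true[g]), bias_se = NA_real_,
        md_width_ci = NA_real_, coverage = NA_real_, spearman = NA_real_,
        n_used = sum(!is.na(prop_est[, g])), n_excluded = 0L)
    }
  } else if (G > 1) {
    for (g in 2:G) {
      idx <- coord_indices(lg$e[, g], lg$s[, g], truth$class_logit[g])
      rows[[length(rows) + 1L]] <- data.frame(
        parameter_type = "class_logit", class = g,
        rmdse = idx["rmdse"], bias_se = idx["bias_se"],
        md_width_ci = idx["md_width_ci"], coverage = idx["coverage"],
        spearman = NA_real_, n_used = sum(!is.na(lg$e[, g])),
        n_excluded = sum(stack$excl$class_logit[, g]))
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
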