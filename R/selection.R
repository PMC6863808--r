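#' Number of free parameters of a mixture adjacent-category model
#'
#' Under the identification constraints (first item discrimination fixed at
#' 1, first class logit fixed at 0):
#' `G * I * (C - 1)` delta-betas, `I - 1` discriminations (rmGPCM only),
#' `G - 1` class logits and `G` trait scales.
#'
#' @param spec a [model_spec()]
#' @return integer parameter count
#' @examples
#' count_free_parameters(model_spec(5, 11, 3))        # 159 for the rmGPCM-3
#' count_free_parameters(model_spec(5, 11, 3, TRUE))  # 155 for the mPCM-3
#' @export
count_free_parameters <- function(spec) {
  G <- spec$n_classes; I <- spec$n_items; C <- spec$n_categories
  as.integer(G * I * (C - 1) +
               (!spec$equal_discrimination) * (I - 1) +
               (G - 1) + G)
}

#' Information criteria for class enumeration
#'
#' AIC, BIC, CAIC, AIC3 and SABIC from the marginal log-likelihood, the free
#' parameter count and the sample size (natural logarithms):
#' \deqn{AIC = -2LL + 2 N_{par}}
#' \deqn{BIC = -2LL + \ln(N) N_{par}}
#' \deqn{CAIC = -2LL + (\ln(N) + 1) N_{par}}
#' \deqn{AIC3 = -2LL + 3 N_{par}}
#' \deqn{SABIC = -2LL + \ln((N + 2)/24) N_{par}}
#'
#' The SABIC uses Sclove's sample-size-adjusted penalty `ln((N + 2)/24)`;
#' `sabic_literal = TRUE` switches to a `ln(N + 224)` penalty for audit
#' purposes (which makes SABIC numerically close to BIC and is not used
#' anywhere by default).
#'
#' @param loglik marginal log-likelihood
#' @param n_par number of free parameters
#' @param N sample size (>= 1)
#' @param sabic_literal use the `ln(N + 224)` penalty variant
#' @return named numeric vector `AIC, BIC, CAIC, AIC3, SABIC`
#' @export
information_criteria <- function(loglik, n_par, N, sabic_literal = FALSE) {
  stopifnot(N >= 1)
  m2ll <- -2 * loglik
  sab_pen <- if (sabic_literal) log(N + 224) else log((N + 2) / 24)
  c(AIC = m2ll + 2 * n_par,
    BIC = m2ll + log(N) * n_par,
    CAIC = m2ll + (log(N) + 1) * n_par,
    AIC3 = m2ll + 3 * n_par,
    SABIC = m2ll + sab_pen * n_par)
}

#' Best class count under one criterion
#'
#' Argmin of the criterion over candidate class counts; ties are broken
#' toward fewer classes (parsimony). Candidates flagged unusable (e.g.
#' improper solutions) are excluded; if none remain the replication is
#' marked unusable (`NA`).
#'
#' @param criterion_values numeric criterion value per candidate
#' @param class_counts integer candidate class counts, same length
#' @param usable logical; which candidates may be selected
#' @return the selected class count, or `NA` if no candidate is usable
#' @export
select_best <- function(criterion_values, class_counts,
                        usable = rep(TRUE, length(criterion_values))) {
  stopifnot(length(criterion_values) == length(class_counts))
  keep <- usable & is.finite(criterion_values)
  if (!any(keep)) return(NA_integer_)
  vals <- criterion_values[keep]
  cls <- class_counts[keep]
  o <- order(vals, cls)   # ties go to the smaller class count
  as.integer(cls[o[1]])
}

#' Selection-rate table across replications
#'
#' Percentage of replications in which each candidate class count was
#' selected, per criterion, with a success flag where the true class count
#' reaches at least 95% of replications.
#'
#' @param records data.frame with columns `criterion` and `selected`
#'   (class count chosen in one replication; `NA` rows are dropped and
#'   reported in `n_unusable`)
#' @param class_counts candidate class counts (columns of the table)
#' @param true_classes the generating class count
#' @return data.frame, one row per criterion: percentage columns
#'   `pct_g<k>`, `success`, `n_used`, `n_unusable`
#' @export
tabulate_selection <- function(records, class_counts, true_classes) {
  stopifnot(all(c("criterion", "selected") %in% names(records)))
  out <- lapply(split(records, records$criterion), function(df) {
    ok <- !is.na(df$selected)
    n <- sum(ok)
    pct <- vapply(class_counts, function(k)
      if (n) 100 * sum(df$selected[ok] == k) / n else 0, numeric(1))
    row <- data.frame(criterion = df$criterion[1], t(pct))
    names(row)[-1] <- paste0("pct_g", class_counts)
    row$success <- n > 0 && pct[class_counts == true_classes] >= 95
    row$n_used <- n
    row$n_unusable <- sum(!ok)
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
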