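test_that("root median squared error follows its definition", {
  expect_equal(rmdse(c(2, 2, 2), 2), 0)
  expect_equal(rmdse(c(1, 2, 4), 2), 1)        # sqrt(median(1, 0, 4))
  expect_equal(rmdse(3.5, 3), 0.5)
  expect_true(is.na(rmdse(rep(NA_real_, 3), 1)))
})

test_that("standard error bias is the median absolute deviation from the empirical SD", {
  expect_equal(bias_se(c(0.2, 0.2), 0.2), 0)
  expect_equal(bias_se(c(0.1, 0.2, 0.3), 0.2), 0.1)
  expect_equal(bias_se(0.7, 0.5), 0.2)
  expect_true(is.na(bias_se(0.7, NA_real_)))
})

test_that("CI width uses the fixed 97.5% normal quantile", {
  expect_equal(md_width_ci(c(1, 1, 1)), 3.919928, tolerance = 1e-6)
  expect_equal(round(md_width_ci(c(0.5, 1.0, 1.5)), 4), 3.9199)
  expect_equal(md_width_ci(0), 0)
})

test_that("coverage counts replications whose CI contains the truth", {
  expect_equal(coverage(rep(1, 20), rep(0.3, 20), 1), 1)
  expect_equal(coverage(2 + 3 * 0.4, 0.4, 2), 0)
  expect_equal(coverage(c(0, 10), c(1, 1), 0.5), 0.5)

  # a correctly specified simulated estimator covers at the nominal rate
  set.seed(991)
  n_rep <- 10000
  est <- rnorm(n_rep, mean = 3, sd = 0.7)
  expect_equal(coverage(est, rep(0.7, n_rep), 3), 0.95, tolerance = 0.01)
})

test_that("robust indices are insensitive to a single wild replication", {
  base <- rnorm(25, 1, 0.1)
  r0 <- rmdse(base, 1)
  r1 <- rmdse(c(base, 1e6), 1)
  expect_lt(abs(r1 - r0), 0.2)
  b0 <- bias_se(abs(base), 0.1)
  b1 <- bias_se(c(abs(base), 1e6), 0.1)
  expect_lt(abs(b1 - b0), 0.2)
})

# build a small stack by hand: R replications of a 1-class, 1-item model
# with two step parameters
hand_stack <- function(est, se, truth_db = c(0.2, 0.6)) {
  R <- nrow(est$db1)
  db_e <- array(NA_real_, c(R, 1, 1, 2))
  db_s <- array(NA_real_, c(R, 1, 1, 2))
  db_e[, 1, 1, 1] <- est$db1[, 1]; db_e[, 1, 1, 2] <- est$db1[, 2]
  db_s[, 1, 1, 1] <- se$db1[, 1];  db_s[, 1, 1, 2] <- se$db1[, 2]
  structure(list(
    est = list(delta_beta = db_e,
               discrimination = matrix(1, R, 1),
               trait_scale = matrix(est$scale, R, 1),
               class_logit = matrix(0, R, 1)),
    se = list(delta_beta = db_s,
              discrimination = matrix(NA_real_, R, 1),
              trait_scale = matrix(se$scale, R, 1),
              class_logit = matrix(NA_real_, R, 1)),
    excl = list(delta_beta = array(FALSE, c(R, 1, 1, 2)),
                discrimination = matrix(FALSE, R, 1),
                trait_scale = matrix(FALSE, R, 1),
                class_logit = matrix(FALSE, R, 1)),
    n_replications = R), class = "mixirt_stack")
}

hand_truth <- function(db = c(0.2, 0.6))
  parameter_set(array(db, c(1, 1, 2)), 1, 0.5, 0)

test_that("trimming removes extreme and boundary entries pairwise", {
  est <- list(db1 = rbind(c(10.5, 0.3), c(3, 0.4), c(1.2, 0.5)),
              scale = c(0.5, 0.5, 0.5))
  se <- list(db1 = rbind(c(0.2, 0.2), c(49.9, 0.2), c(0.2, 0.2)),
             scale = c(0.1, 0.1, 0.1))
  st <- hand_stack(est, se)
  st$excl$delta_beta[3, 1, 1, 1] <- TRUE   # boundary-flagged SE
  trimmed <- trim_estimates(st)
  expect_true(trimmed$excl$delta_beta[1, 1, 1, 1])    # estimate 10.5 > |10|
  expect_false(trimmed$excl$delta_beta[2, 1, 1, 1])   # SE 49.9 < 50 retained
  expect_true(trimmed$excl$delta_beta[3, 1, 1, 1])    # boundary SE excluded
  expect_false(trimmed$excl$delta_beta[1, 1, 1, 2])
})

test_that("accuracy summaries aggregate coordinates the way the study reports them", {
  # stack identical to the truth: zero error, full coverage
  R <- 6
  est <- list(db1 = matrix(rep(c(0.2, 0.6), each = R), R),
              scale = rep(0.5, R))
  se <- list(db1 = matrix(0.2, R, 2), scale = rep(0.1, R))
  s <- summarize_accuracy(hand_stack(est, se), hand_truth())
  db_row <- s[s$parameter_type == "delta_beta", ]
  expect_equal(db_row$rmdse, 0)
  expect_equal(db_row$coverage, 1)
  expect_equal(db_row$spearman, 1)

  # per-coordinate RMdSEs (0.2, 0.6) aggregate to their median 0.4
  est2 <- list(db1 = cbind(0.2 + c(-0.2, 0.2, -0.2, 0.2, -0.2, 0.2),
                           0.6 + c(-0.6, 0.6, -0.6, 0.6, -0.6, 0.6)),
               scale = rep(0.5, R))
  s2 <- summarize_accuracy(hand_stack(est2, se), hand_truth())
  expect_equal(s2$rmdse[s2$parameter_type == "delta_beta"], 0.4)

  # indices are invariant to replication order
  perm <- c(4, 2, 6, 1, 3, 5)
  est3 <- list(db1 = est2$db1[perm, ], scale = est2$scale[perm])
  s3 <- summarize_accuracy(hand_stack(est3, se), hand_truth())
  expect_equal(s3$rmdse, s2$rmdse)
  expect_equal(s3$coverage, s2$coverage)
})

test_that("spearman concordance matches the textbook rank formula", {
  R <- 3
  truth <- parameter_set(array(1:5, c(1, 1, 5)), 1, 0.5, 0)
  db_e <- array(NA_real_, c(R, 1, 1, 5))
  for (r in 1:R) db_e[r, 1, 1, ] <- c(1, 2, 3, 5, 4)
  st <- structure(list(
    est = list(delta_beta = db_e, discrimination = matrix(1, R, 1),
               trait_scale = matrix(0.5, R, 1),
               class_logit = matrix(0, R, 1)),
    se = list(), excl = list(), n_replications = R),
    class = "mixirt_stack")
  expect_equal(unname(spearman_concordance(st, truth)), 0.9)

  for (r in 1:R) db_e[r, 1, 1, ] <- 1:5
  st$est$delta_beta <- db_e
  expect_equal(unname(spearman_concordance(st, truth)), 1)
  for (r in 1:R) db_e[r, 1, 1, ] <- -(1:5)
  st$est$delta_beta <- db_e
  expect_equal(unname(spearman_concordance(st, truth)), -1)
})

test_that("class-size accuracy is computed on the logit scale by default", {
  tp <- toy_params(G = 2, I = 1, C = 3, seed = 14)
  R <- 4
  db_e <- array(rep(tp$delta_beta, each = R), c(R, dim(tp$delta_beta)))
  st <- structure(list(
    est = list(delta_beta = db_e,
               discrimination = matrix(1, R, 1),
               trait_scale = matrix(tp$trait_scale, R, 2, byrow = TRUE),
               class_logit = matrix(c(0, tp$class_logit[2] + 0.1), R, 2,
                                    byrow = TRUE)),
    se = list(delta_beta = array(0.2, c(R, dim(tp$delta_beta))),
              discrimination = matrix(NA_real_, R, 1),
              trait_scale = matrix(0.05, R, 2),
              class_logit = matrix(c(NA, 0.2), R, 2, byrow = TRUE)),
    excl = list(delta_beta = array(FALSE, c(R, dim(tp$delta_beta))),
                discrimination = matrix(FALSE, R, 1),
                trait_scale = matrix(FALSE, R, 2),
                class_logit = matrix(FALSE, R, 2)),
    n_replications = R), class = "mixirt_stack")
  s <- summarize_accuracy(st, tp)
  lg <- s[s$parameter_type == "class_logit", ]
  expect_equal(nrow(lg), 1)          # reference class excluded
  expect_equal(lg$class, 2)
  expect_equal(lg$rmdse, 0.1)        # deviation applied on the logit scale
  sp <- summarize_accuracy(st, tp, class_size_on_proportion_scale = TRUE)
  expect_true(all(c("class_size") %in% sp$parameter_type))
})
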