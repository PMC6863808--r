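test_that("EM never decreases the marginal log-likelihood", {
  cfg <- toy_fit_config(em_max_iter = 60L, em_tol = 1e-4)
  for (seed in 1:6) {
    tp <- toy_params(G = 2, I = 3, C = 4, seed = seed)
    dat <- generate_dataset(tp, 150, seed + 100)
    fit <- fit_em(dat, random_start(params_spec(tp), seed + 500), cfg)
    expect_true(all(diff(fit$loglik_trace) > -1e-8),
                label = sprintf("monotone ascent, seed %d", seed))
  }
})

test_that("a one-class partial credit model is recovered at large N", {
  truth <- parameter_set(
    load_generating_fixture("mPCM")$delta_beta[2, , , drop = FALSE],
    rep(1, 5), 0.3, 0)
  dat <- generate_dataset(truth, 20000, 17)
  start <- truth
  start$delta_beta[] <- 0
  start$trait_scale <- 0.5
  cfg <- fit_config(em_tol = 1e-3, n_quadrature = 40L)
  fit <- refine_newton(fit_em(dat, start, cfg), dat, cfg)
  err <- abs(fit$estimates$delta_beta - truth$delta_beta)
  # the profile contains near-empty categories (implied probability below
  # 1%) whose step parameters carry little information even at this N;
  # every well-supported step is recovered tightly, sparse ones loosely
  imp <- implied_category_distribution(truth, build_quadrature(40))
  sparse <- sapply(1:5, function(i)
    imp[i, 1:10] < 0.01 | imp[i, 2:11] < 0.01)   # 10 x 5 -> steps x items
  sparse <- t(sparse)
  expect_true(all(err[1, , ][!sparse] < 0.08))
  expect_true(all(err < 1))
  expect_lt(abs(fit$estimates$trait_scale - 0.3), 0.05)
})

test_that("the Newton stage is an ascent step with a small final gradient", {
  # ascent contract on random small instances
  cfg <- toy_fit_config(em_max_iter = 3L, em_tol = 1e-6)
  for (seed in 1:30) {
    tp <- toy_params(G = sample(1:2, 1), I = 2, C = 3, seed = seed)
    dat <- generate_dataset(tp, 80, seed + 40)
    rough <- fit_em(dat, random_start(params_spec(tp), seed), cfg)
    refined <- refine_newton(rough, dat, cfg)
    expect_gte(refined$loglik, rough$loglik - 1e-10)
  }

  # small gradient at the refined optimum of a one-class toy model,
  # cross-checked against numerical differentiation of the marginal loglik
  tp <- toy_params(G = 1, I = 2, C = 3, seed = 4)
  dat <- generate_dataset(tp, 400, 44)
  cfg2 <- toy_fit_config(em_tol = 1e-6, em_max_iter = 2000L,
                         nr_factr = 10, nr_tol = 1e-12)
  fit <- refine_newton(fit_em(dat, tp, cfg2), dat, cfg2)
  grid <- build_quadrature(cfg2$n_quadrature)
  v <- mixirtsim:::free_par(fit$estimates)
  num_grad <- vapply(seq_along(v), function(j) {
    h <- 1e-5
    vp <- v; vp[j] <- v[j] + h
    vm <- v; vm[j] <- v[j] - h
    (marginal_loglik(mixirtsim:::set_free_par(fit$estimates, vp),
                     dat, grid) -
       marginal_loglik(mixirtsim:::set_free_par(fit$estimates, vm),
                       dat, grid)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num_grad)), 1e-3)   # weak trait-scale direction caps
                                        # the reachable gradient norm

  # refining an already-stationary point changes nothing material
  again <- refine_newton(fit, dat, cfg2)
  expect_equal(again$loglik, fit$loglik, tolerance = 1e-7)
})

test_that("the analytic score matches numerical differentiation", {
  tp <- toy_params(G = 2, I = 2, C = 4, seed = 9)
  dat <- generate_dataset(tp, 120, 10)
  grid <- build_quadrature(21)
  y <- dat$responses
  st <- mixirtsim:::estep(tp, y, grid)
  analytic <- mixirtsim:::score_from_stats(tp, st, grid)
  v <- mixirtsim:::free_par(tp)
  num <- vapply(seq_along(v), function(j) {
    h <- 1e-6 * max(1, abs(v[j]))
    vp <- v; vp[j] <- v[j] + h
    vm <- v; vm[j] <- v[j] - h
    (marginal_loglik(mixirtsim:::set_free_par(tp, vp), y, grid) -
       marginal_loglik(mixirtsim:::set_free_par(tp, vm), y, grid)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(analytic), num, tolerance = 1e-5)
})

test_that("standard errors match the closed-form binomial oracle", {
  # one class, one binary item: the single step logit is a binomial logit
  truth <- parameter_set(array(0.4, c(1, 1, 1)), 1, 1e-4, 0)
  dat <- generate_dataset(truth, 4000, 3)
  cfg <- fit_config(em_tol = 1e-6, n_quadrature = 11L)
  fit <- refine_newton(fit_em(dat, truth, cfg), dat, cfg)
  fit <- compute_standard_errors(fit, dat, cfg)
  p_hat <- mean(dat$responses)
  closed <- sqrt(1 / (4000 * p_hat * (1 - p_hat)))
  expect_equal(fit$standard_errors$delta_beta[1, 1, 1], closed,
               tolerance = 0.02)
})

test_that("standard errors shrink like 1/sqrt(N)", {
  # equal-discrimination items keep every coordinate well identified, so
  # the asymptotic scaling is visible without near-singular contamination
  set.seed(12)
  truth <- parameter_set(array(runif(8, -1, 1), c(1, 4, 2)), rep(1, 4),
                         0.6, 0)
  cfg <- fit_config(em_tol = 1e-5, n_quadrature = 21L)
  ses <- lapply(c(1000, 4000), function(N) {
    dat <- generate_dataset(truth, N, 21)
    fit <- compute_standard_errors(
      refine_newton(fit_em(dat, truth, cfg), dat, cfg), dat, cfg)
    as.numeric(fit$standard_errors$delta_beta)
  })
  ratio <- ses[[1]] / ses[[2]]
  expect_true(all(ratio > 1.8 & ratio < 2.2))
})

test_that("degenerate flat data produce boundary flags", {
  truth <- parameter_set(array(0, c(1, 2, 2)), c(1, 1), 0.3, 0)
  flat <- response_matrix(matrix(0L, 60, 2), rep(1L, 60))
  cfg <- fit_config(em_max_iter = 400L, n_quadrature = 11L)
  fit <- fit_em(flat, truth, cfg)
  fit <- compute_standard_errors(fit, flat, cfg)
  expect_true(any(unlist(fit$boundary_se), na.rm = TRUE))
})

test_that("posterior classification obeys its closed forms", {
  # a single class is assigned with certainty
  tp1 <- toy_params(G = 1, I = 2, C = 3, seed = 31)
  dat <- generate_dataset(tp1, 50, 1)
  cfg <- toy_fit_config()
  fit <- fit_em(dat, tp1, toy_fit_config(em_max_iter = 1L))
  pc <- posterior_classification(fit, dat)
  expect_equal(as.numeric(pc$posterior), rep(1, 50))
  expect_equal(pc$mean_assignment_probability, 1)

  # indistinguishable classes: posteriors equal the class proportions
  db <- array(rep(c(0.3, -0.2, 0.5), each = 2), c(2, 1, 3))
  tp2 <- parameter_set(db, 1, c(0.4, 0.4), c(0, 0.6))
  dat2 <- generate_dataset(tp2, 40, 2)
  fit2 <- fit_em(dat2, tp2, toy_fit_config(em_max_iter = 1L))
  fit2$estimates <- tp2   # evaluate at the symmetric parameters themselves
  pc2 <- posterior_classification(fit2, dat2)
  pi_g <- class_proportions(tp2$class_logit)
  expect_true(all(abs(sweep(pc2$posterior, 2, pi_g)) < 1e-10))

  # agreement with brute-force enumeration on a 2-item, 3-category model
  tp3 <- toy_params(G = 2, I = 2, C = 3, seed = 33)
  dat3 <- generate_dataset(tp3, 60, 3)
  fit3 <- fit_em(dat3, tp3, toy_fit_config(em_max_iter = 1L))
  fit3$estimates <- tp3
  pc3 <- posterior_classification(fit3, dat3)
  z <- seq(-8, 8, length.out = 4001)
  w <- dnorm(z); w <- w / sum(w)
  pi_g <- class_proportions(tp3$class_logit)
  for (v in c(1, 17, 42)) {
    lik_g <- vapply(1:2, function(g) {
      lz <- rep(1, length(z))
      for (i in 1:2) {
        pz <- vapply(z, function(zz)
          oracle_catprob(tp3$delta_beta[g, i, ],
                         tp3$item_discrimination[i],
                         tp3$trait_scale[g] * zz)[dat3$responses[v, i] + 1L],
          numeric(1))
        lz <- lz * pz
      }
      sum(w * lz)
    }, numeric(1))
    expect_equal(pc3$posterior[v, ], pi_g * lik_g / sum(pi_g * lik_g),
                 tolerance = 1e-6)
  }
})

test_that("the improper-solution rule is a strict 10% threshold", {
  fake_fit <- function(n_flagged) {
    # 99 delta-beta SEs + 1 trait-scale SE = 100 counted standard errors
    flags <- rep(FALSE, 100)
    flags[seq_len(n_flagged)] <- TRUE
    db <- array(flags[1:99], c(1, 9, 11))
    structure(
      list(spec = model_spec(9, 12, 1, TRUE),
           boundary_se = list(delta_beta = db,
                              item_discrimination = rep(NA, 9),
                              trait_scale = flags[100],
                              class_logit = NA)),
      class = "mixirt_fit")
  }
  expect_false(diagnose_solution(fake_fit(0))$improper)
  expect_false(diagnose_solution(fake_fit(10))$improper)  # exactly 10%
  expect_true(diagnose_solution(fake_fit(11))$improper)   # 11% > 10%
})

test_that("multi-start fitting is a best-of composition", {
  tp <- toy_params(G = 2, I = 2, C = 4, seed = 51)
  dat <- generate_dataset(tp, 250, 52)
  spec <- params_spec(tp)

  # n_starts = 1 equals the fit_em -> refine_newton composition
  cfg1 <- toy_fit_config(n_starts = 1L, em_tol = 1e-3)
  msf <- multi_start_fit(dat, spec, cfg1, seed = 5)
  s <- random_start(spec, 5 + 7)
  short <- cfg1; short$em_max_iter <- cfg1$start_em_iter
  manual <- refine_newton(
    fit_em(dat, fit_em(dat, s, short)$estimates, cfg1), dat, cfg1)
  expect_equal(msf$loglik, manual$loglik, tolerance = 1e-6)

  # a warm start at the truth is never beaten by it being left out
  cfgw <- toy_fit_config(n_starts = 2L, em_tol = 1e-3, warm_start = tp)
  best <- multi_start_fit(dat, spec, cfgw, seed = 5)
  truth_run <- refine_newton(fit_em(dat, tp, cfg1), dat, cfg1)
  expect_gte(best$loglik, truth_run$loglik - 0.01)
})

test_that("well-separated mixtures reach a replicated optimum", {
  db <- array(0, c(2, 3, 1))
  db[1, , 1] <- 2.5
  db[2, , 1] <- -2.5
  tp <- parameter_set(db, rep(1, 3), c(0.3, 0.3), c(0, 0.2))
  dat <- generate_dataset(tp, 300, 71)
  lls <- vapply(1:10, function(k)
    multi_start_fit(dat, params_spec(tp),
                    toy_fit_config(n_starts = 3L, em_tol = 1e-4),
                    seed = k)$loglik, numeric(1))
  expect_gte(sum(abs(lls - max(lls)) < 0.01), 9)
})

test_that("the estimator is equivariant to label permutation of the start", {
  tp <- toy_params(G = 2, I = 2, C = 4, seed = 61)
  dat <- generate_dataset(tp, 150, 62)
  cfg <- toy_fit_config(em_max_iter = 25L, em_tol = 1e-8)
  f1 <- fit_em(dat, tp, cfg)
  f2 <- fit_em(dat, permute_classes(tp, c(2, 1)), cfg)
  expect_equal(f2$estimates$delta_beta[c(2, 1), , , drop = FALSE],
               f1$estimates$delta_beta, tolerance = 1e-6)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("free-parameter counts match the optimized vector length", {
  for (args in list(list(5, 11, 3, FALSE), list(5, 11, 3, TRUE),
                    list(15, 6, 2, FALSE), list(1, 2, 1, TRUE))) {
    spec <- do.call(model_spec, args)
    p <- random_start(spec, 1)
    expect_identical(count_free_parameters(spec),
                     length(mixirtsim:::free_par(p)))
  }
})

test_that("observed-information and OPG standard errors agree on a toy model", {
  # four equal-discrimination items keep the trait scale well identified,
  # so both information estimates are far from singular
  set.seed(81)
  truth <- parameter_set(array(runif(8, -1, 1), c(1, 4, 2)), rep(1, 4),
                         0.6, 0)
  dat <- generate_dataset(truth, 3000, 82)
  cfg <- fit_config(em_tol = 1e-5, n_quadrature = 21L)
  fit <- refine_newton(fit_em(dat, truth, cfg), dat, cfg)
  oi <- compute_standard_errors(fit, dat, cfg)
  cfg_opg <- cfg; cfg_opg$se_method <- "opg"
  opg <- compute_standard_errors(fit, dat, cfg_opg)
  expect_equal(as.numeric(opg$standard_errors$delta_beta),
               as.numeric(oi$standard_errors$delta_beta), tolerance = 0.15)

  # per-respondent scores add up to the full analytic score
  grid <- build_quadrature(21)
  sc <- mixirtsim:::per_respondent_scores(fit$estimates, dat$responses, grid)
  st <- mixirtsim:::estep(fit$estimates, dat$responses, grid)
  expect_equal(colSums(sc),
               mixirtsim:::score_from_stats(fit$estimates, st, grid),
               tolerance = 1e-8)
})
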