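test_that("cluster weight matrix is the sd-outer-product times R", {
  expect_equal(cluster_weight_matrix(c(0.5, 0.5), diag(2)),
               diag(0.25, 2))
  W <- cluster_weight_matrix(c(0.5, 0.5),
                             build_correlation(
                               working_correlation("exchangeable",
                                                   rho = 0.4), 1:2))
  expect_equal(W[1, 2], 0.1)
  set.seed(5)
  pi <- runif(4, 0.1, 0.9)
  R <- build_correlation(working_correlation("ar1", rho = 0.3), 1:4)
  sd <- sqrt(pi * (1 - pi))
  expect_equal(cluster_weight_matrix(pi, R), outer(sd, sd) * R)
  expect_error(cluster_weight_matrix(c(0, 0.5), diag(2)), "inside")
})

test_that("independence GEE at alpha = 1 reproduces pooled ML logistic regression", {
  d <- small_cohort(n = 120, seed = 11)
  X <- build_design(d)
  fit <- gee_fit(X, d$y, d$subject_id, d$time, link_spec("logit"),
                 working_correlation("independence"))
  oracle <- glm.fit(X, d$y, family = binomial())
  se_oracle <- sqrt(diag(chol2inv(chol(
    crossprod(X * sqrt(oracle$weights))))))
  expect_equal(unname(fit$beta), unname(oracle$coefficients),
               tolerance = 1e-4)
  expect_equal(unname(fit$se_model), se_oracle, tolerance = 1e-4)
})

test_that("size-one clusters make every structure collapse to independence", {
  fx <- independent_fixture(250, alpha = 1, seed = 13, z_sd = 1)
  ref <- gee_fit(fx$x, fx$y, id = seq_len(250))
  for (s in c("exchangeable", "ar1", "m_dependent", "unstructured")) {
    expect_warning(f <- gee_fit(fx$x, fx$y, id = seq_len(250),
                                wc = working_correlation(s)),
                   "independence")
    expect_equal(f$beta, ref$beta)
  }
})

test_that("information accumulates: duplicating all clusters halves both covariances", {
  d <- small_cohort(n = 60, seed = 17, mcar = 0)
  X <- build_design(d)
  wc <- working_correlation("exchangeable")
  f1 <- gee_fit(X, d$y, d$subject_id, d$time, wc = wc)
  d2 <- rbind(d, d)
  d2$subject_id <- c(d$subject_id, d$subject_id + max(d$subject_id))
  X2 <- build_design(d2)
  f2 <- gee_fit(X2, d2$y, d2$subject_id, d2$time, wc = wc)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  expect_equal(model_based_covariance(f2),
               model_based_covariance(f1) / 2, tolerance = 1e-5)
  expect_equal(sandwich_covariance(f2),
               sandwich_covariance(f1) / 2, tolerance = 1e-5)
})

test_that("misspecified independence inflates robust over model SEs", {
  cfg <- simulation_config(n_subjects = 400, alpha_true = 1,
                           latent_corr = working_correlation("ar1",
                                                             rho = 0.8),
                           mcar_rate = 0, seed = 23)
  d <- simulate_morbidity_study(cfg)
  X <- build_design(d)
  fit <- gee_fit(X, d$y, d$subject_id, d$time,
                 wc = working_correlation("independence"))
  vr <- variance_ratio(fit$se_model, fit$se_robust)
  # baseline (time-constant) covariates are the ones whose independence
  # SEs understate the truth most
  expect_gt(vr[["bv"]], 1)
  expect_gt(mean(vr), 1)
})

test_that("coefficients agree across structures on exchangeable data", {
  cfg <- simulation_config(n_subjects = 350, alpha_true = 1,
                           latent_corr = working_correlation(
                             "exchangeable", rho = 0.5),
                           mcar_rate = 0, seed = 29)
  d <- simulate_morbidity_study(cfg)
  X <- build_design(d)
  fits <- lapply(c("independence", "exchangeable", "ar1", "m_dependent",
                   "unstructured"), function(s) {
    gee_fit(X, d$y, d$subject_id, d$time,
            wc = working_correlation(s))
  })
  ref <- fits[[2]]
  for (f in fits) {
    expect_true(all(abs(f$beta - ref$beta) < 2 * ref$se_robust))
  }
})

test_that("Wald table relations hold and the fit is deterministic", {
  d <- small_cohort(n = 90, seed = 31)
  X <- build_design(d)
  f1 <- gee_fit(X, d$y, d$subject_id, d$time,
                link_spec("skewed_logit", 3),
                working_correlation("ar1"))
  tab <- wald_table(f1)
  expect_equal(tab$wald_z, tab$estimate / tab$se_robust)
  expect_equal(tab$p_value, 2 * pnorm(-abs(tab$wald_z)))
  expect_equal(tab$se_model, unname(sqrt(diag(model_based_covariance(f1)))))
  expect_equal(tab$se_robust, unname(sqrt(diag(sandwich_covariance(f1)))))
  f2 <- gee_fit(X, d$y, d$subject_id, d$time,
                link_spec("skewed_logit", 3),
                working_correlation("ar1"))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$cov_robust, f2$cov_robust)
  expect_identical(f1$n_iter, f2$n_iter)
})

test_that("convergence control is honored and reported", {
  d <- small_cohort(n = 70, seed = 37)
  X <- build_design(d)
  expect_warning(f <- gee_fit(X, d$y, d$subject_id, d$time,
                              wc = working_correlation("ar1"),
                              control = gee_control(tol = 1e-12,
                                                    max_iter = 2L)),
                 "converge")
  expect_false(f$converged)
  expect_identical(f$n_iter, 2L)
  expect_error(gee_control(tol = 0), "tol")
})
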