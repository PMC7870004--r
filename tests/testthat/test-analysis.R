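test_that("morbidity scores binarize as any-illness", {
  expect_identical(binarize_morbidity(0L), 0L)
  expect_identical(binarize_morbidity(7L), 1L)
  expect_identical(binarize_morbidity(c(0, 1, 19, 0)), c(0L, 1L, 1L, 0L))
  expect_error(binarize_morbidity(20), "\\[0, 19\\]")
  expect_error(binarize_morbidity(-1), "\\[0, 19\\]")
  expect_error(binarize_morbidity(1.5), "\\[0, 19\\]")
})

test_that("complete-case filter drops rows and empty subjects with a report", {
  # 401 subjects; 74 lose their exposure entirely, one loses month 3
  d <- do.call(rbind, lapply(1:401, function(i) {
    data.frame(subject_id = i, time = 1:6, y = rep(0:1, 3), bv = 0L,
               hiv = 0L, male = 1L, breastfed = 1L, weight = 4)
  }))
  d$bv[d$subject_id <= 74] <- NA
  d$y[d$subject_id == 100 & d$time == 3] <- NA
  expect_message(out <- complete_case_filter(d), "74 subjects removed")
  expect_identical(length(unique(out$subject_id)), 327L)
  expect_identical(sum(out$subject_id == 100), 5L)
  expect_identical(attr(out, "n_rows_dropped"), 74L * 6L + 1L)
  # no missingness: identity
  d2 <- d[d$subject_id > 74 & !is.na(d$y), ]
  out2 <- suppressMessages(complete_case_filter(d2))
  expect_identical(nrow(out2), nrow(d2))
  d3 <- d; d3$weight <- NA
  expect_error(suppressMessages(complete_case_filter(d3)), "complete")
})

test_that("design matrix lays out the eight model columns", {
  d <- data.frame(subject_id = rep(1:2, each = 6), time = rep(1:6, 2),
                  y = rep(c(0L, 1L), 6),
                  bv = rep(c(1L, 0L), each = 6),
                  hiv = rep(c(0L, 1L), each = 6),
                  male = rep(c(1L, 0L), each = 6),
                  breastfed = rep(c(0L, 1L), each = 6),
                  weight = seq(3, 5.2, length.out = 12))
  X <- build_design(d)
  expect_identical(colnames(X),
                   c("intercept", "breastfed", "bv", "bv_time", "hiv",
                     "male", "time", "weight"))
  expect_identical(dim(X), c(12L, 8L))
  expect_true(all(X[, "intercept"] == 1))
  expect_equal(unname(X[4, "bv_time"]), 4)  # BV subject, month 4
  expect_equal(X[d$bv == 0, "bv_time"], rep(0, 6)) # unexposed: always 0
  expect_equal(X[, "weight"], d$weight)
  d_const <- d; d_const$hiv <- 1L
  expect_warning(build_design(d_const), "constant")
})

test_that("dataset validation enforces the longitudinal invariants", {
  d <- small_cohort(n = 20, seed = 41)
  expect_silent(validate_morbidity_data(d))
  d_dup <- rbind(d, d[1, ])
  expect_error(validate_morbidity_data(d_dup), "duplicate")
  d_var <- d; d_var$bv[1] <- 1 - d_var$bv[1]
  expect_error(validate_morbidity_data(d_var),
               "constant within subject")
  d_bady <- d; d_bady$y[3] <- 2
  expect_error(validate_morbidity_data(d_bady), "0/1")
  d_badw <- d; d_badw$weight[2] <- -1
  expect_error(validate_morbidity_data(d_badw), "positive")
})

test_that("variance ratio squares the SE quotient", {
  expect_equal(round(variance_ratio(0.228, 0.276), 3), 1.465)
  expect_equal(variance_ratio(0.3, 0.3), 1)
  expect_equal(variance_ratio(0.431, 0.791), (0.791 / 0.431)^2)
  expect_error(variance_ratio(0, 0.1), "positive")
})

test_that("time-varying exposure odds ratios follow the interaction", {
  expect_equal(unname(bv_time_effects(0.7, 0, 1:6)), rep(exp(0.7), 6))
  # shifting the time coding by c multiplies every OR by exp(c * b_int)
  or1 <- bv_time_effects(1.2, -0.3, 1:6)
  or2 <- bv_time_effects(1.2, -0.3, 1:6 + 2)
  expect_equal(unname(or2 / or1), rep(exp(2 * -0.3), 6))
  expect_error(bv_time_effects(1, 0.1, 0), "positive integers")
})

test_that("fitted exposure effect declines over months under a negative interaction", {
  d <- small_cohort(n = 327, seed = 43, mcar = 0)
  fits <- suppressWarnings(fit_all(d, alpha = 3, structures = "ar1"))
  sl <- fits$fits$slgee$ar1
  or <- bv_time_effects(sl$beta[["bv"]], sl$beta[["bv_time"]], 1:6)
  expect_true(all(diff(or) < 0))
})

test_that("frequency table counts are internally consistent", {
  d <- small_cohort(n = 100, seed = 47)
  tab <- morbidity_frequency_table(d)
  expect_equal(tab$n_present + tab$n_absent, tab$n_total)
  expect_equal(tab$ill_present + tab$ill_absent, tab$ill_total)
  expect_true(all(tab$pct_total == round(100 * tab$ill_total / tab$n_total)))
  d0 <- d; d0$y <- 0L
  tab0 <- morbidity_frequency_table(d0)
  expect_true(all(tab0$pct_total == 0))
})

test_that("the two model arms coincide when alpha is one", {
  d <- small_cohort(n = 80, seed = 53)
  fits <- suppressWarnings(fit_all(d, alpha = 1, structures = "exchangeable"))
  expect_equal(fits$fits$gee$exchangeable$beta,
               fits$fits$slgee$exchangeable$beta, tolerance = 1e-12)
  vr <- variance_ratio_table(fits)
  expect_identical(nrow(vr), 16L)
  expect_true(all(vr$variance_ratio > 0))
})

test_that("long-format CSV round-trips, including the score variant", {
  d <- small_cohort(n = 15, seed = 59)
  path <- withr::local_tempfile(fileext = ".csv")
  write_morbidity_csv(d, path)
  d2 <- read_morbidity_csv(path)
  expect_equal(d2$y, d$y)
  expect_equal(d2$weight, d$weight, tolerance = 1e-12)
  # raw-score variant binarizes on read
  d_score <- d; d_score$score <- ifelse(d$y == 1, 5L, 0L); d_score$y <- NULL
  write.csv(d_score, path, row.names = FALSE, na = "")
  d3 <- read_morbidity_csv(path)
  expect_equal(d3$y, d$y)
  # schema errors name the column
  write.csv(d[setdiff(names(d), "weight")], path, row.names = FALSE)
  expect_error(read_morbidity_csv(path), "weight")
})
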