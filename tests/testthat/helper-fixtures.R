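# Shared fixtures, generated in code at test time.

# Small correlated cohort in the default generating regime.
small_cohort <- function(n = 80L, seed = 42L, alpha = 3, mcar = 0.05) {
  simulate_morbidity_study(simulation_config(n_subjects = n,
                                             alpha_true = alpha,
                                             mcar_rate = mcar,
                                             seed = seed))
}

# Independent Bernoulli observations with a wide linear predictor, the
# regime where the skewness parameter is best identified.
independent_fixture <- function(n, alpha, seed, beta = c(0.2, 1),
                                z_sd = 3) {
  set.seed(seed)
  x <- cbind(intercept = 1, z = stats::rnorm(n, 0, z_sd))
  lk <- if (alpha == 1) link_spec("logit") else
    link_spec("skewed_logit", alpha = alpha)
  y <- stats::rbinom(n, 1, inverse_link(drop(x %*% beta), lk))
  list(x = x, y = y)
}

# Deterministic cohort reproducing the motivating study's month-one
# margins: 327 subjects, 148 BV-exposed (115 ill in month 1), 179
# unexposed (85 ill), 61 HIV-positive, 168 male, 185 breastfed.
descriptives_cohort <- function() {
  n <- 327L
  bv <- rep(c(1L, 0L), c(148L, 179L))
  hiv <- rep(c(1L, 0L), c(61L, n - 61L))
  male <- rep(c(1L, 0L), c(168L, n - 168L))
  breastfed <- rep(c(1L, 0L), c(185L, n - 185L))
  y1 <- integer(n)
  y1[bv == 1][seq_len(115L)] <- 1L
  y1[bv == 0][seq_len(85L)] <- 1L
  data.frame(subject_id = seq_len(n), time = 1L, y = y1, bv = bv,
             hiv = hiv, male = male, breastfed = breastfed, weight = 3.5)
}
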