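#' GEE fitting control
#'
#' @param tol Convergence tolerance on the maximum relative coefficient
#'   change between scoring iterations (default 1e-4).
#' @param max_iter Maximum scoring iterations (default 100; raise to 200
#'   for slowly converging structures).
#' @return A list of class `"gee_control"`.
#' @export
gee_control <- function(tol = 1e-4, max_iter = 100L) {
  stopifnot(is.numeric(tol), length(tol) == 1L, tol > 0,
            max_iter >= 1L)
  structure(list(tol = tol, max_iter = as.integer(max_iter)),
            class = "gee_control")
}

#' Cluster weight matrix
#'
#' \eqn{W_i = G_i^{1/2} R_i(\rho) G_i^{1/2}} with \eqn{G_i} diagonal,
#' entries \eqn{v(\pi_{ij}) = \pi_{ij}(1-\pi_{ij})} (dispersion fixed
#' at 1).
#'
#' @param pi_i Fitted probabilities for one cluster, strictly in (0,1).
#' @param R_i Working correlation matrix, conformable with `pi_i`.
#' @return Symmetric positive-definite matrix with diagonal
#'   \eqn{\pi(1-\pi)}; near-singular results are ridge-repaired with a
#'   warning.
#' @export
cluster_weight_matrix <- function(pi_i, R_i) {
  if (any(pi_i <= 0 | pi_i >= 1)) {
    stop("`pi_i` must be strictly inside (0, 1)", call. = FALSE)
  }
  sd_i <- sqrt(pi_i * (1 - pi_i))
  W <- outer(sd_i, sd_i) * R_i
  repair_pd(W, min_eig = 1e-12, label = "cluster weight")
}

# Split row indices by cluster id, preserving first-appearance order.
split_clusters <- function(id) {
  split(seq_along(id), factor(id, levels = unique(id)))
}

#' Fit a marginal binary regression by generalized estimating equations
#'
#' Solves \eqn{\sum_i D_i^\top W_i^{-1} (y_i - \pi_i) = 0} by modified
#' Fisher scoring (iteratively reweighted least squares in matrix form),
#' where \eqn{D_i = \Lambda_i X_i} and \eqn{\Lambda_i} holds the
#' mean derivatives of the chosen link. The skewness \eqn{\alpha} of an
#' asymmetric link is held fixed at its supplied value (typically the
#' first-stage [fit_skew_glm()] estimate). Association parameters are
#' moment re-estimated from Pearson residuals after every scoring step.
#'
#' Both the model-based covariance \eqn{B^{-1}} (the inverse bread
#' \eqn{B = \sum_i D_i^\top W_i^{-1} D_i}) and the Huber sandwich
#' \eqn{B^{-1} M B^{-1}} with meat
#' \eqn{M = \sum_i D_i^\top W_i^{-1} r_i r_i^\top W_i^{-1} D_i}
#' are returned; clusters, not rows, are the independent units in the
#' meat. Wald statistics use the robust standard errors with two-sided
#' standard-normal p-values.
#'
#' @param x Design matrix (include the intercept column).
#' @param y Binary response vector.
#' @param id Cluster (subject) identifier, one per row.
#' @param times Integer visit times, one per row, strictly increasing
#'   within cluster. Defaults to row order within cluster.
#' @param link A [link_spec()]; `alpha` is fixed, not estimated, here.
#' @param wc A [working_correlation()]. A supplied `rho` is used as the
#'   starting value and still re-estimated; independence skips
#'   estimation.
#' @param control A [gee_control()].
#' @return An object of class `"gee_fit"` with elements `beta`,
#'   `cov_model`, `cov_robust`, `se_model`, `se_robust`, `wald_z`,
#'   `p_values`, `alpha`, `link`, `wc` (with the final `rho`),
#'   `phi` (fixed at 1), `n_iter`, `converged`, `n_clusters`, `n_obs`.
#' @examples
#' set.seed(42)
#' x <- cbind(intercept = 1, z = rnorm(300))
#' y <- rbinom(300, 1, plogis(x %*% c(0.2, 0.8)))
#' fit <- gee_fit(x, y, id = seq_len(300), link = link_spec("logit"),
#'                wc = working_correlation("independence"))
#' wald_table(fit)
#' @export
gee_fit <- function(x, y, id, times = NULL,
                    link = link_spec("logit"),
                    wc = working_correlation("independence"),
                    control = gee_control()) {
  x <- as.matrix(x)
  link <- as_link_spec(link)
  stopifnot(inherits(wc, "working_correlation"),
            inherits(control, "gee_control"))
  check_binary(y, nrow(x))
  if (length(id) != nrow(x)) stop("`id` must match rows of `x`",
                                  call. = FALSE)
  q <- ncol(x)
  clusters <- split_clusters(id)
  if (is.null(times)) {
    times <- unlist(lapply(clusters, seq_along), use.names = FALSE)[
      order(unlist(clusters, use.names = FALSE))]
  }
  times <- as.integer(times)
  times_by <- lapply(clusters, function(ix) times[ix])
  if (any(vapply(times_by, function(tt) any(diff(tt) <= 0), logical(1)))) {
    stop("`times` must be strictly increasing within cluster",
         call. = FALSE)
  }
  n_times <- max(times)

  all_singletons <- all(lengths(clusters) == 1L)
  structure_used <- wc$structure
  if (all_singletons && wc$structure != "independence") {
    warning("all clusters have size 1; falling back to independence",
            call. = FALSE)
    structure_used <- "independence"
  }

  # Initialize at the logistic MLE; for a non-logit link, translate it
  # into link space by regressing the forward-linked fitted
  # probabilities on the design (a saturating skew link diverges if
  # started at the raw logistic coefficients).
  glm0 <- stats::glm.fit(x, y, family = stats::binomial())
  beta <- glm0$coefficients
  if (link$family != "logit") {
    p0 <- clamp_prob(glm0$fitted.values, 1e-6)
    beta <- stats::lm.fit(x, forward_link(p0, link))$coefficients
  }
  rho <- wc$rho
  converged <- FALSE
  iter <- 0L
  bread <- meat <- NULL

  repeat {
    iter <- iter + 1L
    eta <- drop(x %*% beta)
    pi <- clamp_prob(inverse_link(eta, link))
    lam <- mean_derivative(eta, link)

    if (structure_used != "independence") {
      res <- pearson_residuals(y, pi)
      rho <- clip_rho(estimate_rho(lapply(clusters, function(ix) res[ix]),
                                   times_by, structure_used, m = wc$m,
                                   n_times = n_times))
    }
    wcur <- working_correlation(structure_used, rho = rho, m = wc$m)

    bread <- matrix(0, q, q)
    score <- numeric(q)
    meat <- matrix(0, q, q)
    for (k in seq_along(clusters)) {
      ix <- clusters[[k]]
      Di <- lam[ix] * x[ix, , drop = FALSE]
      Ri <- build_correlation(wcur, times_by[[k]])
      Wi <- cluster_weight_matrix(pi[ix], Ri)
      ri <- y[ix] - pi[ix]
      WiD <- solve(Wi, Di)
      Wir <- solve(Wi, ri)
      bread <- bread + crossprod(Di, WiD)
      score <- score + drop(crossprod(Di, Wir))
      u <- drop(crossprod(Di, Wir))
      meat <- meat + tcrossprod(u)
    }
    delta <- tryCatch(solve(bread, score), error = function(e) {
      stop("singular bread matrix in GEE update", call. = FALSE)
    })
    # cap the scoring step so an early overshoot cannot saturate the mean
    step_max <- max(abs(delta))
    if (step_max > 2) delta <- delta * (2 / step_max)
    beta <- beta + delta
    rel <- max(abs(delta) / pmax(abs(beta), 1e-4))
    if (rel < control$tol) { converged <- TRUE; break }
    if (iter >= control$max_iter) break
  }
  if (!converged) {
    warning("GEE did not converge in ", control$max_iter, " iterations",
            call. = FALSE)
  }
  if (length(clusters) < q) {
    warning("fewer clusters than coefficients; sandwich variance unreliable",
            call. = FALSE)
  }

  cov_model <- solve(bread)
  cov_model <- (cov_model + t(cov_model)) / 2
  cov_robust <- cov_model %*% meat %*% cov_model
  cov_robust <- (cov_robust + t(cov_robust)) / 2
  se_model <- sqrt(diag(cov_model))
  se_robust <- sqrt(diag(cov_robust))
  z <- beta / se_robust
  cn <- colnames(x) %||% paste0("x", seq_len(q))
  fit <- list(beta = stats::setNames(beta, cn),
              cov_model = cov_model, cov_robust = cov_robust,
              se_model = stats::setNames(se_model, cn),
              se_robust = stats::setNames(se_robust, cn),
              wald_z = stats::setNames(z, cn),
              p_values = stats::setNames(2 * stats::pnorm(-abs(z)), cn),
              alpha = link$alpha, link = link,
              wc = working_correlation(structure_used, rho = rho, m = wc$m),
              phi = 1, n_iter = iter, converged = converged,
              n_clusters = length(clusters), n_obs = nrow(x))
  class(fit) <- "gee_fit"
  fit
}

# Moment estimates can stray outside (-1, 1) early in the iteration;
# keep them in the feasible region.
clip_rho <- function(rho, bound = 0.99) {
  if (is.null(rho)) return(NULL)
  if (is.matrix(rho)) {
    off <- row(rho) != col(rho)
    rho[off] <- pmin(pmax(rho[off], -bound), bound)
    rho
  } else {
    pmin(pmax(rho, -bound), bound)
  }
}

#' Wald summary table for a GEE fit
#'
#' One row per coefficient: estimate, model-based SE, robust (sandwich)
#' SE, Wald Z (estimate / robust SE), and the two-sided normal p-value.
#'
#' @param fit A [gee_fit()] result.
#' @return A `data.frame` with columns `term`, `estimate`, `se_model`,
#'   `se_robust`, `wald_z`, `p_value`.
#' @export
wald_table <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  data.frame(term = names(fit$beta),
             estimate = unname(fit$beta),
             se_model = unname(fit$se_model),
             se_robust = unname(fit$se_robust),
             wald_z = unname(fit$wald_z),
             p_value = unname(fit$p_values),
             row.names = NULL)
}

#' @export
print.gee_fit <- function(x, digits = 3, ...) {
  cat(sprintf("GEE fit: %s link (alpha = %g), %s working correlation\n",
              x$link$family, x$alpha, x$wc$structure))
  cat(sprintf("%d clusters, %d observations, %d iterations (%s)\n",
              x$n_clusters, x$n_obs, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  tab <- wald_table(x)
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Model-based and sandwich covariance accessors
#'
#' The model-based covariance is the inverse bread
#' \eqn{(\sum_i D_i^\top W_i^{-1} D_i)^{-1}}; the robust (Huber
#' sandwich) covariance wraps the empirical meat between two inverse
#' breads and stays valid when the working correlation is misspecified.
#'
#' @param fit A [gee_fit()] result.
#' @return A symmetric positive-semidefinite q x q matrix.
#' @export
model_based_covariance <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  fit$cov_model
}

#' @rdname model_based_covariance
#' @export
sandwich_covariance <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  fit$cov_robust
}
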