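#' Working correlation specification
#'
#' Describes the assumed within-cluster correlation pattern
#' \eqn{R_i(\rho)} used by the GEE solver. Misspecifying the structure
#' costs efficiency only — the coefficient estimates remain consistent —
#' so all five common structures are offered and the choice is left to
#' the analyst.
#'
#' @param structure One of `"independence"`, `"exchangeable"`, `"ar1"`,
#'   `"m_dependent"`, `"unstructured"`.
#' @param rho Association parameter(s): a scalar for exchangeable / AR(1),
#'   a vector of length `m` (lags 1..m) for m-dependent, a symmetric
#'   matrix indexed by time for unstructured. `NULL` means "to be
#'   moment-estimated during fitting".
#' @param m Band width for the m-dependent structure (default 1).
#' @return An object of class `"working_correlation"`.
#' @export
working_correlation <- function(structure = c("independence", "exchangeable",
                                              "ar1", "m_dependent",
                                              "unstructured"),
                                rho = NULL, m = 1L) {
  structure <- match.arg(structure)
  m <- as.integer(m)
  if (structure == "m_dependent" && m < 1L) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  if (!is.null(rho)) check_rho(structure, rho, m)
  structure(list(structure = structure, rho = rho, m = m),
            class = "working_correlation")
}

check_rho <- function(structure, rho, m) {
  bad <- function(v) any(!is.finite(v)) || any(abs(v) >= 1)
  switch(structure,
    independence = NULL,
    exchangeable = ,
    ar1 = if (length(rho) != 1L || bad(rho)) {
      stop("scalar rho with |rho| < 1 required for ", structure,
           call. = FALSE)
    },
    m_dependent = if (length(rho) != m || bad(rho)) {
      stop("m-dependent rho must be a length-m vector with |rho| < 1",
           call. = FALSE)
    },
    unstructured = {
      if (!is.matrix(rho) || nrow(rho) != ncol(rho) ||
          max(abs(rho - t(rho))) > 1e-10 ||
          bad(rho[row(rho) != col(rho)])) {
        stop("unstructured rho must be a symmetric matrix with ",
             "off-diagonal entries in (-1, 1)", call. = FALSE)
      }
    })
  invisible(TRUE)
}

#' @export
print.working_correlation <- function(x, ...) {
  cat(sprintf("<working_correlation> %s\n", x$structure))
  if (!is.null(x$rho)) {
    cat("rho:\n"); print(x$rho)
  }
  if (x$structure == "m_dependent") cat("m =", x$m, "\n")
  invisible(x)
}

#' Realize a working correlation matrix for one cluster
#'
#' Builds the \eqn{n_i \times n_i} matrix \eqn{R_i(\rho)} for a cluster
#' observed at the given times. Lags are computed from the recorded time
#' values, not row positions, so a subject missing an intermediate visit
#' contributes the correct larger-lag entries.
#'
#' @param wc A [working_correlation()] with `rho` set (unless
#'   independence).
#' @param times Strictly increasing integer visit times.
#' @return A symmetric unit-diagonal correlation matrix. Non-positive-
#'   definite realizations (possible for unstructured moment estimates)
#'   are ridge-repaired with a warning.
#' @export
build_correlation <- function(wc, times) {
  stopifnot(inherits(wc, "working_correlation"))
  times <- as.integer(times)
  if (length(times) == 0L || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing integers", call. = FALSE)
  }
  n <- length(times)
  if (wc$structure == "independence") return(diag(n))
  if (is.null(wc$rho)) {
    stop("rho has not been set for structure ", wc$structure, call. = FALSE)
  }
  check_rho(wc$structure, wc$rho, wc$m)
  lag <- abs(outer(times, times, "-"))
  R <- switch(wc$structure,
    exchangeable = {
      R <- matrix(wc$rho, n, n); diag(R) <- 1; R
    },
    ar1 = wc$rho^lag,
    m_dependent = {
      R <- diag(n)
      for (d in seq_len(wc$m)) R[lag == d] <- wc$rho[d]
      R
    },
    unstructured = {
      if (max(times) > nrow(wc$rho)) {
        stop("unstructured rho does not cover observed time ",
             max(times), call. = FALSE)
      }
      R <- wc$rho[times, times, drop = FALSE]
      diag(R) <- 1
      R
    })
  repair_pd(R, label = wc$structure)
}

# Smallest-eigenvalue ridge repair to keep realized correlation /
# weight matrices invertible.
repair_pd <- function(M, min_eig = 1e-6, label = "matrix") {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lo <- min(ev)
  if (lo < min_eig) {
    warning(sprintf("%s matrix not positive definite (min eigenvalue %.2e); ridge-repaired",
                    label, lo), call. = FALSE)
    M <- M + diag(min_eig - lo, nrow(M))
  }
  M
}

#' Pearson residuals for binary responses
#'
#' \eqn{(y - \pi)/\sqrt{\pi(1-\pi)}}, with dispersion \eqn{\phi}
#' fixed at 1.
#'
#' @param y Binary responses.
#' @param pi Fitted probabilities; boundary values are clamped with a
#'   warning.
#' @return Residual vector.
#' @export
pearson_residuals <- function(y, pi) {
  check_binary(y, length(pi))
  if (any(pi <= 0 | pi >= 1)) {
    warning("fitted probabilities at the boundary were clamped",
            call. = FALSE)
    pi <- clamp_prob(pi)
  }
  (y - pi) / sqrt(pi * (1 - pi))
}

#' Moment estimation of the association parameters
#'
#' Liang–Zeger moment estimators from the current Pearson residuals.
#' Denominators are the number of contributing pairs (no small-sample
#' correction); the dispersion is fixed at 1. Lags are measured in time
#' units.
#'
#' @param residuals List of per-cluster Pearson residual vectors.
#' @param times List of per-cluster strictly increasing integer times.
#' @param structure Correlation structure name.
#' @param m Band width for `"m_dependent"`.
#' @param n_times Total number of time points (needed to shape the
#'   unstructured estimate); defaults to the maximum observed time.
#' @return The estimated `rho` in the shape [working_correlation()]
#'   expects: scalar, length-m vector, or time-indexed matrix. For
#'   `"independence"`, `NULL`.
#' @export
estimate_rho <- function(residuals, times, structure, m = 1L,
                         n_times = NULL) {
  stopifnot(is.list(residuals), is.list(times),
            length(residuals) == length(times))
  if (structure == "independence") return(NULL)
  sizes <- lengths(residuals)
  if (all(sizes <= 1L)) {
    stop("no within-cluster pairs: all clusters have size 1", call. = FALSE)
  }
  keep <- sizes >= 2L
  residuals <- residuals[keep]
  times <- times[keep]

  pair_mean <- function(target_lag) {
    s <- 0; npair <- 0L
    for (k in seq_along(residuals)) {
      e <- residuals[[k]]; tt <- times[[k]]
      lag <- abs(outer(tt, tt, "-"))
      idx <- which(lag == target_lag & upper.tri(lag), arr.ind = TRUE)
      if (nrow(idx)) {
        s <- s + sum(e[idx[, 1]] * e[idx[, 2]])
        npair <- npair + nrow(idx)
      }
    }
    if (npair == 0L) {
      stop("no residual pairs observed at lag ", target_lag, call. = FALSE)
    }
    s / npair
  }

  switch(structure,
    exchangeable = {
      s <- 0; npair <- 0L
      for (k in seq_along(residuals)) {
        e <- residuals[[k]]
        s <- s + (sum(e)^2 - sum(e^2)) / 2
        npair <- npair + length(e) * (length(e) - 1L) / 2L
      }
      s / npair
    },
    ar1 = pair_mean(1L),
    m_dependent = vapply(seq_len(m), pair_mean, numeric(1)),
    unstructured = {
      if (is.null(n_times)) n_times <- max(unlist(times))
      R <- diag(n_times)
      S <- matrix(0, n_times, n_times)
      Np <- matrix(0L, n_times, n_times)
      for (k in seq_along(residuals)) {
        e <- residuals[[k]]; tt <- times[[k]]
        for (a in seq_along(tt)) {
          for (b in seq_along(tt)) {
            if (a < b) {
              S[tt[a], tt[b]] <- S[tt[a], tt[b]] + e[a] * e[b]
              Np[tt[a], tt[b]] <- Np[tt[a], tt[b]] + 1L
            }
          }
        }
      }
      miss <- which(Np == 0L & upper.tri(Np), arr.ind = TRUE)
      if (nrow(miss)) {
        stop(sprintf("no residual pairs observed for time pair (%d, %d)",
                     miss[1, 1], miss[1, 2]), call. = FALSE)
      }
      up <- upper.tri(R)
      R[up] <- (S / pmax(Np, 1L))[up]
      R[lower.tri(R)] <- t(R)[lower.tri(R)]
      R
    },
    stop("unknown structure: ", structure, call. = FALSE))
}
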