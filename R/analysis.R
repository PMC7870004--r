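#' Collapse morbidity questionnaire scores to a binary outcome
#'
#' The cohort instrument is a 19-item yes/no questionnaire; the total
#' score counts the "yes" answers. Any illness in the month (score of 1
#' or more) is coded 1; a score of 0 (no illness) is coded 0.
#'
#' @param scores Integer vector of total scores in 0..19.
#' @return Integer 0/1 vector.
#' @export
binarize_morbidity <- function(scores) {
  if (anyNA(scores) || any(scores != floor(scores)) ||
      any(scores < 0 | scores > 19)) {
    stop("scores must be integers in [0, 19]", call. = FALSE)
  }
  as.integer(scores >= 1)
}

required_columns <- c("subject_id", "time", "y", "bv", "hiv", "male",
                      "breastfed", "weight")

#' Validate a long-format morbidity dataset
#'
#' One row per (subject, visit month). Checks column presence, strictly
#' increasing times within subject, binary outcome and exposures,
#' within-subject constancy of baseline covariates, and positive finite
#' weight.
#'
#' @param data A data.frame with columns `subject_id`, `time`, `y`,
#'   `bv`, `hiv`, `male`, `breastfed`, `weight`.
#' @return The validated data.frame, invisibly classed
#'   `"morbidity_data"`.
#' @export
validate_morbidity_data <- function(data) {
  miss <- setdiff(required_columns, names(data))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data[required_columns])) {
    stop("data contain missing values; run complete_case_filter() first",
         call. = FALSE)
  }
  if (any(duplicated(data[c("subject_id", "time")]))) {
    stop("duplicate (subject_id, time) rows", call. = FALSE)
  }
  bad_t <- vapply(split(data$time, data$subject_id),
                  function(tt) any(diff(sort(tt)) <= 0) || any(tt < 1),
                  logical(1))
  if (any(bad_t)) stop("times must be distinct positive integers within subject",
                       call. = FALSE)
  for (v in c("y", "bv", "hiv", "male", "breastfed")) {
    if (!all(data[[v]] %in% c(0, 1))) {
      stop("column `", v, "` must be 0/1", call. = FALSE)
    }
  }
  for (v in c("bv", "hiv", "male", "breastfed")) {
    const <- vapply(split(data[[v]], data$subject_id),
                    function(z) length(unique(z)) == 1L, logical(1))
    if (!all(const)) stop("column `", v, "` must be constant within subject",
                          call. = FALSE)
  }
  if (any(!is.finite(data$weight) | data$weight <= 0)) {
    stop("weight must be finite and positive", call. = FALSE)
  }
  class(data) <- unique(c("morbidity_data", class(data)))
  invisible(data)
}

#' Complete-case filter (MCAR handling)
#'
#' Drops rows with any missing required field and subjects left with no
#' rows, then reports the counts. Under missingness completely at
#' random, complete-case GEE remains consistent as long as the mean
#' model is correct.
#'
#' @param data Long-format data.frame, possibly with `NA` fields.
#' @return The filtered data.frame with attributes `n_rows_dropped` and
#'   `n_subjects_dropped`.
#' @export
complete_case_filter <- function(data) {
  miss <- setdiff(required_columns, names(data))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(data[required_columns])
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no complete rows remain", call. = FALSE)
  subj_before <- unique(data$subject_id)
  subj_after <- unique(out$subject_id)
  attr(out, "n_rows_dropped") <- sum(!keep)
  attr(out, "n_subjects_dropped") <- length(subj_before) - length(subj_after)
  message(sprintf("complete-case filter: dropped %d of %d rows (%d subjects removed entirely)",
                  sum(!keep), nrow(data), attr(out, "n_subjects_dropped")))
  rownames(out) <- NULL
  out
}

#' Build the regression design matrix
#'
#' Columns, in reporting order: intercept, breastfed, bv, bv_time
#' (the BV-by-month interaction), hiv, male, time (integer month), and
#' weight (kg, the month-specific value). Time enters linearly as the
#' month index.
#'
#' @param data A validated long-format dataset (see
#'   [validate_morbidity_data()]).
#' @return A numeric matrix with 8 named columns, rows aligned with
#'   `data`.
#' @export
build_design <- function(data) {
  data <- validate_morbidity_data(data)
  X <- cbind(intercept = 1,
             breastfed = data$breastfed,
             bv = data$bv,
             bv_time = data$bv * data$time,
             hiv = data$hiv,
             male = data$male,
             time = data$time,
             weight = data$weight)
  const <- apply(X[, -1, drop = FALSE], 2, function(col) {
    length(unique(col)) == 1L
  })
  if (any(const)) {
    warning("constant non-intercept column(s): ",
            paste(names(const)[const], collapse = ", "),
            "; design may be rank deficient", call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}

#' Fit both marginal models under all working correlation structures
#'
#' Runs the full two-model comparison: the standard GEE (logit link,
#' alpha = 1) and the skewed-logit GEE (alpha fixed at the supplied
#' first-stage estimate), each under the selected working correlation
#' structures.
#'
#' @param data Validated long-format dataset.
#' @param alpha Skewness for the skewed-logit arm, typically
#'   `fit_skew_glm(...)$alpha_hat`.
#' @param structures Character vector of structures to fit (default all
#'   five).
#' @param m Band width for `"m_dependent"`.
#' @param control A [gee_control()].
#' @return A list of class `"gee_fit_set"`: `fits` is a nested list
#'   `fits[[model]][[structure]]` with models `"gee"` and `"slgee"`;
#'   `alpha` records the skewed-arm skewness.
#' @export
fit_all <- function(data, alpha,
                    structures = c("independence", "exchangeable", "ar1",
                                   "m_dependent", "unstructured"),
                    m = 1L, control = gee_control()) {
  data <- validate_morbidity_data(data)
  structures <- match.arg(structures, several.ok = TRUE)
  X <- build_design(data)
  links <- list(gee = link_spec("logit"),
                slgee = link_spec("skewed_logit", alpha = alpha))
  fits <- lapply(links, function(lk) {
    out <- lapply(structures, function(s) {
      gee_fit(X, data$y, id = data$subject_id, times = data$time,
              link = lk, wc = working_correlation(s, m = m),
              control = control)
    })
    stats::setNames(out, structures)
  })
  structure(list(fits = fits, alpha = alpha, structures = structures),
            class = "gee_fit_set")
}

#' @export
print.gee_fit_set <- function(x, ...) {
  cat(sprintf("GEE fit set: 2 models x %d structures (slgee alpha = %.3f)\n",
              length(x$structures), x$alpha))
  for (mdl in names(x$fits)) {
    for (s in names(x$fits[[mdl]])) {
      f <- x$fits[[mdl]][[s]]
      cat(sprintf("  %-6s %-13s iterations %3d  %s\n", mdl, s, f$n_iter,
                  if (f$converged) "converged" else "NOT converged"))
    }
  }
  invisible(x)
}

#' Model-based vs sandwich variance ratio
#'
#' \eqn{V.R = (\text{robust SE} / \text{model SE})^2}, the working-
#' correlation adequacy diagnostic: values near 1 indicate the assumed
#' structure matches the data.
#'
#' @param model_se,robust_se Positive standard errors (vectorized).
#' @return The squared ratio.
#' @export
variance_ratio <- function(model_se, robust_se) {
  if (any(model_se <= 0) || any(robust_se <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  (robust_se / model_se)^2
}

#' Variance-ratio table across a fit set
#'
#' @param fit_set A [fit_all()] result.
#' @return Long data.frame with columns `model`, `structure`, `term`,
#'   `estimate`, `variance_ratio`.
#' @export
variance_ratio_table <- function(fit_set) {
  stopifnot(inherits(fit_set, "gee_fit_set"))
  rows <- list()
  for (mdl in names(fit_set$fits)) {
    for (s in names(fit_set$fits[[mdl]])) {
      f <- fit_set$fits[[mdl]][[s]]
      rows[[paste(mdl, s)]] <- data.frame(
        model = mdl, structure = s, term = names(f$beta),
        estimate = unname(f$beta),
        variance_ratio = variance_ratio(unname(f$se_model),
                                        unname(f$se_robust)),
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Time-varying exposure odds ratios
#'
#' The month-specific odds ratio of the BV exposure implied by a model
#' with a BV-by-time interaction:
#' \eqn{\exp(\beta_{BV} + \beta_{int} \cdot t)} at each month `t`.
#'
#' @param beta_bv Main-effect coefficient of the exposure.
#' @param beta_interaction Exposure-by-month interaction coefficient.
#' @param months Positive integer months (default 1:6).
#' @return Named numeric vector of odds ratios.
#' @export
bv_time_effects <- function(beta_bv, beta_interaction, months = 1:6) {
  if (any(months < 1) || any(months != floor(months))) {
    stop("months must be positive integers", call. = FALSE)
  }
  stats::setNames(exp(beta_bv + beta_interaction * months),
                  paste0("month", months))
}

#' Monthly morbidity frequencies by exposure group
#'
#' For each month: the number and percentage of infants with any
#' morbidity (`y = 1`), within the BV-present group, the BV-absent
#' group, and overall. Percentages are rounded to integers.
#'
#' @param data Validated long-format dataset with binary `y`.
#' @return A data.frame with one row per month and columns
#'   `time`, `n_present`, `ill_present`, `pct_present`, `n_absent`,
#'   `ill_absent`, `pct_absent`, `n_total`, `ill_total`, `pct_total`.
#' @export
morbidity_frequency_table <- function(data) {
  data <- validate_morbidity_data(data)
  months <- sort(unique(data$time))
  rows <- lapply(months, function(t) {
    d <- data[data$time == t, ]
    grp <- function(sel) {
      n <- sum(sel); ill <- sum(d$y[sel])
      if (n == 0L) {
        warning("empty group at month ", t, call. = FALSE)
        c(0, 0, 0)
      } else c(n, ill, round(100 * ill / n))
    }
    p <- grp(d$bv == 1); a <- grp(d$bv == 0); tot <- grp(rep(TRUE, nrow(d)))
    data.frame(time = t,
               n_present = p[1], ill_present = p[2], pct_present = p[3],
               n_absent = a[1], ill_absent = a[2], pct_absent = a[3],
               n_total = tot[1], ill_total = tot[2], pct_total = tot[3],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Baseline cohort descriptives
#'
#' Subject-level counts and integer percentages of the binary baseline
#' covariates (BV, HIV, male, breastfed), computed from each subject's
#' first row.
#'
#' @param data Validated long-format dataset.
#' @return Data.frame with columns `covariate`, `n_positive`,
#'   `n_subjects`, `pct`.
#' @export
cohort_descriptives <- function(data) {
  data <- validate_morbidity_data(data)
  first <- data[!duplicated(data$subject_id), ]
  n <- nrow(first)
  vars <- c("bv", "hiv", "male", "breastfed")
  data.frame(covariate = vars,
             n_positive = vapply(vars, function(v) sum(first[[v]]),
                                 numeric(1)),
             n_subjects = n,
             pct = vapply(vars, function(v) round(100 * mean(first[[v]])),
                          numeric(1)),
             row.names = NULL)
}

#' Read / write the long-format morbidity CSV
#'
#' The on-disk format is a comma-separated UTF-8 file with header
#' `subject_id,time,y,bv,hiv,male,breastfed,weight`; empty fields are
#' missing values. A variant with a raw `score` column (0..19) instead
#' of `y` is accepted and binarized on read.
#'
#' @param path File path.
#' @return `read_morbidity_csv()`: a data.frame (not yet filtered or
#'   validated, so missing values survive the round trip).
#' @export
read_morbidity_csv <- function(path) {
  data <- utils::read.csv(path, na.strings = "")
  if (!"y" %in% names(data) && "score" %in% names(data)) {
    ok <- !is.na(data$score)
    data$y <- NA_integer_
    data$y[ok] <- binarize_morbidity(data$score[ok])
    data$score <- NULL
  }
  miss <- setdiff(required_columns, names(data))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data[required_columns]
}

#' @rdname read_morbidity_csv
#' @param data Long-format data.frame.
#' @export
write_morbidity_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}
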