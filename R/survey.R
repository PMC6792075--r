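# Survey-weighted estimation for stratified cluster designs: the weighted
# (ratio) mean, its Taylor-linearized variance from with-replacement PSU
# totals within strata, t-based confidence limits on PSU-minus-strata
# degrees of freedom, and the CI non-overlap decision rule.

#' Survey-weighted mean
#'
#' @param values Numeric vector.
#' @param weights Positive weights of the same length.
#' @return `sum(w * y) / sum(w)`.
#' @export
weighted_mean <- function(values, weights) {
  if (!length(values)) stop("weighted_mean: empty input", call. = FALSE)
  if (length(values) != length(weights)) {
    stop("weighted_mean: values and weights differ in length", call. = FALSE)
  }
  if (any(!is.finite(weights) | weights <= 0)) {
    stop("weighted_mean: weights must be finite and > 0", call. = FALSE)
  }
  sum(weights * values) / sum(weights)
}

#' Construct a survey design
#'
#' @param stratum,psu Design labels per observation.
#' @param weight Positive survey weight per observation.
#' @return Object of class `survey_design` (a data frame).
#' @export
survey_design <- function(stratum, psu, weight) {
  stratum <- as.character(stratum); psu <- as.character(psu)
  weight <- as.numeric(weight)
  n <- length(stratum)
  if (length(psu) != n || length(weight) != n) {
    stop("survey_design: stratum, psu, weight must have equal length",
         call. = FALSE)
  }
  if (any(is.na(stratum) | !nzchar(stratum)) ||
      any(is.na(psu) | !nzchar(psu))) {
    stop("survey_design: empty stratum/psu label", call. = FALSE)
  }
  if (any(!is.finite(weight) | weight <= 0)) {
    stop("survey_design: weights must be finite and > 0", call. = FALSE)
  }
  structure(data.frame(stratum = stratum, psu = psu, weight = weight,
                       stringsAsFactors = FALSE),
            class = c("survey_design", "data.frame"))
}

#' Survey-weighted mean with Taylor-linearized uncertainty
#'
#' Estimates the population mean as the ratio `sum(w*y)/sum(w)` and its
#' variance by Taylor linearization: with `z = w * (y - mean)` summed to
#' PSU totals `z_hi`, the variance is
#' `sum_h n_h/(n_h - 1) * sum_i (z_hi - zbar_h)^2 / (sum w)^2`,
#' the first-stage with-replacement approximation for stratified cluster
#' samples. Degrees of freedom are the number of PSUs minus the number of
#' strata; limits use the two-sided t quantile.
#'
#' @param values Numeric vector, one observation per sampled person.
#' @param design A [survey_design()] aligned with `values`.
#' @param level Confidence level (default 0.99, the LCL99/UCL99 of the
#'   decision rule).
#' @param collapse_single_psu Merge single-PSU strata into an adjacent
#'   stratum instead of erroring (off by default).
#' @return Object of class `survey_estimate`: mean, se, lcl, ucl, df,
#'   level, n.
#' @export
survey_estimate <- function(values, design, level = 0.99,
                            collapse_single_psu = FALSE) {
  stopifnot(inherits(design, "survey_design"))
  if (length(values) != nrow(design)) {
    stop("survey_estimate: values and design differ in length",
         call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  stratum <- design$stratum; psu <- design$psu; w <- design$weight

  npsu_by_stratum <- tapply(psu, stratum, function(p) length(unique(p)))
  if (any(npsu_by_stratum < 2)) {
    if (!collapse_single_psu) {
      stop("survey_estimate: stratum with a single PSU (",
           paste(names(npsu_by_stratum)[npsu_by_stratum < 2], collapse = ", "),
           "); set collapse_single_psu = TRUE to merge", call. = FALSE)
    }
    env <- environment()
    stratum <- .collapse_single_psu_env(stratum, psu, env)
    psu <- env$psu
  }

  m <- weighted_mean(values, w)
  z <- w * (values - m)
  key <- paste(stratum, psu, sep = "\r")
  z_psu <- tapply(z, key, sum)
  h_psu <- vapply(strsplit(names(z_psu), "\r", fixed = TRUE), `[[`, "", 1L)
  var_num <- 0
  for (h in unique(h_psu)) {
    zh <- z_psu[h_psu == h]
    nh <- length(zh)
    var_num <- var_num + nh / (nh - 1) * sum((zh - mean(zh))^2)
  }
  se <- sqrt(var_num) / sum(w)
  df <- length(z_psu) - length(unique(h_psu))
  tq <- stats::qt(1 - (1 - level) / 2, df)
  half <- tq * se
  structure(list(mean = m, se = se, lcl = m - half, ucl = m + half,
                 df = df, level = level, n = length(values)),
            class = "survey_estimate")
}

# environment-passing wrapper so the collapse can also rename PSUs
.collapse_single_psu_env <- function(stratum, psu, env) {
  repeat {
    tab <- tapply(psu, stratum, function(p) length(unique(p)))
    singles <- names(tab)[tab < 2]
    if (!length(singles)) break
    if (length(tab) < 2) {
      stop("survey_estimate: cannot collapse a lone single-PSU stratum",
           call. = FALSE)
    }
    lev <- sort(names(tab))
    s <- singles[1]
    i <- match(s, lev)
    target <- if (i < length(lev)) lev[i + 1] else lev[i - 1]
    psu[stratum == s] <- paste0(s, ".", psu[stratum == s])
    stratum[stratum == s] <- target
  }
  env$psu <- psu
  stratum
}

#' @export
print.survey_estimate <- function(x, ...) {
  cat(sprintf("mean %.4g ± %.3g  [%.4g, %.4g]  (df %d, %g%% CI, n %d)\n",
              x$mean, x$se, x$lcl, x$ucl, x$df, 100 * x$level, x$n))
  invisible(x)
}

#' Confidence-interval non-overlap decision rule
#'
#' Two estimates differ meaningfully when their confidence intervals do not
#' overlap. Intervals are closed: a shared endpoint counts as overlap.
#'
#' @param a,b [survey_estimate()] objects at the same confidence level.
#' @return `TRUE` iff the intervals are disjoint.
#' @export
meaningful_difference <- function(a, b) {
  stopifnot(inherits(a, "survey_estimate"), inherits(b, "survey_estimate"))
  if (!isTRUE(all.equal(a$level, b$level))) {
    stop("meaningful_difference: estimates are at different levels",
         call. = FALSE)
  }
  a$ucl < b$lcl || b$ucl < a$lcl
}
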