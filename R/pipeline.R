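# One-call pipeline: scenarios -> per-person modified totals -> HEI-2010 ->
# survey estimates -> the five report tables (nutrients to limit, nutrients
# of public-health concern, shortfall nutrients, enrichment nutrients, HEI)
# plus a pairwise meaningfulness matrix per measure and a run log.

.TABLE_MEASURES <- list(
  nutrients_to_limit = c("energy", "total_fat", "saturated_fat",
                         "added_sugar", "sodium"),
  public_health_concern = c("dietary_fiber", "calcium", "vitamin_d",
                            "potassium"),
  shortfall = c("folate_dfe", "iron", "magnesium", "vitamin_a_rae",
                "vitamin_e_at", "vitamin_c"),
  enrichment = c("thiamin", "riboflavin", "niacin"),
  hei = "hei2010_total"
)

#' Configure a pipeline run
#'
#' @param data List of [person_day()] objects, or `NULL` to generate a
#'   synthetic population from `population`.
#' @param population A [population_config()] used when `data` is `NULL`.
#' @param scenarios Named list mapping scenario label to a
#'   [sandwich_profile()], a built-in profile name, or `NULL` for the
#'   pass-through baseline. Default: "0" (baseline) through "5", the six
#'   packaged scenarios.
#' @param policy A [substitution_policy()].
#' @param level Confidence level for all estimates (default 0.99).
#' @param collapse_single_psu Passed to [survey_estimate()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(data = NULL, population = NULL, scenarios = NULL,
                       policy = substitution_policy(), level = 0.99,
                       collapse_single_psu = FALSE) {
  if (is.null(data) && is.null(population)) {
    stop("run_config: supply data or a population config", call. = FALSE)
  }
  if (is.null(scenarios)) {
    profs <- load_builtin_profiles()
    scenarios <- c(list("0" = NULL),
                   stats::setNames(profs[paste("Sandwich", 1:5)],
                                   as.character(1:5)))
  }
  if (!length(scenarios) || is.null(names(scenarios)) ||
      any(!nzchar(names(scenarios)))) {
    stop("run_config: scenarios must be a non-empty named list",
         call. = FALSE)
  }
  # resolve profile names and fail before any computation
  builtin <- NULL
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    if (is.null(sc)) next
    if (is.character(sc)) {
      if (is.null(builtin)) builtin <- load_builtin_profiles()
      if (!sc %in% names(builtin)) {
        stop("run_config: unknown profile name in scenario ", nm, ": ", sc,
             call. = FALSE)
      }
      scenarios[[nm]] <- builtin[[sc]]
    } else if (!inherits(sc, "sandwich_profile")) {
      stop("run_config: scenario ", nm,
           " is neither NULL, a profile name, nor a sandwich_profile",
           call. = FALSE)
    }
  }
  stopifnot(inherits(policy, "substitution_policy"))
  structure(list(data = data, population = population,
                 scenarios = scenarios, policy = policy, level = level,
                 collapse_single_psu = collapse_single_psu),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognised keys: `recall_csv` (canonical recall table path),
#' `scenarios` (map label -> built-in profile name or `~` for baseline),
#' `policy: {sandwich_categories: [...], sandwich_codes: [...]}`,
#' `level`, `collapse_single_psu`.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  data <- if (!is.null(y$recall_csv)) read_recall_table(y$recall_csv) else NULL
  policy <- if (!is.null(y$policy)) {
    do.call(substitution_policy, y$policy)
  } else {
    substitution_policy()
  }
  run_config(data = data,
             scenarios = y$scenarios,
             policy = policy,
             level = if (is.null(y$level)) 0.99 else y$level,
             collapse_single_psu = isTRUE(y$collapse_single_psu))
}

#' Run the substitution pipeline
#'
#' For every scenario: substitute the scenario's profile into each
#' person-day, score the modified totals with the HEI-2010, and estimate
#' the survey-weighted mean, Taylor-linearized SE and confidence limits of
#' every reported measure. Emits the five report tables, a pairwise CI
#' non-overlap (meaningfulness) matrix per measure, per-scenario totals,
#' and a text log.
#'
#' @param config A [run_config()].
#' @return Object of class `dietshift_run`: list with `tables` (named list
#'   of data frames: scenario, mean, se, lcl99, ucl99 per measure),
#'   `meaningful` (named list of logical scenario-by-scenario matrices),
#'   `estimates`, `totals`, `n_replaced`, and `log` (character lines).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  data <- config$data
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  if (is.null(data)) {
    data <- gen_population(config$population)
    note("synthetic population generated: n=%d, seed=%d",
         length(data), config$population$seed)
  }
  note("n person-days: %d", length(data))
  note("policy: categories [%s], codes [%s], per-item fixed-size replacement",
       paste(config$policy$sandwich_categories, collapse = ", "),
       paste(config$policy$sandwich_codes, collapse = ", "))
  note("confidence level: %g; single-PSU collapse: %s", config$level,
       config$collapse_single_psu)

  design <- survey_design(
    vapply(data, `[[`, "", "stratum"),
    vapply(data, `[[`, "", "psu"),
    vapply(data, `[[`, 0, "weight"))

  sc_names <- names(config$scenarios)
  totals <- list(); n_rep <- list()
  measures <- unique(unlist(.TABLE_MEASURES))
  est <- list()
  for (nm in sc_names) {
    res <- withCallingHandlers(
      apply_scenario(data, config$scenarios[[nm]], config$policy),
      warning = function(w) {
        note("scenario %s: %s", nm, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    tot <- res$modified
    tot$hei2010_total <- .hei_total_rows(tot)
    totals[[nm]] <- tot
    n_rep[[nm]] <- res$n_replaced
    note("scenario %s: %d sandwich item(s) replaced across %d person-day(s)",
         nm, sum(res$n_replaced), sum(res$n_replaced > 0))
    est[[nm]] <- lapply(stats::setNames(measures, measures), function(m) {
      survey_estimate(tot[[m]], design, level = config$level,
                      collapse_single_psu = config$collapse_single_psu)
    })
  }

  tables <- lapply(.TABLE_MEASURES, function(ms) {
    do.call(rbind, lapply(ms, function(m) {
      do.call(rbind, lapply(sc_names, function(nm) {
        e <- est[[nm]][[m]]
        data.frame(measure = m, scenario = nm, mean = e$mean, se = e$se,
                   lcl99 = e$lcl, ucl99 = e$ucl, stringsAsFactors = FALSE)
      }))
    }))
  })

  meaningful <- lapply(stats::setNames(measures, measures), function(m) {
    mm <- matrix(FALSE, length(sc_names), length(sc_names),
                 dimnames = list(sc_names, sc_names))
    for (a in sc_names) for (b in sc_names) {
      if (a != b) mm[a, b] <- meaningful_difference(est[[a]][[m]],
                                                    est[[b]][[m]])
    }
    mm
  })

  structure(list(tables = tables, meaningful = meaningful, estimates = est,
                 totals = totals, n_replaced = n_rep, log = log_lines),
            class = "dietshift_run")
}

#' Format an estimate table for display
#'
#' Renders `mean`/`se`/`lcl99`/`ucl99` columns as the report's
#' "Mean ± SE" and "LCL99, UCL99" strings. Means (and limits) of 100 or
#' more round to integers, smaller ones to one decimal; SEs keep three
#' significant digits. Display-only: CSV outputs carry full precision.
#'
#' @param estimates Data frame with columns mean, se, lcl99, ucl99 (other
#'   columns pass through); may be empty.
#' @return Data frame with `mean_se` and `ci99` character columns.
#' @export
format_table <- function(estimates) {
  stopifnot(is.data.frame(estimates))
  keep <- setdiff(names(estimates), c("mean", "se", "lcl99", "ucl99"))
  if (!nrow(estimates)) {
    out <- estimates[, keep, drop = FALSE]
    out$mean_se <- character(0); out$ci99 <- character(0)
    return(out)
  }
  fmt_m <- function(x) {
    ifelse(abs(x) >= 100, formatC(round(x), format = "d"),
           formatC(x, format = "f", digits = 1))
  }
  fmt_se <- function(x) vapply(x, function(v) format(signif(v, 3)), "")
  out <- estimates[, keep, drop = FALSE]
  out$mean_se <- paste0(fmt_m(estimates$mean), " ± ", fmt_se(estimates$se))
  out$ci99 <- paste0(fmt_m(estimates$lcl99), ", ", fmt_m(estimates$ucl99))
  out
}

#' @export
print.dietshift_run <- function(x, ...) {
  cat("<dietshift_run>", length(x$totals), "scenario(s)\n")
  for (ln in x$log) cat("  #", ln, "\n")
  cat("\nHEI-2010 total:\n")
  print(format_table(x$tables$hei), row.names = FALSE)
  invisible(x)
}
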