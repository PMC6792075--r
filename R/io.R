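# Readers and writers for the canonical interchange formats.
#
# Canonical recall format: CSV, one row per reported food item, columns
#   participant_id, stratum, psu, weight, food_code, amount
#   [day]             optional recall day; only one day is kept (default 1)
#   [wweia_category]  optional WWEIA category code
#   <20 nutrient columns named as in nutrient_names()>
#   [fg_<group> columns named fg_ + food_group_names()], optional;
#   missing food-group columns are filled with zero (with a warning) since
#   pattern-equivalent merges are often unavailable.
# SAS transport (.XPT), as distributed for NHANES, is supported read-only;
# variable names are lower-cased and then held to the same dictionary.

.FG_COLS <- function() paste0("fg_", .FOOD_GROUPS)

.required_recall_cols <- function() {
  c("participant_id", "stratum", "psu", "weight", "food_code", "amount",
    .NUTRIENTS)
}

#' Read a person-day dietary recall table
#'
#' Parses an item-level recall file into a list of [person_day()] objects,
#' one per participant-day. Multi-day files must carry a `day` column; only
#' the requested day (default Day 1, the in-person collection) is kept.
#'
#' @param path Path to the file.
#' @param format `"csv"` (canonical) or `"xpt"` (SAS transport, read-only).
#' @param day Recall day to keep when a `day` column is present.
#' @return List of [person_day()] objects, in order of first appearance.
#' @export
read_recall_table <- function(path, format = c("csv", "xpt"), day = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- switch(format,
    csv = utils::read.csv(path, check.names = FALSE),
    xpt = {
      x <- foreign::read.xport(path)
      names(x) <- tolower(names(x))
      x
    })
  recall_from_df(df, day = day)
}

#' Build person-days from an item-level data frame
#'
#' The data-frame backend of [read_recall_table()]; useful when recall rows
#' are assembled in memory.
#'
#' @param df Data frame in the canonical item-level layout.
#' @param day Recall day to keep when a `day` column is present.
#' @return List of [person_day()] objects.
#' @export
recall_from_df <- function(df, day = 1L) {
  missing_cols <- setdiff(.required_recall_cols(), names(df))
  if (length(missing_cols)) {
    stop("recall table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("day" %in% names(df)) df <- df[df$day == day, , drop = FALSE]
  if (!nrow(df)) stop("recall table has no rows for day ", day,
                      call. = FALSE)

  fg_cols <- .FG_COLS()
  missing_fg <- setdiff(fg_cols, names(df))
  if (length(missing_fg)) {
    warning("food-group column(s) absent, filled with 0: ",
            paste(missing_fg, collapse = ", "), call. = FALSE)
    for (cc in missing_fg) df[[cc]] <- 0
  }
  if (!("wweia_category" %in% names(df))) df$wweia_category <- NA_integer_

  bad_amt <- which(!is.finite(df$amount) | df$amount < 0)
  if (length(bad_amt)) {
    stop("negative or non-finite amount at row(s): ",
         paste(utils::head(bad_amt, 5L), collapse = ", "), call. = FALSE)
  }
  bad_w <- which(!is.finite(df$weight) | df$weight <= 0)
  if (length(bad_w)) {
    stop("non-positive survey weight at row(s): ",
         paste(utils::head(bad_w, 5L), collapse = ", "), call. = FALSE)
  }

  ids <- unique(df$participant_id)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    rows <- df[df$participant_id == ids[k], , drop = FALSE]
    items <- lapply(seq_len(nrow(rows)), function(i) {
      food_item(rows$food_code[i], rows$amount[i],
                nutrient_vector(unlist(rows[i, .NUTRIENTS])),
                foodgroup_vector(stats::setNames(unlist(rows[i, fg_cols]),
                                                 .FOOD_GROUPS)),
                wweia_category = rows$wweia_category[i])
    })
    out[[k]] <- person_day(ids[k], rows$stratum[1], rows$psu[1],
                           rows$weight[1], items)
  }
  out
}

#' Write person-days to the canonical item-level CSV
#'
#' @param days List of [person_day()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recall_table <- function(days, path) {
  rows <- lapply(days, function(d) {
    if (!length(d$items)) return(NULL)
    nut <- t(vapply(d$items, function(it) as.numeric(it$nutrients),
                    numeric(length(.NUTRIENTS))))
    grp <- t(vapply(d$items, function(it) as.numeric(it$groups),
                    numeric(length(.FOOD_GROUPS))))
    colnames(nut) <- .NUTRIENTS
    colnames(grp) <- .FG_COLS()
    data.frame(participant_id = d$participant_id, day = 1L,
               stratum = d$stratum, psu = d$psu, weight = d$weight,
               food_code = vapply(d$items, `[[`, "", "food_code"),
               wweia_category = vapply(d$items, `[[`, NA_integer_,
                                       "wweia_category"),
               amount = vapply(d$items, `[[`, 0, "amount"),
               nut, grp, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write result tables to a directory
#'
#' One CSV per table, full numeric precision (display rounding is
#' [format_table()]'s job). An empty table set writes nothing and warns.
#'
#' @param tables Named list of data frames.
#' @param path Output directory; created if needed.
#' @return Character vector of file paths written, invisibly.
#' @export
write_results <- function(tables, path) {
  stopifnot(is.list(tables))
  if (!length(tables)) {
    warning("no result tables to write", call. = FALSE)
    return(invisible(character()))
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("every result table must be named", call. = FALSE)
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path,
                              call. = FALSE)
  files <- character(length(tables))
  for (i in seq_along(tables)) {
    files[i] <- file.path(path, paste0(names(tables)[i], ".csv"))
    utils::write.csv(tables[[i]], files[i], row.names = FALSE)
  }
  invisible(files)
}
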