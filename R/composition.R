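#' Meal moment labels
#'
#' The closed set of eating-occasion labels under which food-record rows are
#' grouped. `BREAKFAST`, `LUNCH`, and `DINNER` are the three main meals;
#' `BEFORE_BREAKFAST` and `SNACK` intake falls outside them and is tracked as
#' "missed" protein in per-person summaries.
#'
#' @return Character vector of the five labels, in chronological order.
#' @export
meal_moments <- function() {
  c("BEFORE_BREAKFAST", "BREAKFAST", "LUNCH", "DINNER", "SNACK")
}

#' @rdname meal_moments
#' @export
main_moments <- function() c("BREAKFAST", "LUNCH", "DINNER")

# external schema shared by the CSV and JSON dialects
food_table_schema <- function() {
  c("id", "name", "protein_g_per_100g", "energy_kcal_per_100g", "origin",
    "digestibility_pct", eaa_cols())
}

#' Construct a validated food-composition table
#'
#' Builds the package's central food-table object from a data frame in the
#' external schema (digestibility as percent, AA columns in mg per g
#' protein). Foods whose AA columns are all absent are loaded with
#' `has_aa_data = FALSE` and an all-zero profile: they still contribute to
#' protein and energy totals but add nothing to EAA intake, and the scorer
#' reports the fraction of meal protein they account for.
#'
#' @param df Data frame with columns
#'   `id,name,protein_g_per_100g,energy_kcal_per_100g,origin,digestibility_pct`
#'   plus the ten AA columns `his,ile,leu,lys,met,cys,phe_tyr,thr,trp,val`.
#'   `energy_kcal_per_100g` is optional (default 0). Unknown columns are
#'   ignored with a warning.
#' @param source,version Metadata strings stored as attributes.
#' @return A tibble of class `mpqs_food_table`, rows sorted by `id`, with
#'   `digestibility` as a fraction in \[0, 1\] and a logical `has_aa_data`.
#' @export
food_table <- function(df, source = "unspecified", version = "0") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("id", "name", "protein_g_per_100g", "origin", "digestibility_pct")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("food table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), food_table_schema())
  if (length(extra)) {
    warning("ignoring unknown food table column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!"energy_kcal_per_100g" %in% names(df)) df$energy_kcal_per_100g <- 0
  df$energy_kcal_per_100g[is.na(df$energy_kcal_per_100g)] <- 0

  n <- nrow(df)
  if (n > 0L) {
    df$id <- as.character(df$id)
    df$name <- as.character(df$name)
    if (anyDuplicated(df$id)) {
      stop("duplicate food id(s): ",
           paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
           call. = FALSE)
    }
    for (i in seq_len(n)) {
      row_id <- df$id[i]
      check_nonneg(df$protein_g_per_100g[i], row_id, "protein_g_per_100g")
      check_nonneg(df$energy_kcal_per_100g[i], row_id, "energy_kcal_per_100g")
      d <- df$digestibility_pct[i]
      if (is.na(d) || !is.numeric(d) || d < 0 || d > 100) {
        stop(sprintf("food '%s': digestibility_pct must be in [0, 100], got %s",
                     row_id, format(d)), call. = FALSE)
      }
      if (!df$origin[i] %in% c("plant", "animal")) {
        stop(sprintf("food '%s': origin must be 'plant' or 'animal', got '%s'",
                     row_id, df$origin[i]), call. = FALSE)
      }
    }
  }

  aa <- matrix(NA_real_, nrow = n, ncol = 10L, dimnames = list(NULL, eaa_cols()))
  for (col in eaa_cols()) {
    if (col %in% names(df)) aa[, col] <- as.numeric(df[[col]])
  }
  has_aa <- if (n > 0L) rowSums(!is.na(aa)) > 0L else logical(0)
  aa[is.na(aa)] <- 0
  if (any(aa < 0)) {
    bad <- which(rowSums(aa < 0) > 0)[1]
    field <- eaa_cols()[which(aa[bad, ] < 0)[1]]
    stop(sprintf("food '%s': negative amino acid value in column '%s'",
                 df$id[bad], field), call. = FALSE)
  }

  out <- tibble::tibble(
    id = as.character(df$id),
    name = as.character(df$name),
    protein_g_per_100g = as.numeric(df$protein_g_per_100g),
    energy_kcal_per_100g = as.numeric(df$energy_kcal_per_100g),
    origin = as.character(df$origin),
    digestibility = as.numeric(df$digestibility_pct) / 100,
    has_aa_data = has_aa
  )
  out <- cbind(out, tibble::as_tibble(aa))
  out <- tibble::as_tibble(out)
  if (n > 0L) out <- out[order(out$id), , drop = FALSE]
  structure(out,
            class = c("mpqs_food_table", class(tibble::tibble())),
            source = source, version = version)
}

#' Load a food-composition table from CSV or JSON
#'
#' @param path File path. The CSV dialect is UTF-8, comma-separated, with the
#'   header `id,name,protein_g_per_100g,energy_kcal_per_100g,origin,`
#'   `digestibility_pct,his,ile,leu,lys,met,cys,phe_tyr,thr,trp,val`
#'   (AA columns in mg per g protein, digestibility in percent). The JSON
#'   dialect mirrors the schema: either a plain array of item objects or an
#'   object `{source, version, items}`.
#' @param dialect `"csv"` or `"json"`; inferred from the file extension by
#'   default.
#' @return An `mpqs_food_table`; see [food_table()].
#' @export
load_food_table <- function(path, dialect = c("auto", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "csv") {
    if (file.size(path) == 0L) {
      return(food_table(empty_food_df(), source = basename(path)))
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    food_table(df, source = basename(path))
  } else {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (is.data.frame(obj)) {
      food_table(obj, source = basename(path))
    } else if (is.list(obj) && !is.null(obj$items)) {
      items <- obj$items
      if (length(items) == 0L) items <- empty_food_df()
      food_table(items,
                 source = if (!is.null(obj$source)) obj$source else basename(path),
                 version = if (!is.null(obj$version)) obj$version else "0")
    } else if (is.list(obj) && length(obj) == 0L) {
      food_table(empty_food_df(), source = basename(path))
    } else {
      stop("unrecognized food table JSON structure in ", path, call. = FALSE)
    }
  }
}

empty_food_df <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(numeric(0)), length(food_table_schema())), food_table_schema()))
  df$id <- character(0); df$name <- character(0); df$origin <- character(0)
  df
}

#' Save a food-composition table
#'
#' Writes the external schema (digestibility back in percent, AA columns in
#' mg/g protein). Saving then loading reproduces all numeric fields to full
#' precision.
#'
#' @param table An `mpqs_food_table`.
#' @param path Output path.
#' @param dialect `"csv"` or `"json"`; inferred from extension by default.
#' @export
save_food_table <- function(table, path, dialect = c("auto", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- as.data.frame(table)
  df$digestibility_pct <- df$digestibility * 100
  # foods loaded without AA data keep empty AA cells, so the flag survives
  # a save/load round trip
  df[!df$has_aa_data, eaa_cols()] <- NA_real_
  df <- df[, food_table_schema(), drop = FALSE]
  if (dialect == "csv") {
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(
      list(source = attr(table, "source"), version = attr(table, "version"),
           items = df),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# resolve food ids to row indices; unknown ids are an error, never silent zero
food_lookup <- function(table, ids) {
  idx <- match(ids, table$id)
  if (anyNA(idx)) {
    stop("unknown food id(s): ",
         paste(unique(ids[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Load per-person food records
#'
#' @param path CSV with columns `person_id,day,meal_moment,food_id,mass_g`.
#'   `meal_moment` must come from [meal_moments()]; `day` is an integer
#'   starting at 1.
#' @return Tibble sorted deterministically by (person, day, moment, food id),
#'   with `meal_moment` as a factor over the closed label set.
#' @export
load_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("person_id", "day", "meal_moment", "food_id", "mass_g")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("records file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  as_records(df)
}

#' Coerce a data frame to validated food records
#'
#' @param df Data frame with columns `person_id,day,meal_moment,food_id,mass_g`.
#' @return Sorted, validated tibble (see [load_records()]).
#' @export
as_records <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$meal_moment), meal_moments())
  if (length(bad)) {
    stop("unknown meal moment(s): ", paste(bad, collapse = ", "),
         "; allowed values: ", paste(meal_moments(), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(df$day)) || any(df$day < 1) || any(df$day != round(df$day))) {
    stop("day must be an integer >= 1", call. = FALSE)
  }
  if (any(is.na(df$mass_g)) || any(df$mass_g < 0)) {
    stop("mass_g must be non-negative", call. = FALSE)
  }
  out <- tibble::tibble(
    person_id = as.character(df$person_id),
    day = as.integer(df$day),
    meal_moment = factor(df$meal_moment, levels = meal_moments()),
    food_id = as.character(df$food_id),
    mass_g = as.numeric(df$mass_g)
  )
  out[order(out$person_id, out$day, out$meal_moment, out$food_id), ,
      drop = FALSE]
}

#' Validate food records against a food table
#'
#' @param records Tibble from [load_records()] / [as_records()].
#' @param table An `mpqs_food_table`.
#' @return `records`, invisibly, if every `food_id` resolves.
#' @export
validate_records <- function(records, table) {
  food_lookup(table, unique(records$food_id))
  invisible(records)
}

#' Load person profiles
#'
#' @param path CSV with columns `person_id,body_weight_kg`.
#' @return Tibble with positive body weights and unique person ids.
#' @export
load_persons <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("person_id", "body_weight_kg")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("persons file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  as_persons(df)
}

#' @rdname load_persons
#' @param df Data frame with the persons schema.
#' @export
as_persons <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (any(is.na(df$body_weight_kg)) || any(df$body_weight_kg <= 0)) {
    stop("body_weight_kg must be positive for every person", call. = FALSE)
  }
  if (anyDuplicated(df$person_id)) {
    stop("duplicate person_id(s) in persons table", call. = FALSE)
  }
  out <- tibble::tibble(person_id = as.character(df$person_id),
                        body_weight_kg = as.numeric(df$body_weight_kg))
  out[order(out$person_id), , drop = FALSE]
}

check_nonneg <- function(x, row_id, field) {
  if (is.na(x) || !is.numeric(x) || x < 0) {
    stop(sprintf("food '%s': %s must be a non-negative number, got %s",
                 row_id, field, format(x)), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.mpqs_food_table <- function(x, ...) {
  cat(sprintf("<mpqs_food_table> %d foods (source: %s, version: %s)\n",
              nrow(x), attr(x, "source"), attr(x, "version")))
  NextMethod()
}
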