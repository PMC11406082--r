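#' Construct a meal intake
#'
#' A meal is a set of portions (food id + consumed mass in grams) eaten by
#' one person at one meal moment. Portions must resolve against a food table
#' at scoring time; an empty portion list is permitted and scores 0.
#'
#' @param portions Data frame with columns `food_id` and `mass_g`
#'   (non-negative grams).
#' @param person_id,day,meal_moment Optional metadata carried into results.
#' @return An object of class `mpqs_meal`.
#' @export
#' @examples
#' meal_intake(data.frame(food_id = "rice_white", mass_g = 180))
meal_intake <- function(portions = data.frame(food_id = character(0),
                                              mass_g = numeric(0)),
                        person_id = NA_character_, day = NA_integer_,
                        meal_moment = NA_character_) {
  portions <- as_portions(portions)
  if (!is.na(meal_moment) && !meal_moment %in% meal_moments()) {
    stop("unknown meal moment '", meal_moment, "'; allowed: ",
         paste(meal_moments(), collapse = ", "), call. = FALSE)
  }
  structure(list(portions = portions, person_id = person_id,
                 day = day, meal_moment = meal_moment),
            class = "mpqs_meal")
}

as_portions <- function(x) {
  if (inherits(x, "mpqs_meal")) return(x$portions)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c("food_id", "mass_g") %in% names(x))) {
    stop("portions need columns 'food_id' and 'mass_g'", call. = FALSE)
  }
  if (any(is.na(x$mass_g)) || any(x$mass_g < 0)) {
    stop("portion mass_g must be non-negative", call. = FALSE)
  }
  tibble::tibble(food_id = as.character(x$food_id),
                 mass_g = as.numeric(x$mass_g))
}

#' Digestibility-adjusted EAA intake of a meal
#'
#' For each EAA the absolute intake in mg is summed over the meal's foods:
#' `mass_g x protein_g_per_100g / 100 x aa_mg_per_g_protein x digestibility`.
#' Each food's intake is adjusted by that food's digestibility factor
#' *before* summation; the sum is carried at full precision (no per-food
#' rounding). Foods without AA data contribute zero.
#'
#' @param meal An `mpqs_meal` or a portions data frame.
#' @param table An `mpqs_food_table`.
#' @param apply_digestibility If `FALSE`, digestibility factors are replaced
#'   by 1 (unadjusted intake).
#' @return Named numeric vector, mg per EAA over [eaa_keys()].
#' @export
adjusted_eaa_intake <- function(meal, table, apply_digestibility = TRUE) {
  portions <- as_portions(meal)
  idx <- food_lookup(table, portions$food_id)
  if (length(idx) == 0L) return(aa_vector())
  protein_g <- portions$mass_g * table$protein_g_per_100g[idx] / 100
  dig <- if (apply_digestibility) table$digestibility[idx] else rep(1, length(idx))
  aa <- as.matrix(table[idx, eaa_cols(), drop = FALSE])
  out <- colSums(aa * (protein_g * dig))
  stats::setNames(as.numeric(out), eaa_keys())
}

#' Methionine-to-cysteine top-up
#'
#' Methionine can be unidirectionally converted into cysteine, so cysteine
#' intake is topped up with all methionine consumed above the methionine
#' requirement: `CYS' = CYS + max(0, MET - req_MET)`. Methionine itself and
#' every other entry are unchanged, and cysteine surplus never augments
#' methionine.
#'
#' @param intake Named EAA intake vector, mg.
#' @param req An `mpqs_requirements` or a named requirement vector (mg) with
#'   a positive `MET` entry.
#' @return Intake vector with `CYS` topped up.
#' @export
met_cys_topup <- function(intake, req) {
  intake <- as_aa_vector(intake)
  req_mg <- if (inherits(req, "mpqs_requirements")) req$mg else as_aa_vector(req)
  if (req_mg[["MET"]] <= 0) {
    stop("methionine requirement must be positive for the top-up", call. = FALSE)
  }
  intake[["CYS"]] <- intake[["CYS"]] + max(0, intake[["MET"]] - req_mg[["MET"]])
  intake
}

#' Score a meal: the MPQS
#'
#' The meal protein quality score is 100 times the minimum, over the ten
#' scored EAA entities, of digestibility-adjusted intake (after the Met-Cys
#' top-up) divided by the personalized per-meal requirement. A score of 0
#' means at least one EAA is completely missing from the meal; 100 means all
#' EAAs exactly reach the requirement; scores above 100 mean every EAA
#' exceeds it. The limiting EAA is the entity attaining the minimum; when
#' all EAAs exceed the requirement there is no limiting EAA (`"NONE"`).
#'
#' Coverage percentages and the score are kept at full precision in the
#' result; published-style integer rounding is applied only in printing
#' (see [print.mpqs_score()]). Methionine coverage is reported uncapped even
#' when its surplus is donated to cysteine: since the score is a minimum the
#' donation can never change the score, only non-limiting diagnostics.
#'
#' @param meal An `mpqs_meal` or portions data frame.
#' @param table An `mpqs_food_table`.
#' @param req An `mpqs_requirements` with scope `per_meal`.
#' @param apply_digestibility Apply per-food digestibility factors
#'   (default `TRUE`).
#' @return An object of class `mpqs_score`: list with `mpqs`,
#'   `mpqs_truncated`, `limiting_eaa` (`"NONE"` when all requirements are
#'   met), `limiting_ties` (all keys tied at the minimum), `coverage_pct`,
#'   `raw_intake_mg` (pre-digestibility), `digestible_intake_mg` (adjusted,
#'   pre-top-up), `adjusted_intake_mg` (post-top-up), `requirement`,
#'   `total_protein_g`, `plant_protein_g`, `animal_protein_g`,
#'   `energy_kcal`, `pct_protein_without_aa_data`, `empty`.
#' @export
#' @examples
#' fx <- table2_fixture()
#' res <- score_meal(fx$meal, fx$table, meal_requirements(70))
#' res$mpqs           # ~44.05
#' res$limiting_eaa   # "MET"
score_meal <- function(meal, table, req, apply_digestibility = TRUE) {
  if (!inherits(req, "mpqs_requirements")) {
    stop("req must be an mpqs_requirements object", call. = FALSE)
  }
  if (req$scope != "per_meal") {
    stop("score_meal needs a per_meal requirement set; use score_day for ",
         "per_day requirements", call. = FALSE)
  }
  score_intake(meal, table, req, apply_digestibility)
}

#' Score a whole day of meals
#'
#' The daily adaptation of the score: all portions of one person-day
#' (snacks included) are pooled and the identical minimum-coverage math is
#' applied against a per-day requirement set.
#'
#' @param meals List of `mpqs_meal` objects (or portion data frames) for one
#'   person and one day.
#' @param table An `mpqs_food_table`.
#' @param req An `mpqs_requirements` with scope `per_day`.
#' @param apply_digestibility Apply per-food digestibility factors.
#' @return An `mpqs_score` (see [score_meal()]).
#' @export
score_day <- function(meals, table, req, apply_digestibility = TRUE) {
  if (!inherits(req, "mpqs_requirements")) {
    stop("req must be an mpqs_requirements object", call. = FALSE)
  }
  if (req$scope != "per_day") {
    stop("score_day needs a per_day requirement set; see daily_requirements()",
         call. = FALSE)
  }
  if (inherits(meals, "mpqs_meal") || is.data.frame(meals)) meals <- list(meals)
  ids <- unique(stats::na.omit(vapply(
    meals, function(m) if (inherits(m, "mpqs_meal")) m$person_id else NA_character_,
    character(1))))
  days <- unique(stats::na.omit(vapply(
    meals, function(m) if (inherits(m, "mpqs_meal")) as.integer(m$day) else NA_integer_,
    integer(1))))
  if (length(ids) > 1L || length(days) > 1L) {
    stop("score_day pools meals of a single person-day; got persons [",
         paste(ids, collapse = ", "), "] days [",
         paste(days, collapse = ", "), "]", call. = FALSE)
  }
  pooled <- do.call(rbind, lapply(meals, as_portions))
  if (is.null(pooled)) pooled <- as_portions(data.frame(food_id = character(0),
                                                        mass_g = numeric(0)))
  score_intake(pooled, table, req, apply_digestibility)
}

# shared scoring core for per-meal and per-day scopes
score_intake <- function(meal, table, req, apply_digestibility) {
  portions <- as_portions(meal)
  idx <- food_lookup(table, portions$food_id)

  raw <- adjusted_eaa_intake(portions, table, apply_digestibility = FALSE)
  digestible <- if (apply_digestibility) {
    adjusted_eaa_intake(portions, table, apply_digestibility = TRUE)
  } else {
    raw
  }
  adjusted <- met_cys_topup(digestible, req)

  coverage <- 100 * adjusted / req$mg
  mpqs <- min(coverage)
  ties <- eaa_keys()[coverage == mpqs]
  limiting <- if (mpqs >= 100) "NONE" else ties[1]

  protein_g <- portions$mass_g * table$protein_g_per_100g[idx] / 100
  plant <- table$origin[idx] == "plant"
  no_aa <- !table$has_aa_data[idx]
  total_protein <- sum(protein_g)
  empty <- nrow(portions) == 0L

  structure(list(
    mpqs = mpqs,
    mpqs_truncated = min(mpqs, 100),
    limiting_eaa = limiting,
    limiting_ties = ties,
    coverage_pct = coverage,
    raw_intake_mg = raw,
    digestible_intake_mg = digestible,
    adjusted_intake_mg = adjusted,
    requirement = req,
    total_protein_g = total_protein,
    plant_protein_g = sum(protein_g[plant]),
    animal_protein_g = sum(protein_g[!plant]),
    energy_kcal = sum(portions$mass_g * table$energy_kcal_per_100g[idx] / 100),
    pct_protein_without_aa_data =
      if (total_protein > 0) 100 * sum(protein_g[no_aa]) / total_protein else 0,
    apply_digestibility = apply_digestibility,
    empty = empty,
    person_id = if (inherits(meal, "mpqs_meal")) meal$person_id else NA_character_,
    day = if (inherits(meal, "mpqs_meal")) meal$day else NA_integer_,
    meal_moment = if (inherits(meal, "mpqs_meal")) meal$meal_moment else NA_character_
  ), class = "mpqs_score")
}

#' Print an MPQS result
#'
#' Coverage percentages and the score are shown rounded to integers, the
#' style used in published score tables; the underlying object keeps full
#' precision.
#'
#' @param x An `mpqs_score`.
#' @param ... Ignored.
#' @export
print.mpqs_score <- function(x, ...) {
  cat(sprintf("MPQS: %.0f%s  limiting EAA: %s\n",
              round_half_up(x$mpqs),
              if (x$empty) " (empty meal)" else "",
              x$limiting_eaa))
  tab <- data.frame(
    adjusted_mg = round_half_up(x$adjusted_intake_mg),
    requirement_mg = round_half_up(x$requirement$mg),
    coverage_pct = round_half_up(x$coverage_pct)
  )
  print(tab)
  cat(sprintf("protein: %.1f g (plant %.1f g, animal %.1f g), %.0f kcal\n",
              x$total_protein_g, x$plant_protein_g, x$animal_protein_g,
              x$energy_kcal))
  if (x$pct_protein_without_aa_data > 0) {
    cat(sprintf("note: %.1f%% of meal protein lacks amino acid data\n",
                x$pct_protein_without_aa_data))
  }
  invisible(x)
}

# flat list view of a score, for JSON output and tabulation
score_as_list <- function(x) {
  list(
    mpqs = round_half_up(x$mpqs),
    mpqs_unrounded = x$mpqs,
    mpqs_truncated = round_half_up(x$mpqs_truncated),
    limiting_eaa = x$limiting_eaa,
    limiting_ties = x$limiting_ties,
    coverage_pct = as.list(round_half_up(x$coverage_pct)),
    adjusted_intake_mg = as.list(x$adjusted_intake_mg),
    raw_intake_mg = as.list(x$raw_intake_mg),
    requirement_mg = as.list(x$requirement$mg),
    requirement_scope = x$requirement$scope,
    protein_target_g = x$requirement$protein_target_g,
    total_protein_g = x$total_protein_g,
    plant_protein_g = x$plant_protein_g,
    animal_protein_g = x$animal_protein_g,
    energy_kcal = x$energy_kcal,
    pct_protein_without_aa_data = x$pct_protein_without_aa_data,
    digestibility_applied = x$apply_digestibility,
    empty = x$empty
  )
}
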