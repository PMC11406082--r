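#' Personalized per-meal EAA requirements
#'
#' Requirements follow from a protein-quantity target and an amino acid
#' reference pattern: for each EAA,
#' `requirement_mg = body_weight_kg * protein_target_g_per_kg * pattern_mg_per_g`.
#' The default target of 0.3 g protein per kg body weight per meal is the
#' amount sufficient to stimulate muscle protein synthesis in older adults;
#' with three main meals plus snacks it adds up to roughly 1.0-1.2 g/kg/d.
#'
#' @param body_weight_kg Positive body weight in kilograms.
#' @param pattern Reference pattern in mg EAA per g protein; defaults to
#'   [reference_pattern()].
#' @param protein_target_g_per_kg Protein target per meal, grams per kg body
#'   weight (default 0.3).
#' @param person_id Optional person identifier carried through to reports.
#' @return An object of class `mpqs_requirements`: list with `mg` (named
#'   vector over [eaa_keys()], all positive), `scope` (`"per_meal"` or
#'   `"per_day"`), `protein_target_g`, `body_weight_kg`, `person_id`.
#' @export
#' @examples
#' req <- meal_requirements(70)
#' req$mg[["MET"]]  # 336 mg
meal_requirements <- function(body_weight_kg,
                              pattern = reference_pattern(),
                              protein_target_g_per_kg = 0.3,
                              person_id = NA_character_) {
  new_requirements(body_weight_kg, pattern, protein_target_g_per_kg,
                   scope = "per_meal", person_id = person_id)
}

#' Personalized daily EAA requirements
#'
#' Same product form as [meal_requirements()] but scoped to a whole day, for
#' the daily adaptation of the score: cumulative daily intake is compared
#' against a daily protein target (commonly 0.8 or 1.2 g/kg/d) spread over
#' the reference pattern.
#'
#' @inheritParams meal_requirements
#' @param protein_target_g_per_kg_per_day Daily protein target in g/kg/d.
#'   Values outside 0.4-2.5 trigger a warning (they are outside the range
#'   used in adult recommendations) but are accepted.
#' @return An `mpqs_requirements` with scope `"per_day"`.
#' @export
#' @examples
#' daily_requirements(70, protein_target_g_per_kg_per_day = 1.2)
daily_requirements <- function(body_weight_kg,
                               pattern = reference_pattern(),
                               protein_target_g_per_kg_per_day = 1.2,
                               person_id = NA_character_) {
  if (is.na(protein_target_g_per_kg_per_day) ||
      protein_target_g_per_kg_per_day <= 0) {
    stop("daily protein target must be positive", call. = FALSE)
  }
  if (protein_target_g_per_kg_per_day < 0.4 ||
      protein_target_g_per_kg_per_day > 2.5) {
    warning("daily protein target ", protein_target_g_per_kg_per_day,
            " g/kg/d is outside the usual 0.4-2.5 range", call. = FALSE)
  }
  new_requirements(body_weight_kg, pattern, protein_target_g_per_kg_per_day,
                   scope = "per_day", person_id = person_id)
}

new_requirements <- function(body_weight_kg, pattern, target, scope, person_id) {
  if (length(body_weight_kg) != 1L || is.na(body_weight_kg) ||
      body_weight_kg <= 0) {
    stop("body_weight_kg must be a single positive number", call. = FALSE)
  }
  if (length(target) != 1L || is.na(target) || target <= 0) {
    stop("protein target must be a single positive number", call. = FALSE)
  }
  pattern <- validate_pattern(pattern)
  protein_target_g <- body_weight_kg * target
  mg <- pattern * protein_target_g
  structure(
    list(mg = mg, scope = scope, protein_target_g = protein_target_g,
         body_weight_kg = body_weight_kg, protein_target_g_per_kg = target,
         person_id = person_id),
    class = "mpqs_requirements"
  )
}

#' @export
print.mpqs_requirements <- function(x, ...) {
  cat(sprintf(
    "<mpqs_requirements> %s, %.3g kg body weight, protein target %.3g g\n",
    x$scope, x$body_weight_kg, x$protein_target_g))
  print(round(x$mg, 1))
  invisible(x)
}

#' Read a reference-pattern override from YAML or JSON
#'
#' The file maps amino acid keys (case-insensitive, from [eaa_keys()]) to
#' mg per g protein; keys omitted fall back to the built-in pattern. Intended
#' for e.g. leucine-enriched patterns proposed for older adults.
#'
#' @param path YAML or JSON file.
#' @return Named numeric pattern over [eaa_keys()].
#' @export
load_pattern <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(obj) && !is.numeric(obj)) {
    stop("pattern file must map amino acid keys to mg/g values", call. = FALSE)
  }
  pat <- reference_pattern()
  ov <- aa_vector(obj)
  nm <- toupper(names(obj))
  pat[nm] <- ov[nm]
  validate_pattern(pat)
}
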