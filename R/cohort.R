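#' Plant-protein category of a meal
#'
#' Meals are categorized by the percentage of their protein (or total amino
#' acid mass) originating from plant-source foods, into `[0,27)`, `[27,65)`,
#' `[65,100)`, and exactly 100% (fully vegan). The categories partition
#' \[0, 100\]; a meal with zero total protein cannot be categorized and is
#' returned as `NA`.
#'
#' @param plant_pct Numeric vector of plant percentages in \[0, 100\].
#' @return Factor with levels `"0-27"`, `"27-65"`, `"65-99"`, `"100"`.
#' @export
plant_category <- function(plant_pct) {
  out <- rep(NA_character_, length(plant_pct))
  ok <- !is.na(plant_pct)
  out[ok & plant_pct == 100] <- "100"
  out[ok & plant_pct < 100] <- "65-99"
  out[ok & plant_pct < 65] <- "27-65"
  out[ok & plant_pct < 27] <- "0-27"
  factor(out, levels = c("0-27", "27-65", "65-99", "100"))
}

rowmins <- function(m) do.call(pmin, as.data.frame(m))

#' Batch-score food records into per-meal summaries
#'
#' Groups record entries by (person, day, meal moment), scores every group
#' both with and without digestibility adjustment, and attaches the
#' plant-protein proportion (on both the protein-mass and amino-acid-mass
#' bases), its category, and the relative impact of the digestibility
#' adjustment. Requirements are personalized per person from the body
#' weights in `persons`.
#'
#' Implemented with vectorized matrix aggregation rather than a per-meal
#' loop; [score_meal()] on any single group gives identical numbers.
#'
#' @param entries Record tibble ([load_records()] / [as_records()]).
#' @param persons Person tibble ([load_persons()] / [as_persons()]); every
#'   person appearing in `entries` must have a body weight.
#' @param table An `mpqs_food_table`.
#' @param include_snacks Also score `SNACK` groups as meals (default: main
#'   meals only).
#' @param merge_before_breakfast Relabel `BEFORE_BREAKFAST` entries as
#'   `BREAKFAST` before grouping (default off; when off those entries are
#'   not scored as meals but still count toward daily and missed protein in
#'   [person_summary()]).
#' @param category_basis Which plant-percentage basis drives the category:
#'   `"protein"` (protein mass, default) or `"aa"` (total EAA mass).
#' @param pattern,protein_target_g_per_kg Passed to requirement
#'   construction; defaults [reference_pattern()] and 0.3 g/kg per meal.
#' @return Tibble with one row per scored meal: identifiers, `mpqs`,
#'   `mpqs_truncated`, `limiting_eaa`, `mpqs_nodig`, `limiting_eaa_nodig`,
#'   `digestibility_impact_pct` (percent decrease caused by the adjustment,
#'   `NA` when the unadjusted score is 0), protein/energy totals,
#'   `plant_pct_protein`, `plant_pct_aa`, `category`, and
#'   `pct_protein_without_aa_data`. Meals with zero protein are flagged by
#'   `NA` category; their count is in attribute `n_uncategorized`.
#' @export
score_records <- function(entries, persons, table, include_snacks = FALSE,
                          merge_before_breakfast = FALSE,
                          category_basis = c("protein", "aa"),
                          pattern = reference_pattern(),
                          protein_target_g_per_kg = 0.3) {
  category_basis <- match.arg(category_basis)
  entries <- if (is.data.frame(entries)) as_records(entries) else
    stop("entries must be a data frame of record rows", call. = FALSE)
  persons <- as_persons(persons)
  pattern <- validate_pattern(pattern)

  missing <- setdiff(unique(entries$person_id), persons$person_id)
  if (length(missing)) {
    stop("missing body weight for person(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  if (merge_before_breakfast) {
    lv <- entries$meal_moment == "BEFORE_BREAKFAST"
    entries$meal_moment[lv] <- "BREAKFAST"
  }
  moments <- c(main_moments(), if (include_snacks) "SNACK")
  scored <- entries[entries$meal_moment %in% moments, , drop = FALSE]
  if (nrow(scored) == 0L) {
    stop("no scorable meal entries at moments: ",
         paste(moments, collapse = ", "), call. = FALSE)
  }

  idx <- food_lookup(table, scored$food_id)
  protein_g <- scored$mass_g * table$protein_g_per_100g[idx] / 100
  dig <- table$digestibility[idx]
  plant <- table$origin[idx] == "plant"
  no_aa <- !table$has_aa_data[idx]
  energy <- scored$mass_g * table$energy_kcal_per_100g[idx] / 100
  aa <- as.matrix(table[idx, eaa_cols(), drop = FALSE])
  raw_mg <- aa * protein_g            # per-portion raw EAA intake, mg
  adj_mg <- raw_mg * dig              # digestibility-adjusted

  key <- paste(scored$person_id, scored$day, scored$meal_moment, sep = "\r")
  key <- factor(key, levels = unique(key))  # entries are pre-sorted

  g_raw <- rowsum(raw_mg, key)
  g_adj <- rowsum(adj_mg, key)
  g_scal <- rowsum(cbind(protein_g, plant_protein = protein_g * plant,
                         no_aa_protein = protein_g * no_aa, energy,
                         aa_total = rowSums(raw_mg),
                         aa_plant = rowSums(raw_mg) * plant,
                         n = 1), key)
  meta <- scored[!duplicated(key), c("person_id", "day", "meal_moment")]

  weights <- persons$body_weight_kg[match(meta$person_id, persons$person_id)]
  req <- outer(weights * protein_target_g_per_kg, pattern)

  cov_of <- function(intake) {
    topped <- intake
    topped[, "CYS"] <- topped[, "CYS"] +
      pmax(0, intake[, "MET"] - req[, "MET"])
    100 * topped / req
  }
  colnames(g_raw) <- colnames(g_adj) <- eaa_keys()
  cov_d <- cov_of(g_adj)
  cov_n <- cov_of(g_raw)
  mpqs_d <- rowmins(cov_d)
  mpqs_n <- rowmins(cov_n)
  lim_d <- ifelse(mpqs_d >= 100, "NONE", eaa_keys()[max.col(-cov_d, "first")])
  lim_n <- ifelse(mpqs_n >= 100, "NONE", eaa_keys()[max.col(-cov_n, "first")])

  # fully-plant meals must land on exactly 100 (the vegan category edge is
  # exact), so short-circuit the ratio when the sums are identical
  pct_of <- function(part, whole) {
    ifelse(whole > 0, ifelse(part == whole, 100, 100 * part / whole), NA)
  }
  tot_prot <- g_scal[, "protein_g"]
  plant_pct_protein <- pct_of(g_scal[, "plant_protein"], tot_prot)
  plant_pct_aa <- pct_of(g_scal[, "aa_plant"], g_scal[, "aa_total"])
  basis <- if (category_basis == "protein") plant_pct_protein else plant_pct_aa

  out <- tibble::tibble(
    person_id = meta$person_id,
    day = meta$day,
    meal_moment = factor(as.character(meta$meal_moment),
                         levels = meal_moments()),
    n_portions = as.integer(g_scal[, "n"]),
    body_weight_kg = unname(weights),
    mpqs = unname(mpqs_d),
    mpqs_truncated = unname(pmin(mpqs_d, 100)),
    limiting_eaa = unname(lim_d),
    mpqs_nodig = unname(mpqs_n),
    limiting_eaa_nodig = unname(lim_n),
    digestibility_impact_pct = unname(
      ifelse(mpqs_n > 0, 100 * (mpqs_n - mpqs_d) / mpqs_n, NA)),
    total_protein_g = unname(tot_prot),
    plant_protein_g = unname(g_scal[, "plant_protein"]),
    animal_protein_g = unname(tot_prot - g_scal[, "plant_protein"]),
    energy_kcal = unname(g_scal[, "energy"]),
    plant_pct_protein = unname(plant_pct_protein),
    plant_pct_aa = unname(plant_pct_aa),
    category = plant_category(unname(basis)),
    pct_protein_without_aa_data = unname(
      ifelse(tot_prot > 0, 100 * g_scal[, "no_aa_protein"] / tot_prot, 0))
  )
  n_uncat <- sum(is.na(out$category))
  if (n_uncat > 0) {
    message(n_uncat, " zero-protein meal(s) left uncategorized")
  }
  attr(out, "n_uncategorized") <- n_uncat
  out
}

#' Summarize MPQS by meal moment
#'
#' Per meal moment and adjustment status (with / without digestibility),
#' reports mean, SD, SEM, median and quartiles of the MPQS, plus the paired
#' per-meal differences between the unadjusted and adjusted score. Moments
#' are ordered breakfast, lunch, dinner (then snack). SEM is `NA` when a
#' cell holds a single meal.
#'
#' @param summaries Tibble from [score_records()].
#' @return List with `stats` (tibble: `meal_moment`, `adjustment`, `n`,
#'   `mean`, `sd`, `sem`, `median`, `q25`, `q75`) and `paired` (tibble of
#'   per-meal `decrease = mpqs_nodig - mpqs` and
#'   `decrease_pct = 100 * decrease / mpqs_nodig`).
#' @export
moment_summary <- function(summaries) {
  if (nrow(summaries) == 0L) stop("no meal summaries given", call. = FALSE)
  mom <- droplevels(summaries$meal_moment)
  cell <- function(values, moment, adjustment) {
    x <- values[mom == moment]
    tibble::tibble(
      meal_moment = moment, adjustment = adjustment, n = length(x),
      mean = mean(x), sd = stats::sd(x),
      sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_,
      median = stats::median(x),
      q25 = unname(stats::quantile(x, 0.25)),
      q75 = unname(stats::quantile(x, 0.75)))
  }
  moms <- intersect(meal_moments(), levels(mom))
  stats_tbl <- do.call(rbind, c(
    lapply(moms, function(m) cell(summaries$mpqs, m, "with_digestibility")),
    lapply(moms, function(m) cell(summaries$mpqs_nodig, m, "without_digestibility"))
  ))
  stats_tbl$meal_moment <- factor(stats_tbl$meal_moment, levels = moms)
  stats_tbl <- stats_tbl[order(stats_tbl$meal_moment, stats_tbl$adjustment), ]
  paired <- tibble::tibble(
    person_id = summaries$person_id, day = summaries$day,
    meal_moment = summaries$meal_moment,
    mpqs = summaries$mpqs, mpqs_nodig = summaries$mpqs_nodig,
    decrease = summaries$mpqs_nodig - summaries$mpqs,
    decrease_pct = ifelse(summaries$mpqs_nodig > 0,
                          100 * (summaries$mpqs_nodig - summaries$mpqs) /
                            summaries$mpqs_nodig, NA))
  list(stats = tibble::as_tibble(stats_tbl), paired = paired)
}

#' Limiting-EAA frequency table
#'
#' Distribution of the limiting essential amino acid across meals, by meal
#' moment or by plant-protein category. Only meals that do not meet all
#' requirements (MPQS < 100) enter the distribution; within each group the
#' percentages sum to 100 up to integer rounding. Meals with no limiting
#' EAA are reported separately, and meals without a category are dropped
#' from the category view.
#'
#' @param summaries Tibble from [score_records()].
#' @param by `"moment"` or `"category"`.
#' @return List with `freq` (tibble: `group`, `limiting_eaa`, `n`, `pct`,
#'   `pct_rounded`) and `adequate` (tibble: `group`, `n_adequate`,
#'   `n_total`).
#' @export
limiting_frequency <- function(summaries, by = c("moment", "category")) {
  by <- match.arg(by)
  if (nrow(summaries) == 0L) stop("no meal summaries given", call. = FALSE)
  grp <- if (by == "moment") {
    droplevels(summaries$meal_moment)
  } else {
    summaries$category
  }
  keep <- !is.na(grp)
  grp <- droplevels(grp[keep])
  s <- summaries[keep, , drop = FALSE]

  limited <- s$limiting_eaa != "NONE"
  tab <- table(group = grp[limited],
               limiting_eaa = factor(s$limiting_eaa[limited],
                                     levels = eaa_keys()))
  freq <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(freq)[names(freq) == "Freq"] <- "n"
  totals <- stats::setNames(as.integer(rowSums(tab)), rownames(tab))
  freq$pct <- ifelse(totals[freq$group] > 0,
                     100 * freq$n / totals[freq$group], 0)
  freq$pct_rounded <- round_half_up(freq$pct)
  freq <- freq[freq$n > 0, , drop = FALSE]
  freq <- freq[order(match(freq$group, levels(grp)),
                     match(freq$limiting_eaa, eaa_keys())), , drop = FALSE]

  adequate <- tibble::tibble(
    group = levels(grp),
    n_adequate = as.integer(tapply(!limited, grp, sum, default = 0L)),
    n_total = as.integer(tapply(rep(1L, length(grp)), grp, sum, default = 0L)))
  list(freq = tibble::as_tibble(freq), adequate = adequate)
}

#' Per-person summaries and the median-MPQS split report
#'
#' Summarizes each person's scored meals (median MPQS and quartiles over
#' main meals, percentage of meals reaching 100) together with daily intake
#' derived from the full record, including protein eaten outside the three
#' main meals ("missed" protein, not seen by the per-meal score). Persons
#' are then split at a median MPQS of 100 -- at or above which more than
#' half of a person's meals meet all EAA requirements -- and group
#' descriptives are reported for both strata and the total sample.
#'
#' @param summaries Tibble from [score_records()].
#' @param entries Full record tibble (all moments, used for daily totals).
#' @param persons Person tibble with body weights.
#' @param table An `mpqs_food_table`.
#' @param include_snacks Count snack meals in the per-person MPQS median
#'   (default: main meals only, matching [score_records()] defaults).
#' @return List with `persons` (one row per person: `n_meals`,
#'   `median_mpqs`, `q25`, `q75`, `pct_meals_ge_100`, `protein_g_per_day`,
#'   `protein_g_per_kg_per_day`, `plant_protein_pct`,
#'   `energy_kcal_per_day`, `missed_protein_g_per_day`,
#'   `n_days_missed_gt20`, `group`) and `split` (tidy group descriptives:
#'   `group`, `variable`, `n`, `mean`, `sd`, `median`, `q25`, `q75`).
#' @export
person_summary <- function(summaries, entries, persons, table,
                           include_snacks = FALSE) {
  persons <- as_persons(persons)
  entries <- as_records(entries)
  use <- if (include_snacks) summaries else
    summaries[summaries$meal_moment %in% main_moments(), , drop = FALSE]
  if (nrow(use) == 0L) stop("no scored meals to summarize", call. = FALSE)

  idx <- food_lookup(table, entries$food_id)
  prot <- entries$mass_g * table$protein_g_per_100g[idx] / 100
  kcal <- entries$mass_g * table$energy_kcal_per_100g[idx] / 100
  is_plant <- table$origin[idx] == "plant"
  is_main <- entries$meal_moment %in% main_moments()
  pid <- entries$person_id

  day_key <- paste(pid, entries$day, sep = "\r")
  missed_by_day <- rowsum(prot * !is_main, day_key)
  day_pid <- sub("\r.*$", "", rownames(missed_by_day))

  per_person <- function(ids) {
    n_days <- tapply(entries$day, pid, function(d) length(unique(d)))[ids]
    tot <- tapply(prot, pid, sum)[ids]
    tibble::tibble(
      person_id = ids,
      n_days = as.integer(n_days),
      protein_g_per_day = as.numeric(tot / n_days),
      plant_protein_pct = as.numeric(
        100 * tapply(prot * is_plant, pid, sum)[ids] / tot),
      energy_kcal_per_day = as.numeric(tapply(kcal, pid, sum)[ids] / n_days),
      missed_protein_g_per_day = as.numeric(
        tapply(prot * !is_main, pid, sum)[ids] / n_days),
      n_days_missed_gt20 = as.integer(
        tapply(missed_by_day[, 1] > 20, day_pid, sum)[ids]))
  }

  ids <- sort(unique(use$person_id))
  spid <- use$person_id
  base <- tibble::tibble(
    person_id = ids,
    body_weight_kg = persons$body_weight_kg[match(ids, persons$person_id)],
    n_meals = as.integer(tapply(rep(1L, nrow(use)), spid, sum)[ids]),
    median_mpqs = as.numeric(tapply(use$mpqs, spid, stats::median)[ids]),
    q25 = as.numeric(tapply(use$mpqs, spid, stats::quantile, 0.25)[ids]),
    q75 = as.numeric(tapply(use$mpqs, spid, stats::quantile, 0.75)[ids]),
    pct_meals_ge_100 = as.numeric(
      100 * tapply(use$mpqs >= 100, spid, mean)[ids]))
  daily <- per_person(ids)
  out <- cbind(base, daily[, setdiff(names(daily), "person_id")])
  out$protein_g_per_kg_per_day <- out$protein_g_per_day / out$body_weight_kg
  out$group <- factor(ifelse(out$median_mpqs >= 100, ">=100", "<100"),
                      levels = c("<100", ">=100"))
  out <- tibble::as_tibble(out)

  describe <- function(df, label) {
    num_vars <- c("body_weight_kg", "n_meals", "median_mpqs",
                  "pct_meals_ge_100", "protein_g_per_day",
                  "protein_g_per_kg_per_day", "plant_protein_pct",
                  "energy_kcal_per_day", "missed_protein_g_per_day")
    do.call(rbind, lapply(num_vars, function(v) {
      x <- df[[v]]
      tibble::tibble(group = label, variable = v, n = length(x),
                     mean = mean(x), sd = stats::sd(x),
                     median = stats::median(x),
                     q25 = unname(stats::quantile(x, 0.25)),
                     q75 = unname(stats::quantile(x, 0.75)))
    }))
  }
  split_tbl <- rbind(
    describe(out, "total"),
    describe(out[out$group == "<100", , drop = FALSE], "<100"),
    describe(out[out$group == ">=100", , drop = FALSE], ">=100"))
  list(persons = out, split = tibble::as_tibble(split_tbl))
}
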