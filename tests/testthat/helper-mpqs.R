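# Shared fixtures, built in code.

# minimal hand-made food table: a plant cereal food, an animal dairy food,
# and a food without amino acid data
tiny_foods_df <- function() {
  df <- data.frame(
    id = c("bread", "milk", "mystery"),
    name = c("white bread", "semi-skimmed milk", "fortified drink"),
    protein_g_per_100g = c(10, 3.5, 2),
    energy_kcal_per_100g = c(250, 47, 50),
    origin = c("plant", "animal", "plant"),
    digestibility_pct = c(85, 96, 90),
    stringsAsFactors = FALSE
  )
  aa <- rbind(
    bread = c(22, 38, 70, 26, 17, 22, 78, 28, 11, 44),
    milk = c(27, 49, 96, 78, 24, 9, 93, 44, 14, 57),
    mystery = rep(NA_real_, 10)
  )
  colnames(aa) <- tolower(eaa_keys())
  cbind(df, as.data.frame(aa))
}

tiny_table <- function() food_table(tiny_foods_df(), source = "tiny", version = "1")

# default synthetic study: generated once per test run, under the
# generator's default configuration and seed
.mpqs_cache <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(.mpqs_cache$study)) {
    cfg <- generator_config()
    tab <- make_food_table(cfg)
    co <- make_cohort(cfg, tab)
    summaries <- suppressMessages(score_records(co$records, co$persons, tab))
    .mpqs_cache$study <- list(config = cfg, table = tab,
                              persons = co$persons, records = co$records,
                              summaries = summaries)
  }
  .mpqs_cache$study
}

# Independent scoring oracle: a plain per-EAA, per-food loop with its own
# copy of the reference constants. Shares no code with the package
# internals it checks.
oracle_score <- function(portions, table, body_weight_kg,
                         apply_digestibility = TRUE, target_g_per_kg = 0.3) {
  pat <- c(HIS = 15, ILE = 30, LEU = 59, LYS = 45, MET = 16,
           CYS = 6, PHE_TYR = 38, THR = 23, TRP = 6, VAL = 39)
  req <- body_weight_kg * target_g_per_kg * pat
  intake <- stats::setNames(rep(0, 10), names(pat))
  df <- as.data.frame(table)
  for (i in seq_len(nrow(portions))) {
    row <- df[df$id == portions$food_id[i], , drop = FALSE]
    stopifnot(nrow(row) == 1)
    grams_protein <- portions$mass_g[i] * row$protein_g_per_100g / 100
    d <- if (apply_digestibility) row$digestibility else 1
    for (k in names(pat)) {
      intake[[k]] <- intake[[k]] + grams_protein * row[[tolower(k)]] * d
    }
  }
  if (intake[["MET"]] > req[["MET"]]) {
    intake[["CYS"]] <- intake[["CYS"]] + (intake[["MET"]] - req[["MET"]])
  }
  cov <- 100 * intake / req
  list(mpqs = min(cov), coverage = cov,
       limiting = if (min(cov) >= 100) "NONE" else names(pat)[which.min(cov)])
}

# random meal over a table's foods, for property tests
random_meal <- function(table, n_foods = sample(1:4, 1)) {
  data.frame(food_id = sample(table$id, n_foods, replace = TRUE),
             mass_g = round(stats::runif(n_foods, 5, 300), 1))
}
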