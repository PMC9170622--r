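#' @keywords internal
"_PACKAGE"

MUTATIONS <- c("BRCA1", "BRCA2")
STRATEGIES <- c("IS", "CP", "PBM", "PBSO", "PBM_PBSO")
RATE_TRANSITIONS <- c("bc_death", "mbc_death", "oc_death", "df_bc", "df_oc",
                      "bc_cbc", "bc_mbc", "bc_oc", "postoc_bc")

#' Convert an annual event rate to a one-cycle transition probability
#'
#' Uses the standard exponential relation p = 1 - exp(-rate * dt), which
#' assumes a constant hazard within the cycle.
#'
#' @param rate Event rate in events per person-year. Must be non-negative.
#' @param dt Cycle length in years (default 1).
#' @return Probability of at least one event within `dt` years, in [0, 1).
#' @examples
#' rate_to_probability(0.0209)       # BC mortality band 0-49
#' rate_to_probability(0, 1)         # 0
#' @export
rate_to_probability <- function(rate, dt = 1) {
  if (any(rate < 0)) stop("rate must be non-negative")
  if (any(dt <= 0)) stop("dt must be positive")
  1 - exp(-rate * dt)
}

#' Apply a hazard ratio to an event rate
#'
#' @param rate Event rate (events/person-year), non-negative.
#' @param hr Hazard ratio, non-negative; 1 is the identity.
#' @return Adjusted rate `rate * hr`.
#' @export
apply_hazard_ratio <- function(rate, hr) {
  if (any(rate < 0)) stop("rate must be non-negative")
  if (any(hr < 0)) stop("hazard ratio must be non-negative")
  rate * hr
}

#' Effective breast-cancer incidence under chemoprevention
#'
#' Tamoxifen reduces only hormone-receptor-positive (HR+) disease, so the
#' hazard ratio is applied to the HR+ fraction of the subtype mix and the
#' remaining fraction is left unchanged:
#' rate * (f_HR+ * hr + (1 - f_HR+)).
#'
#' @param rate Baseline breast-cancer incidence rate.
#' @param mix Subtype mix as returned by [subtype_mix()] (named fractions
#'   `hr_pos`, `tnbc`, `her2` summing to 1).
#' @param hr_erpos Hazard ratio for HR+ disease (0.31 in the base case).
#' @return Adjusted incidence rate; never larger than `rate` for hr <= 1.
#' @export
cp_effective_bc_rate <- function(rate, mix, hr_erpos) {
  if (abs(sum(mix) - 1) > 1e-8) stop("subtype mix fractions must sum to 1")
  f <- mix[["hr_pos"]]
  rate * (f * hr_erpos + (1 - f))
}

#' Molecular subtype mix of incident breast cancer by mutation
#'
#' Fractions of hormone-receptor-positive (HR+), triple-negative (TNBC) and
#' Her2+ disease among incident breast cancers: 20/70/10% for BRCA1 and
#' 80/10/10% for BRCA2.
#'
#' @param mutation `"BRCA1"` or `"BRCA2"`.
#' @return Named numeric vector (`hr_pos`, `tnbc`, `her2`) summing to 1.
#' @export
subtype_mix <- function(mutation = MUTATIONS) {
  mutation <- match.arg(mutation)
  if (mutation == "BRCA1") c(hr_pos = 0.20, tnbc = 0.70, her2 = 0.10)
  else                     c(hr_pos = 0.80, tnbc = 0.10, her2 = 0.10)
}

# Vectorized age-band lookup over a band table (age_lo, age_hi inclusive,
# non-overlapping). Returns row indices; errors name the uncovered age.
.band_index <- function(bands, ages, what = "rate table") {
  idx <- rep(NA_integer_, length(ages))
  for (i in seq_len(nrow(bands))) {
    hit <- ages >= bands$age_lo[i] & ages <= bands$age_hi[i]
    if (any(hit & !is.na(idx)))
      stop("overlapping age bands in ", what)
    idx[hit] <- i
  }
  if (anyNA(idx))
    stop("age ", paste(ages[is.na(idx)], collapse = ", "),
         " not covered by any band of ", what)
  idx
}

#' Look up an age-banded annual rate
#'
#' Bands are inclusive on both ends; an age on a printed boundary belongs to
#' the band whose upper bound it equals.
#'
#' @param rates A rate table as in `$rates` of [brca_parameters()].
#' @param transition One of the transition keys, e.g. `"df_bc"`.
#' @param age Age (years); may be a vector.
#' @return Rate(s) in events per person-year.
#' @export
lookup_rate <- function(rates, transition, age) {
  tab <- rates[rates$transition == transition, , drop = FALSE]
  if (nrow(tab) == 0L) stop("unknown transition: ", transition)
  tab$rate[.band_index(tab, age, paste0("transition '", transition, "'"))]
}

.read_params_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df
}

.validate_rates <- function(df, file) {
  need <- c("transition", "age_lo", "age_hi", "rate", "se", "lo", "hi")
  if (!all(need %in% names(df)))
    stop(file, ": missing columns ", paste(setdiff(need, names(df)), collapse = ", "))
  df$age_hi[is.na(df$age_hi)] <- Inf
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header line offset
    if (!df$transition[i] %in% RATE_TRANSITIONS)
      stop(file, " line ", line, ": unknown transition '", df$transition[i], "'")
    if (is.na(df$rate[i]) || df$rate[i] < 0)
      stop(file, " line ", line, ": rate must be a non-negative number")
    if (!is.na(df$se[i]) && df$se[i] < 0)
      stop(file, " line ", line, ": SE must be non-negative")
    if (df$age_lo[i] > df$age_hi[i])
      stop(file, " line ", line, ": age_lo exceeds age_hi")
  }
  for (tr in unique(df$transition)) {
    tab <- df[df$transition == tr, ]
    o <- order(tab$age_lo)
    tab <- tab[o, ]
    if (nrow(tab) > 1 && any(tab$age_lo[-1] <= tab$age_hi[-nrow(tab)]))
      stop(file, ": overlapping bands for transition '", tr, "'")
  }
  df
}

.validate_hrs <- function(df, file) {
  for (i in seq_len(nrow(df))) {
    if (is.na(df$hr[i]) || df$hr[i] <= 0 || df$hr[i] > 1)
      stop(file, " line ", i + 1L, ": base-case hazard ratio must be in (0, 1]")
    if (!is.na(df$se[i]) && df$se[i] < 0)
      stop(file, " line ", i + 1L, ": SE must be non-negative")
  }
  df
}

.validate_utilities <- function(df, file) {
  for (i in seq_len(nrow(df))) {
    if (is.na(df$value[i]) || df$value[i] < 0 || df$value[i] > 1)
      stop(file, " line ", i + 1L, ": utility must lie in [0, 1]")
  }
  df
}

#' Load the model's printed input parameters for one mutation
#'
#' Reads the packaged parameter files (age-banded transition rates, strategy
#' hazard ratios, utilities) and validates them. Rates without a separate
#' BRCA2 estimate carry the BRCA1 value in both files.
#'
#' @param mutation `"BRCA1"` or `"BRCA2"`.
#' @param dir Directory holding `rates_<mutation>.csv`, `hazard_ratios.csv`
#'   and `utilities.csv`; defaults to the packaged parameter set.
#' @return An object of class `brca_params`: a list with elements `rates`,
#'   `hrs`, `utilities` (split into `df_age`, `state`, `strategy`), `mix`
#'   and `mutation`.
#' @export
brca_parameters <- function(mutation = MUTATIONS, dir = NULL) {
  mutation <- match.arg(mutation)
  if (is.null(dir)) dir <- system.file("extdata", "params", package = "brcacua")
  rf <- file.path(dir, paste0("rates_", tolower(mutation), ".csv"))
  hf <- file.path(dir, "hazard_ratios.csv")
  uf <- file.path(dir, "utilities.csv")
  for (f in c(rf, hf, uf)) if (!file.exists(f)) stop("parameter file not found: ", f)
  rates <- .validate_rates(.read_params_csv(rf), rf)
  hrs <- .validate_hrs(.read_params_csv(hf), hf)
  hrs <- hrs[is.na(hrs$mutation) | hrs$mutation == "" | hrs$mutation == mutation, ]
  ut <- .validate_utilities(.read_params_csv(uf), uf)
  ut$age_hi[is.na(ut$age_hi)] <- Inf
  utilities <- list(
    df_age = ut[ut$kind == "df_age", c("age_lo", "age_hi", "value")],
    state = stats::setNames(ut$value[ut$kind == "state"], ut$key[ut$kind == "state"]),
    state_var = stats::setNames(ut$var_pct[ut$kind == "state"], ut$key[ut$kind == "state"]),
    strategy = stats::setNames(ut$value[ut$kind == "strategy"], ut$key[ut$kind == "strategy"]),
    strategy_var = stats::setNames(ut$var_pct[ut$kind == "strategy"], ut$key[ut$kind == "strategy"])
  )
  structure(list(rates = rates, hrs = hrs, utilities = utilities,
                 mix = subtype_mix(mutation), mutation = mutation),
            class = "brca_params")
}

#' @export
print.brca_params <- function(x, ...) {
  cat("Model parameters for", x$mutation, "\n")
  cat("  rate entries:      ", nrow(x$rates), "\n")
  cat("  hazard ratios:     ", nrow(x$hrs), "\n")
  cat("  subtype mix (HR+/TNBC/Her2+):",
      paste(sprintf("%.0f%%", 100 * x$mix), collapse = "/"), "\n")
  invisible(x)
}

#' Read a period life table from CSV
#'
#' @param path CSV with columns `age` and `qx` (annual death probability).
#' @return Data frame of class `life_table`.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(df))) stop("life table needs columns age, qx")
  if (any(df$qx < 0 | df$qx > 1)) stop("life table qx must lie in [0, 1]")
  class(df) <- c("life_table", "data.frame")
  df
}

.qx_at <- function(life_table, ages) {
  i <- match(pmin(ages, max(life_table$age)), life_table$age)
  if (anyNA(i)) stop("life table does not cover age(s) ",
                     paste(ages[is.na(i)], collapse = ", "))
  life_table$qx[i]
}

#' Model run configuration
#'
#' Holds the cohort and analysis settings: start age, horizon, discounting,
#' willingness-to-pay, currency, and the documented model switches.
#'
#' @param start_age Cohort starting age in years (40 in the base case).
#' @param n_cycles Number of one-year cycles; defaults to
#'   `max(60, 100 - start_age)` so the horizon always reaches age 100.
#' @param disc_cost,disc_outcomes Annual discount rates (0.03).
#' @param wtp_chf Willingness-to-pay in CHF per QALY (100,000).
#' @param currency `"EUR"` (results currency, converted at `eur_chf`) or `"CHF"`.
#' @param eur_chf Exchange rate, CHF per EUR (1.10).
#' @param half_cycle Apply a half-cycle correction (default `FALSE`).
#' @param is_disutility `"schedule"` applies the surveillance disutility in
#'   every disease-free cycle with scheduled imaging; `"first_year"` applies
#'   it in cycle 0 only.
#' @param cp_interpretation `"hr"` treats the 0.31 chemoprevention figure as a
#'   hazard ratio on the HR+ fraction; `"one_minus_rrr"` uses 1 - 0.31 = 0.69.
#' @param surgical_disutility_years Duration (years) of the surgical
#'   strategies' utility decrement (1 in the base case; 5 or 10 in scenarios,
#'   held constant without linear recovery).
#' @param tamoxifen_effect_years Duration of chemoprevention's risk reduction
#'   (`Inf` = lifelong in the base case; 5 in the scenario).
#' @param oc_mortality_multiplier Multiplier on ovarian-cancer mortality rates
#'   (0.70 in the scenario, 1 otherwise).
#' @param reconstruction_timing `"immediate"` books the breast reconstruction
#'   cost in year 1 after diagnosis, `"later"` in year 2.
#' @param background_mortality_in_cancer Add life-table mortality as a
#'   competing rate inside cancer states (default `TRUE`).
#' @param implant_mode `"lump"` charges implant replacement after prophylactic
#'   mastectomy every 10 years (to age 70); `"amortized"` spreads it annually.
#' @return Object of class `cua_config`.
#' @export
cua_config <- function(start_age = 40, n_cycles = NULL,
                       disc_cost = 0.03, disc_outcomes = 0.03,
                       wtp_chf = 100000, currency = c("EUR", "CHF"),
                       eur_chf = 1.10, half_cycle = FALSE,
                       is_disutility = c("schedule", "first_year"),
                       cp_interpretation = c("hr", "one_minus_rrr"),
                       surgical_disutility_years = 1,
                       tamoxifen_effect_years = Inf,
                       oc_mortality_multiplier = 1,
                       reconstruction_timing = c("immediate", "later"),
                       background_mortality_in_cancer = TRUE,
                       implant_mode = c("lump", "amortized")) {
  currency <- match.arg(currency)
  if (is.null(n_cycles)) n_cycles <- max(60L, 100L - as.integer(start_age))
  if (start_age + n_cycles < 100) stop("horizon must reach age 100 (lifelong)")
  if (disc_cost < 0 || disc_outcomes < 0) stop("discount rates must be >= 0")
  if (oc_mortality_multiplier < 0) stop("oc_mortality_multiplier must be >= 0")
  structure(list(
    start_age = as.integer(start_age), n_cycles = as.integer(n_cycles),
    cycle_length = 1, disc_cost = disc_cost, disc_outcomes = disc_outcomes,
    wtp_chf = wtp_chf, currency = currency, eur_chf = eur_chf,
    half_cycle = isTRUE(half_cycle),
    is_disutility = match.arg(is_disutility),
    cp_interpretation = match.arg(cp_interpretation),
    surgical_disutility_years = surgical_disutility_years,
    tamoxifen_effect_years = tamoxifen_effect_years,
    oc_mortality_multiplier = oc_mortality_multiplier,
    reconstruction_timing = match.arg(reconstruction_timing),
    background_mortality_in_cancer = isTRUE(background_mortality_in_cancer),
    implant_mode = match.arg(implant_mode)
  ), class = "cua_config")
}

#' Willingness-to-pay in the configured results currency
#' @param config A [cua_config()] object.
#' @return WTP per QALY in `config$currency`.
#' @export
wtp_value <- function(config) {
  if (config$currency == "CHF") config$wtp_chf
  else convert_currency(config$wtp_chf, "CHF", "EUR", config$eur_chf)
}
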