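#' Convert an amount between EUR and CHF
#'
#' @param amount Monetary amount (vectorised).
#' @param from,to `"EUR"` or `"CHF"`.
#' @param rate CHF per EUR (1.10, the model's fixed exchange rate).
#' @return Converted amount.
#' @export
convert_currency <- function(amount, from, to, rate = 1.10) {
  ok <- c("EUR", "CHF")
  if (!from %in% ok || !to %in% ok) stop("unsupported currency pair")
  if (from == to) return(amount)
  if (from == "CHF") amount / rate else amount * rate
}

#' Read a cost schedule file
#'
#' The schedule is a structured YAML text file with sections `one_off`,
#' `recurring`, `annuity`, `palliative`, the treatment cost components
#' (`bc`, `oc`, `mbc`) from which the 10-year state-year cost vectors are
#' composed, and the cohort cost `assumptions` (implant share, reshaping
#' share, radiotherapy share, relapse share).
#'
#' @param path Path to the YAML schedule.
#' @return Object of class `cost_schedule`.
#' @export
read_cost_schedule <- function(path) {
  if (!file.exists(path)) stop("cost schedule file not found: ", path)
  sc <- yaml::read_yaml(path)
  .validate_cost_schedule(sc, path)
  structure(sc, class = "cost_schedule")
}

#' Write a cost schedule to a YAML file
#' @param schedule A `cost_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cost_schedule <- function(schedule, path) {
  yaml::write_yaml(unclass(schedule), path)
  invisible(path)
}

.cost_sections <- c("one_off", "recurring", "annuity", "bc", "oc", "mbc",
                    "palliative", "assumptions")

.validate_cost_schedule <- function(sc, path = "<schedule>") {
  miss <- setdiff(.cost_sections, names(sc))
  if (length(miss)) stop(path, ": missing sections ", paste(miss, collapse = ", "))
  for (sec in .cost_sections) {
    v <- unlist(sc[[sec]])
    if (any(!is.finite(v)) || any(v < 0))
      stop(path, ": section ", sec, " contains negative or non-numeric amounts")
  }
  invisible(sc)
}

#' The bundled synthetic cost schedule
#'
#' Fixture costs with plausible Swiss magnitudes standing in for the national
#' tariff schedules; all cost outputs derived from it are watermarked
#' "fixture costs".
#'
#' @return A `cost_schedule`.
#' @export
default_cost_schedule <- function() {
  read_cost_schedule(system.file("extdata", "fixtures", "costs_synthetic.yaml",
                                 package = "brcacua"))
}

# TRUE in cycles where the surveillance schedule images the breast:
# annual mammography+MRI to 59, annual mammography 60-69, biennial from 70.
.imaging_year <- function(age) age < 70 | ((age - 70) %% 2 == 0)

# Annual surveillance imaging cost at a given age.
.imaging_cost <- function(sc, age) {
  r <- sc$recurring
  ifelse(age < 60, r$mammography + r$mri_breast,
         ifelse(age < 70, r$mammography,
                ifelse(.imaging_year(age), r$mammography, 0)))
}

# Full intensified-surveillance package: imaging + semi-annual consultations.
.is_procedures <- function(sc, age) .imaging_cost(sc, age) + 2 * sc$recurring$consult_gyn

# Expected one-off reconstruction cost (95% implant / 5% autologous).
.recon_mix_cost <- function(sc) {
  a <- sc$assumptions
  a$implant_share * sc$one_off$reconstruction_implant +
    (1 - a$implant_share) * sc$one_off$reconstruction_autologous
}

#' Ten-year cost vector for a year since breast-cancer diagnosis
#'
#' Year 1 bundles surgery, breast reconstruction (unless deferred to year 2),
#' reshaping, radiotherapy weighted by the nodal-involvement share, and
#' subtype-weighted chemo-/targeted therapy; later years carry follow-up,
#' endocrine therapy for the HR+ fraction (years 1-5) and, outside
#' prophylactic-mastectomy arms, the annualised implant-replacement cost.
#'
#' @param sc Cost schedule.
#' @param mix Subtype mix, see [subtype_mix()].
#' @param config A [cua_config()].
#' @param pbm_arm Is this a prophylactic-mastectomy-containing strategy?
#' @return Numeric vector of length 10 (cost per year since diagnosis).
#' @export
bc_year_costs <- function(sc, mix, config, pbm_arm = FALSE) {
  a <- sc$assumptions
  chemo <- mix[["tnbc"]] * sc$bc$chemo_tnbc + mix[["her2"]] * sc$bc$chemo_her2
  hormone <- mix[["hr_pos"]] * sc$bc$hormone_year
  amort <- if (pbm_arm) 0 else a$implant_share * sc$annuity$implant_replacement / 10
  y <- rep(sc$bc$followup_year, 10)
  y[1:5] <- y[1:5] + hormone
  y[2:10] <- y[2:10] + amort
  recon <- .recon_mix_cost(sc)
  y[1] <- y[1] + sc$bc$surgery + a$reshaping_share * sc$one_off$reshaping +
    a$radiotherapy_share * sc$bc$radiotherapy + chemo
  if (config$reconstruction_timing == "immediate") y[1] <- y[1] + recon
  else y[2] <- y[2] + recon
  y
}

#' Ten-year cost vector for a year since ovarian-cancer diagnosis
#'
#' Year 1: debulking surgery, first-line chemotherapy and PARP-inhibitor
#' maintenance; year 2: maintenance continues; years 3-5 add recurrence
#' treatment weighted by the relapse share; follow-up throughout.
#'
#' @inheritParams bc_year_costs
#' @return Numeric vector of length 10.
#' @export
oc_year_costs <- function(sc, config) {
  a <- sc$assumptions
  y <- rep(sc$oc$followup_year, 10)
  y[1] <- y[1] + sc$oc$surgery + sc$oc$chemo_first_line + sc$oc$parpi_year
  y[2] <- y[2] + sc$oc$parpi_year
  y[3:5] <- y[3:5] + a$relapse_share * sc$oc$recurrence_year
  y
}

#' Annual metastatic breast-cancer therapy cost
#'
#' Subtype-weighted total therapy cost divided by the subtype's median
#' overall survival, weighted by the mutation-specific subtype mix.
#'
#' @inheritParams bc_year_costs
#' @return Annual cost while in the metastatic state.
#' @export
mbc_annual_cost <- function(sc, mix) {
  m <- sc$mbc
  mix[["tnbc"]] * m$total_tnbc / m$os_tnbc +
    mix[["hr_pos"]] * m$total_hrpos / m$os_hrpos +
    mix[["her2"]] * m$total_her2 / m$os_her2
}

# Annual surveillance cost under a strategy's profile.
.surveillance_cost <- function(sc, profile, age) {
  r <- sc$recurring
  switch(profile,
    is_full = .is_procedures(sc, age),
    consults_semiannual = 2 * r$consult_gyn,
    consults_annual = r$consult_gyn,
    stop("unknown surveillance profile: ", profile))
}

# Annual cost in the disease-free state by strategy spec, age and cycle.
.df_recurring <- function(sc, sp, age, cycle, config) {
  r <- sc$recurring
  out <- .surveillance_cost(sc, sp$surveillance, age)
  if (isTRUE(sp$hrt) && age < 51) out <- out + r$hrt_year
  if (isTRUE(sp$cp_drug) && cycle < 5)
    out <- out + r$tamoxifen_year + r$vaginal_ultrasound
  out
}

# Annual follow-up cost in the post-BC / post-CBC states; the
# implant-replacement annuity after therapeutic reconstruction continues to
# age 70 outside prophylactic-mastectomy arms (whose implants are already on
# the prophylactic replacement clock).
.post_bc_recurring <- function(sc, sp, age, config) {
  amort <- if (isTRUE(sp$implant_lumps) || age >= 70) 0
           else sc$assumptions$implant_share * sc$annuity$implant_replacement / 10
  .surveillance_cost(sc, sp$surveillance, age) + amort
}

.post_oc_recurring <- function(sc, sp, age) {
  base <- if (sp$surveillance == "consults_semiannual") sc$recurring$consult_gyn
          else .surveillance_cost(sc, sp$surveillance, age)
  base + sc$recurring$vaginal_ultrasound
}

# One-off prophylactic intervention cost charged at cycle 0.
.strategy_one_off <- function(sc, sp) {
  a <- sc$assumptions
  total <- 0
  for (key in sp$one_off) {
    total <- total + switch(key,
      reconstruction = .recon_mix_cost(sc),
      reshaping = a$reshaping_share * sc$one_off$reshaping,
      {
        if (is.null(sc$one_off[[key]])) stop("no one-off cost entry '", key, "'")
        sc$one_off[[key]]
      })
  }
  total
}

#' Per-cycle cost increment of a cohort slice
#'
#' Occupancy-weighted state costs for one cycle, given the per-state cost
#' row already composed for that cycle. Exposed mainly for inspection; the
#' engine applies the same arithmetic internally.
#'
#' @param occupancy Occupancy vector over the expanded states.
#' @param cost_row Per-state annual cost for this cycle.
#' @param death_flows Mass flowing from each expanded state to dead this
#'   cycle (for the palliative lump sum).
#' @param palliative_states Logical marker of states whose death transitions
#'   incur the palliative lump.
#' @param palliative Lump-sum amount.
#' @return Undiscounted cost increment for the cycle.
#' @export
cycle_cost <- function(occupancy, cost_row, death_flows = NULL,
                       palliative_states = NULL, palliative = 0) {
  if (length(occupancy) != length(cost_row))
    stop("occupancy and cost_row lengths differ")
  total <- sum(occupancy * cost_row)
  if (!is.null(death_flows) && palliative > 0)
    total <- total + palliative * sum(death_flows[palliative_states])
  total
}
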