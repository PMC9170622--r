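# Synthetic input fixtures: a parametric female life table and a cost
# schedule with plausible Swiss magnitudes. Both stand in for external
# sources (a national period life table; tariff-derived cost tables) and are
# clearly watermarked as synthetic.

#' Generate a Gompertz-Makeham female life table
#'
#' Annual death probability qx(age) = 1 - exp(-(A + B * exp(theta * age))):
#' a constant background (Makeham) component plus an exponentially rising
#' (Gompertz) senescent component. The defaults are chosen so that the table
#' resembles a modern low-mortality female population (remaining life
#' expectancy at 40 around 45 years).
#'
#' @param makeham Background mortality rate per year (A).
#' @param gompertz_a Senescent baseline rate at age 0 (B).
#' @param gompertz_b Log-slope of the senescent hazard per year of age (theta).
#' @param max_age Last tabulated age.
#' @return A `life_table` data frame (age, qx).
#' @export
make_life_table <- function(makeham = 3e-4, gompertz_a = 1.2e-6,
                            gompertz_b = 0.13, max_age = 100) {
  if (makeham < 0 || gompertz_a < 0 || gompertz_b < 0)
    stop("life-table parameters must be non-negative")
  age <- 0:max_age
  qx <- 1 - exp(-(makeham + gompertz_a * exp(gompertz_b * age)))
  if (any(qx >= 1))
    stop("parameters produce qx >= 1 below age ", max_age)
  df <- data.frame(age = age, qx = qx)
  class(df) <- c("life_table", "data.frame")
  df
}

#' Write a life table to CSV
#' @param life_table A `life_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(as.data.frame(life_table), path, row.names = FALSE)
  invisible(path)
}

#' The bundled synthetic Swiss-like life table
#'
#' A Gompertz-Makeham stand-in for the national female period life table,
#' shipped as a two-column CSV fixture.
#'
#' @return A `life_table`.
#' @export
swiss_life_table <- function() {
  read_life_table(system.file("extdata", "fixtures", "life_table_synthetic.csv",
                              package = "brcacua"))
}

# Anchor amounts (EUR) for the synthetic cost schedule: one-time choices of
# plausible Swiss magnitudes for each cost component.
.cost_anchors <- function() {
  list(
    currency = "EUR",
    watermark = "synthetic fixture costs (not tariff-derived)",
    one_off = list(pbm_surgery = 11000, pbso_surgery = 7500,
                   reconstruction_implant = 9000,
                   reconstruction_autologous = 22000, reshaping = 5000),
    recurring = list(consult_gyn = 130, mammography = 170, mri_breast = 500,
                     vaginal_ultrasound = 110, tamoxifen_year = 250,
                     hrt_year = 400),
    annuity = list(implant_replacement = 8500),
    bc = list(surgery = 13000, radiotherapy = 15000, chemo_tnbc = 36000,
              chemo_her2 = 72000, hormone_year = 900, followup_year = 700),
    oc = list(surgery = 21000, chemo_first_line = 22000, parpi_year = 45000,
              recurrence_year = 16000, followup_year = 600),
    mbc = list(total_tnbc = 70000, os_tnbc = 1.2, total_hrpos = 90000,
               os_hrpos = 2.5, total_her2 = 180000, os_her2 = 2.2),
    palliative = list(lump = 30000),
    assumptions = list(implant_share = 0.95, reshaping_share = 0.50,
                       radiotherapy_share = 0.38, relapse_share = 0.73)
  )
}

#' Generate a synthetic cost schedule
#'
#' Builds the fixture cost schedule from its anchor amounts, optionally
#' jittering every monetary anchor by a uniform multiplicative factor
#' (deterministic given the seed). The cohort assumption shares and median
#' survivals are never jittered.
#'
#' @param seed Integer seed for the jitter draws.
#' @param jitter Half-width of the uniform multiplicative jitter (0 = exact
#'   anchors, the bundled fixture).
#' @return A `cost_schedule`.
#' @export
make_cost_schedule <- function(seed = 1, jitter = 0) {
  if (jitter < 0 || jitter >= 1) stop("jitter must lie in [0, 1)")
  sc <- .cost_anchors()
  if (jitter > 0) {
    money <- c("one_off", "recurring", "annuity", "bc", "oc", "palliative")
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    for (sec in money)
      sc[[sec]] <- lapply(sc[[sec]], function(v)
        v * stats::runif(1, 1 - jitter, 1 + jitter))
    for (k in c("total_tnbc", "total_hrpos", "total_her2"))
      sc$mbc[[k]] <- sc$mbc[[k]] * stats::runif(1, 1 - jitter, 1 + jitter)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  structure(sc, class = "cost_schedule")
}

#' @export
print.cost_schedule <- function(x, ...) {
  cat("Cost schedule [", x$currency, "] -", x$watermark %||% "", "\n")
  cat("  sections:", paste(intersect(.cost_sections, names(x)), collapse = ", "), "\n")
  invisible(x)
}
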