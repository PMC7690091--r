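#' Build a stylized general-population life table
#'
#' Constructs a single-year-of-age life table over ages 0-100 from a
#' Gompertz-Makeham annual hazard, `h(age) = a + b * exp(c * age)`, and
#' converts annual death probabilities to weekly ones via
#' `p_week = 1 - (1 - p_year)^(1 / weeks_per_year)`. The table is an
#' explicitly synthetic stand-in for a national general-population life
#' table (the model applies it to patients in the SCT-success state, who
#' are assumed to face general-population mortality); its exact values are
#' configuration, not estimates of any real population.
#'
#' Defaults give an annual death probability of roughly 0.3% at age 48
#' rising to about 25% at age 100, a plausible adult-mortality profile.
#'
#' @param makeham_a Age-independent annual hazard component.
#' @param gompertz_b Gompertz level parameter.
#' @param gompertz_c Gompertz log-slope per year of age.
#' @param weeks_per_year Weeks per model year (default 52.1).
#' @return A data frame of class `ptcl_life_table` with columns
#'   `age_years` (0-100), `annual_death_prob`, `weekly_death_prob`.
#' @examples
#' lt <- make_life_table()
#' lt$weekly_death_prob[lt$age_years == 48]
#' @export
make_life_table <- function(makeham_a = 5e-4, gompertz_b = 3e-5,
                            gompertz_c = 0.09, weeks_per_year = 52.1) {
  age <- 0:100
  hazard <- makeham_a + gompertz_b * exp(gompertz_c * age)
  annual <- 1 - exp(-hazard)
  if (any(annual < 0 | annual >= 1))
    stop("life-table parameters yield annual probabilities outside [0, 1)")
  weekly <- 1 - (1 - annual)^(1 / weeks_per_year)
  lt <- data.frame(age_years = age, annual_death_prob = annual,
                   weekly_death_prob = weekly)
  class(lt) <- c("ptcl_life_table", "data.frame")
  lt
}

#' Weekly general-population death probability at a given age
#'
#' @param lt A life table from [make_life_table()] or [read_life_table()].
#' @param age Age in years (vectorized); clamped to the table's age range.
#' @return Weekly death probability/ies.
#' @export
life_table_weekly_prob <- function(lt, age) {
  a <- pmin(pmax(floor(age), min(lt$age_years)), max(lt$age_years))
  lt$weekly_death_prob[match(a, lt$age_years)]
}

#' Read / write a life table as CSV
#'
#' CSV columns: `age_years`, `weekly_death_prob` (and `annual_death_prob`
#' when present).
#'
#' @param lt A life table.
#' @param path File path.
#' @return `read_life_table()` returns a `ptcl_life_table`;
#'   `write_life_table()` returns `path` invisibly.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  stopifnot(all(c("age_years", "weekly_death_prob") %in% names(lt)))
  if (any(lt$weekly_death_prob < 0 | lt$weekly_death_prob >= 1))
    stop("weekly death probabilities must lie in [0, 1)")
  class(lt) <- c("ptcl_life_table", "data.frame")
  lt
}
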