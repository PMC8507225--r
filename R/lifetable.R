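# Life tables: age- and sex-indexed annual death probabilities.

#' Construct a life table
#'
#' @param age Integer ages, contiguous from 0 to a terminal age, repeated per
#'   sex.
#' @param sex `"F"` or `"M"` per row.
#' @param qx Annual probability of death in `[0, 1]`.
#' @return A `life_table` (a data frame with columns `age`, `sex`, `qx`).
#' @export
life_table <- function(age, sex, qx) {
  x <- data.frame(age = as.integer(age), sex = as.character(sex),
                  qx = as.numeric(qx))
  class(x) <- c("life_table", "data.frame")
  validate_life_table(x)
}

validate_life_table <- function(lt) {
  issues <- character()
  if (!all(c("age", "sex", "qx") %in% names(lt)))
    stop("life table must have columns age, sex, qx", call. = FALSE)
  bad_sex <- which(!lt$sex %in% c("F", "M"))
  if (length(bad_sex))
    issues <- c(issues, sprintf("row %d: sex must be F or M", bad_sex[1]))
  bad_qx <- which(!is.finite(lt$qx) | lt$qx < 0 | lt$qx > 1)
  if (length(bad_qx))
    issues <- c(issues, sprintf("row %d: qx must be in [0, 1]", bad_qx[1]))
  for (s in c("F", "M")) {
    ages <- sort(lt$age[lt$sex == s])
    if (!length(ages)) {
      issues <- c(issues, sprintf("no rows for sex %s", s))
    } else if (ages[1] != 0L || !identical(ages, seq(0L, ages[length(ages)]))) {
      issues <- c(issues, sprintf("ages for sex %s must be contiguous from 0", s))
    }
  }
  if (length(issues))
    stop("invalid life table:\n", paste0("  - ", issues, collapse = "\n"),
         call. = FALSE)
  invisible(lt)
}

#' Read / write a life table as delimited text
#'
#' Format: comma-separated with header `age,sex,qx`; `sex` in `{F, M}`; ages
#' contiguous from 0 per sex.
#'
#' @param path File path.
#' @param lt A `life_table`.
#' @return `read_life_table` returns a validated `life_table`;
#'   `write_life_table` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  life_table(df$age, df$sex, df$qx)
}

#' @rdname read_life_table
#' @export
write_life_table <- function(lt, path) {
  validate_life_table(lt)
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Fast lookup closure: returns function(age, sex) -> annual qx, using the
# terminal row (with a one-time warning) beyond the tabulated range.
lifetable_lookup <- function(lt) {
  qxF <- lt$qx[lt$sex == "F"][order(lt$age[lt$sex == "F"])]
  qxM <- lt$qx[lt$sex == "M"][order(lt$age[lt$sex == "M"])]
  max_age <- min(length(qxF), length(qxM)) - 1L
  warned <- FALSE
  function(age, sex) {
    a <- floor(age)
    if (a > max_age) {
      if (!warned) {
        warning("age ", a, " beyond life-table range; using terminal age ",
                max_age, call. = FALSE)
        warned <<- TRUE
      }
      a <- max_age
    }
    if (sex == "F") qxF[a + 1L] else qxM[a + 1L]
  }
}

#' Sex-mix-weighted weekly background death probability
#'
#' The annual probability for each sex at `floor(age)` is converted to a
#' per-cycle probability by compounding ([annual_prob_to_weekly_prob()]) and
#' the two are averaged with weight `sex_mix` on females.
#'
#' @param age Age in years (within the life-table range).
#' @param sex_mix Proportion female in `[0, 1]`.
#' @param lt A `life_table` (or a lookup closure from it).
#' @param cycles_per_year Cycles per year (default 52).
#' @return Weekly probability of background death.
#' @export
weekly_background_death_prob <- function(age, sex_mix, lt, cycles_per_year = 52) {
  lookup <- if (is.function(lt)) lt else lifetable_lookup(lt)
  sex_mix * annual_prob_to_weekly_prob(lookup(age, "F"), cycles_per_year) +
    (1 - sex_mix) * annual_prob_to_weekly_prob(lookup(age, "M"), cycles_per_year)
}

#' Discounted life expectancy from a life table
#'
#' Weekly-cycle survival recursion under background mortality only, summing
#' discounted alive-time. This is the quantity the synthetic life table is
#' calibrated against.
#'
#' @param lt A `life_table`.
#' @param start_age Starting age in years.
#' @param discount Annual discount rate.
#' @param sex_mix Proportion female.
#' @param horizon_years Years simulated (default 50).
#' @param cycles_per_year Cycles per year (default 52).
#' @return Discounted life expectancy in years.
#' @export
discounted_life_expectancy <- function(lt, start_age = 41, discount = 0.015,
                                       sex_mix = 0.5, horizon_years = 50,
                                       cycles_per_year = 52) {
  lookup <- lifetable_lookup(lt)
  n <- round(horizon_years * cycles_per_year)
  alive <- 1
  total <- 0
  v <- (1 + discount)^(-1 / cycles_per_year)
  vt <- 1
  for (t in seq_len(n)) {
    age <- start_age + (t - 1) / cycles_per_year
    alive <- alive * (1 - weekly_background_death_prob(age, sex_mix, lookup,
                                                       cycles_per_year))
    vt <- vt * v
    total <- total + alive * vt / cycles_per_year
  }
  total
}
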