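#' Published colony phenology medians
#'
#' Median colony departure and arrival dates of tracked murres by year
#' and sex (month-day strings, SD in days, sample sizes), as summarised
#' from the wet/dry logs of the Newfoundland deployments. Shipped as a
#' plain-text table for worked date-arithmetic examples.
#'
#' @return data.frame (year, sex, departure_md, departure_sd_days,
#'   departure_n, arrival_md, arrival_sd_days, arrival_n).
#' @export
load_phenology_medians <- function() {
  path <- system.file("extdata", "colony_phenology_medians.csv",
                      package = "murrelog", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(year = "character", sex = "character",
                                 departure_md = "character", arrival_md = "character"))
}

#' Day difference between two month-day dates
#'
#' Signed number of days from `md_b` to `md_a` ("MM-DD" strings placed
#' in a common non-leap reference year).
#'
#' @param md_a,md_b "MM-DD" strings.
#' @return numeric days (`md_a - md_b`).
#' @export
md_difference_days <- function(md_a, md_b) {
  as.numeric(as.Date(paste0("2010-", md_a)) - as.Date(paste0("2010-", md_b)))
}

#' Female-minus-male phenology differences
#'
#' For each year (and the overall row) of the published medians,
#' computes the female-minus-male difference in days for departure and
#' arrival: females leave the colony about a week after males and
#' return about six days later in spring.
#'
#' @param medians table from [load_phenology_medians()].
#' @return data.frame (year, departure_diff_days, arrival_diff_days).
#' @export
phenology_sex_differences <- function(medians = load_phenology_medians()) {
  years <- unique(medians$year)
  out <- do.call(rbind, lapply(years, function(y) {
    f <- medians[medians$year == y & medians$sex == "F", ]
    m <- medians[medians$year == y & medians$sex == "M", ]
    data.frame(
      year = y,
      departure_diff_days = if (nzchar(f$departure_md) && nzchar(m$departure_md))
        md_difference_days(f$departure_md, m$departure_md) else NA_real_,
      arrival_diff_days = if (!is.na(f$arrival_md) && !is.na(m$arrival_md) &&
                              nzchar(f$arrival_md) && nzchar(m$arrival_md))
        md_difference_days(f$arrival_md, m$arrival_md) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
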