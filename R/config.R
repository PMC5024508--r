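# Country-configuration IO. The on-disk format is YAML with a fixed schema;
# any scalar may be written as a percentage string with an explicit "%"
# suffix ("24.5%"), which is converted to a fraction on read. Unknown keys
# are rejected by name so typos cannot silently fall back to defaults.

config_profile_keys <- c("name", "year", "population", "prevalence",
                         "pct_agriculture", "labor_participation",
                         "death_fraction")
config_status_keys <- c("smokefree_coverage", "smokefree_enforcement",
                        "cessation_nrt", "cessation_rx_meds",
                        "cessation_provision", "cessation_quitline",
                        "media_tier", "marketing_tier",
                        "marketing_enforcement", "warning_tier",
                        "excise_share", "vat_rate", "publicity_level")

parse_percent <- function(x, field) {
  if (is.character(x) && length(x) == 1L && grepl("%\\s*$", x)) {
    v <- suppressWarnings(as.numeric(sub("%\\s*$", "", x)))
    if (is.na(v)) stop_field(field, "not a valid percentage")
    return(v / 100)
  }
  x
}

# apply percent parsing recursively to a named scalar-or-list value
parse_values <- function(x, field) {
  if (is.list(x)) {
    out <- lapply(names(x), function(k) parse_values(x[[k]], paste(field, k, sep = ".")))
    names(out) <- names(x)
    return(out)
  }
  parse_percent(x, field)
}

#' Read a country configuration file
#'
#' Parses a YAML country configuration into a validated
#' [country_profile()] / [policy_status()] pair, plus any
#' `price_increase_override` and effect-parameter overrides (`params:`
#' block, merged by [default_effect_params()]). Percent-suffixed strings
#' are accepted anywhere a fraction is expected. Unknown keys raise an
#' error naming the key; invalid values raise an error naming the field and
#' the violated constraint.
#'
#' @param path path to a YAML configuration (see the packaged example,
#'   `system.file("extdata", "israel.yaml", package = "mpowersim")`).
#' @return list with `profile`, `status`, `price_increase_override`
#'   (or `NULL`), and `params_overrides` (or `NULL`).
#' @examples
#' cfg <- read_config(system.file("extdata", "israel.yaml", package = "mpowersim"))
#' cfg$profile$name
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c(config_profile_keys, "policy", "price_increase_override", "params")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop(sprintf("unknown key '%s' in %s", bad[[1]], path), call. = FALSE)
  }
  missing <- setdiff(c(setdiff(config_profile_keys, "death_fraction"), "policy"), names(raw))
  if (length(missing)) {
    stop(sprintf("missing required key '%s' in %s", missing[[1]], path), call. = FALSE)
  }
  bad_pol <- setdiff(names(raw$policy), config_status_keys)
  if (length(bad_pol)) {
    stop(sprintf("unknown key 'policy.%s' in %s", bad_pol[[1]], path), call. = FALSE)
  }
  raw <- parse_values(raw, "config")

  as_gender_vec <- function(x, field) {
    if (!is.list(x) || is.null(names(x))) stop_field(field, "must map gender to value")
    unlist(x)
  }
  df <- raw$death_fraction %||% list(lower = 0.50, upper = 0.65)
  profile <- country_profile(
    name = raw$name, year = raw$year,
    population = as_gender_vec(raw$population, "population"),
    prevalence = as_gender_vec(raw$prevalence, "prevalence"),
    pct_agriculture = raw$pct_agriculture,
    labor_participation = as_gender_vec(raw$labor_participation, "labor_participation"),
    death_fraction_lower = df$lower %||% 0.50,
    death_fraction_upper = df$upper %||% 0.65
  )
  pol <- raw$policy
  pol$cessation_quitline <- isTRUE(pol$cessation_quitline)
  status <- do.call(policy_status, pol)
  list(profile = profile, status = status,
       price_increase_override = raw$price_increase_override,
       params_overrides = raw$params)
}

#' Write a country configuration file
#'
#' Serializes a profile/status pair to the YAML schema [read_config()]
#' reads; a read-back of the written file is value-identical.
#'
#' @param profile a [country_profile()].
#' @param status a [policy_status()].
#' @param path output path.
#' @param price_increase_override optional pinned relative price increase to
#'   carry in the file.
#' @return `path`, invisibly.
#' @export
write_config <- function(profile, status, path, price_increase_override = NULL) {
  cfg <- list(
    name = profile$name, year = profile$year,
    population = as.list(profile$population),
    prevalence = as.list(profile$prevalence),
    pct_agriculture = profile$pct_agriculture,
    labor_participation = as.list(profile$labor_participation),
    death_fraction = list(lower = profile$death_fraction_lower,
                          upper = profile$death_fraction_upper),
    policy = unclass(status)
  )
  if (!is.null(price_increase_override)) {
    cfg$price_increase_override <- price_increase_override
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Write a projection report to CSV or JSON
#'
#' The CSV variant has one row per scenario with the report's columns in
#' table order (effects as fractions, counts as integers); the JSON variant
#' additionally carries the baseline block and round-trips through
#' [read_report()] value-identically. Output is deterministic for a fixed
#' report.
#'
#' @param report a `projection_report` from [build_report()].
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  } else {
    b <- attr(report, "baseline")
    for (f in grep("by_gender|prevalence", names(b), value = TRUE)) {
      b[[f]] <- as.list(b[[f]]) # keep gender names through JSON
    }
    payload <- list(baseline = b, scenarios = as.data.frame(report))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a JSON projection report written by [write_report()]
#'
#' @param path path to a JSON report.
#' @return a `projection_report`.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  report <- payload$scenarios
  b <- payload$baseline
  for (f in grep("by_gender|prevalence", names(b), value = TRUE)) b[[f]] <- unlist(b[[f]])
  attr(report, "baseline") <- b
  class(report) <- c("projection_report", "data.frame")
  report
}
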