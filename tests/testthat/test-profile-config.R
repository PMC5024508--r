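test_that("profile and status validation rejects inadmissible values by field name", {
  ok <- israel_profile()
  expect_error(country_profile("x", 2020, c(male = 1e6, female = 1e6),
                               c(male = 1.5, female = 0.1), 0.02,
                               c(male = 0.7, female = 0.6)),
               "prevalence")
  expect_error(country_profile("x", 2020, c(male = 0, female = 1e6),
                               c(male = 0.2, female = 0.1), 0.02,
                               c(male = 0.7, female = 0.6)),
               "population")
  expect_error(country_profile("x", 2020, c(male = 1e6, female = 1e6),
                               c(male = 0.2, female = 0.1), 0.02,
                               c(male = 0.7, female = 0.6),
                               death_fraction_lower = 0.7,
                               death_fraction_upper = 0.6),
               "death_fraction_lower")
  s <- unclass(ok$status)
  s$smokefree_enforcement <- 11
  expect_error(do.call(policy_status, s), "smokefree_enforcement")
  s <- unclass(ok$status)
  s$marketing_tier <- "total"
  expect_error(do.call(policy_status, s), "marketing_tier")
  s <- unclass(ok$status)
  s$excise_share <- 0.95 # with 17% VAT this exceeds the whole price
  expect_error(do.call(policy_status, s), "excise_share")
})

test_that("publicity presets map to their fractions and fractions pass through", {
  s <- unclass(israel_profile()$status)
  presets <- c(none = 0, low = 0.25, moderate = 0.5, high = 1.0)
  for (nm in names(presets)) {
    s$publicity_level <- nm
    expect_equal(do.call(policy_status, s)$publicity_level, presets[[nm]])
  }
  s$publicity_level <- 0.33
  expect_equal(do.call(policy_status, s)$publicity_level, 0.33)
})

test_that("the packaged Israel config file matches the in-code fixture", {
  cfg <- read_config(system.file("extdata", "israel.yaml", package = "mpowersim"))
  isr <- israel_profile()
  expect_equal(cfg$profile, isr$profile)
  expect_equal(cfg$status, isr$status)
  expect_equal(cfg$price_increase_override, isr$price_increase_override)
})

test_that("config round-trips value-identically, including percent parsing", {
  isr <- israel_profile()
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  write_config(isr$profile, isr$status, path,
               price_increase_override = isr$price_increase_override)
  back <- read_config(path)
  expect_equal(back$profile, isr$profile)
  expect_equal(back$status, isr$status)
  expect_equal(back$price_increase_override, 0.39)

  gen <- generate_profile(42)
  write_config(gen$profile, gen$status, path)
  back <- read_config(path)
  expect_equal(back$profile, gen$profile)
  expect_equal(back$status, gen$status)
})

test_that("malformed configs fail with the offending key or field named", {
  isr <- israel_profile()
  src <- tempfile(fileext = ".yaml")
  on.exit(unlink(src))
  write_config(isr$profile, isr$status, src)

  mangle <- function(f) {
    cfg <- yaml::read_yaml(src)
    p <- tempfile(fileext = ".yaml")
    yaml::write_yaml(f(cfg), p)
    p
  }
  expect_error(read_config(mangle(function(c) { c$bogus <- 1; c })),
               "unknown key 'bogus'")
  expect_error(read_config(mangle(function(c) { c$prevalence$male <- 1.5; c })),
               "prevalence")
  expect_error(read_config(mangle(function(c) { c$policy$smokefree_enforcement <- 11; c })),
               "smokefree_enforcement")
  expect_error(read_config(mangle(function(c) { c$policy$media_tyre <- "low"; c })),
               "media_tyre")
  expect_error(read_config(mangle(function(c) { c$prevalence <- NULL; c })),
               "prevalence")
  expect_error(read_config(file.path(tempdir(), "absent.yaml")), "not found")
})
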