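test_that("currency conversion at the survey-period rate is exact and invertible", {
  expect_equal(convert_currency(1600), 1)
  expect_equal(convert_currency(0), 0)
  expect_equal(round(convert_currency(656), 2), 0.41)
  expect_error(convert_currency(-5), "negative")
  expect_error(convert_currency(100, rate = 0), "positive")
  x <- c(0, 123.45, 99999)
  expect_equal(convert_currency(x, 1600) * 1600, x)
})

test_that("round-trip convention doubles travel components only, once", {
  s <- toy_survey(4)
  rt <- apply_convention(s, "round_trip")
  expect_equal(rt$records$travel_time_min, 2 * s$records$travel_time_min)
  expect_equal(rt$records$transport_cost_tzs, 2 * s$records$transport_cost_tzs)
  expect_equal(rt$records$waiting_time_min, s$records$waiting_time_min)
  expect_equal(rt$records$consultation_time_min, s$records$consultation_time_min)
  expect_equal(rt$records$medical_cost_tzs, s$records$medical_cost_tzs)
  expect_error(apply_convention(rt, "round_trip"), "refusing to double")
  expect_equal(apply_convention(s, "one_way")$records, s$records)
})

test_that("round-trip total time equals one-way total plus one-way travel", {
  s <- generate_survey(generator_config(seed = 40, n_patients = 300,
                                        n_facilities = 30,
                                        missing_rates = c(travel_time = 0,
                                                          waiting_time = 0,
                                                          consultation_time = 0,
                                                          transport_amount = 0,
                                                          medical_amount = 0)))
  rt <- apply_convention(s, "round_trip")
  total <- function(x) x$records$travel_time_min + x$records$waiting_time_min +
    x$records$consultation_time_min
  expect_equal(total(rt), total(s) + s$records$travel_time_min)
})

test_that("cost_summary reports complete-case mean, median and nonzero share", {
  cs <- cost_summary(survey_with_travel(c(0, 0, 0, 2)), "travel_time")
  expect_equal(cs$n, 4L)
  expect_equal(cs$mean, 0.5)
  expect_equal(cs$median, 0)
  expect_equal(cs$pct_nonzero, 25)
  s <- toy_survey(6)
  s$records$medical_cost_tzs <- c(NA, 0, 1600, 800, NA, 0)
  m <- cost_summary(s, "medical_cost")
  expect_equal(m$n, 4L)
  expect_equal(m$mean, (0 + 1 + 0.5 + 0) / 4)
  p <- cost_summary(s, "paid_medical")
  expect_equal(p$mean, 0.5)
})

test_that("synthetic gamma travel times reproduce the configured mean", {
  cfg <- generator_config(seed = 19, n_patients = 8000, n_facilities = 800)
  s <- generate_survey(cfg)
  cs <- cost_summary(s, "travel_time")
  expect_lt(abs(cs$mean - 30), 1)  # a + b/2 = 30; ~4 se of the gamma mean
})

test_that("share decomposition is symmetric, scale free, and fails on zero totals", {
  eq <- share_decomposition(c(travel_time = 3, waiting_time = 3))
  expect_equal(unname(eq$shares), c(0.5, 0.5))
  comp <- c(travel_time = 30.1, waiting_time = 46.7, consultation_time = 12.9)
  a <- share_decomposition(comp)
  b <- share_decomposition(10 * comp)
  expect_equal(a$shares, b$shares)
  expect_equal(sum(a$shares), 1, tolerance = 1e-12)
  expect_error(share_decomposition(c(x = 0, y = 0)), "zero total")
  expect_error(share_decomposition(c(x = -1, y = 2)), "negative")
  expect_error(share_decomposition(c(1, 2)), "named")
})

test_that("round-trip shares double the travel components and leave others", {
  comp <- c(travel_time = 30, waiting_time = 45, consultation_time = 15)
  rt <- share_decomposition(comp, "round_trip")
  expect_equal(unname(rt$components["travel_time"]), 60)
  expect_equal(unname(rt$components["waiting_time"]), 45)
  expect_equal(rt$total, 120)
  dc <- share_decomposition(c(transport_cost = 0.5, medical_cost = 0.25),
                            "round_trip")
  expect_equal(unname(dc$components), c(1, 0.25))
})

test_that("public-facility restriction filters exactly and errors when empty", {
  s <- toy_survey(6)  # ownership pattern public, public, fbo
  pub <- restrict_public(s)
  expect_equal(n_records(pub), 4L)
  expect_true(all(pub$records$ownership == "public"))
  s$records$ownership <- "private"
  expect_error(restrict_public(s), "no public-facility records")
  syn <- generate_survey(generator_config(seed = 23, n_patients = 1400,
                                          n_facilities = 150))
  frac <- n_records(restrict_public(syn)) / 1400
  expect_lt(abs(frac - 0.82), 0.05)
})

test_that("wealth-gradient outcomes yield a negative CI and positive poor-rich gap", {
  s <- generate_survey(generator_config(seed = 61, n_patients = 4000,
                                        n_facilities = 400))
  tab <- stratified_equity_table(s, "travel_time", "ses_quintile_extremes")
  expect_lt(tab$ci, 0)
  expect_gt(tab$gap, 0)
  expect_gt(tab$ratio, 1)
  expect_equal(tab$gap_stars, "***")
  res <- stratified_equity_table(s, "travel_time", "residence")
  expect_gt(res$gap, 0)  # rural residents are poorer, so travel longer
})

test_that("facility and service tables use the conventional reference groups", {
  s <- generate_survey(generator_config(seed = 62, n_patients = 2000,
                                        n_facilities = 200))
  own <- stratified_equity_table(s, "medical_cost", "ownership")
  expect_equal(own$stars[own$group == "public"], "(ref)")
  expect_setequal(own$group, c("public", "fbo", "private"))
  lev <- stratified_equity_table(s, "waiting_time", "level")
  expect_equal(lev$stars[lev$group == "hospital"], "(ref)")
  srv <- stratified_equity_table(s, "consultation_time", "service")
  expect_equal(srv$stars[srv$group == "anc"], "(ref)")
  expect_equal(sum(srv$n), cost_summary(s, "consultation_time")$n)
})

test_that("degenerate single-group stratifiers are rejected by name", {
  s <- toy_survey(6)
  s$records$residence <- "rural"
  expect_error(stratified_equity_table(s, "travel_time", "residence"),
               "single group")
  s2 <- toy_survey(6)
  s2$records$ownership <- "public"
  expect_error(stratified_equity_table(s2, "travel_time", "ownership"),
               "single group")
})

test_that("mode filter selects the subgroup feeding mode-specific rows", {
  s <- toy_survey(6)
  expect_equal(unique(filter_mode(s, "foot")$records$travel_mode), "foot")
  expect_error(filter_mode(exit_survey(within(toy_records(3),
                                              travel_mode <- "car")), "foot"),
               "no records")
})
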