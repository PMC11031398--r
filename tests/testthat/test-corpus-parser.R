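test_that("sentence segmentation respects abbreviations and decimals", {
  txt <- "Patient weighed 62.5 kg. Seen by dr. Jansen in 2001. Tremor e.g. at rest was noted! Recovered?"
  out <- split_history(txt)
  expect_length(out, 4)
  expect_match(out[1], "62.5 kg", fixed = TRUE)
  expect_match(out[2], "dr. Jansen", fixed = TRUE)
  expect_match(out[3], "e.g. at rest", fixed = TRUE)
})

test_that("sentence segmentation handles empty and whitespace input", {
  expect_identical(split_history(""), character(0))
  expect_identical(split_history("   "), character(0))
  expect_identical(split_history("One sentence without terminator"),
                   "One sentence without terminator")
})

test_that("literal years and ranges are resolved and expanded", {
  expect_identical(resolve_years("Tremor since 2003."), 2003L)
  expect_identical(resolve_years("Falls from 2005-2007."), 2005:2007)
  expect_identical(resolve_years("Falls from 2005 to 2007."), 2005:2007)
  expect_identical(resolve_years("Falls 1998–2000."), 1998:2000)
  expect_identical(sort(resolve_years("In 2001 and again in 2004.")),
                   c(2001L, 2004L))
})

test_that("back-referenced years do not anchor a sentence", {
  expect_identical(resolve_years("Worse in comparison to 2003."),
                   NA_integer_)
  expect_identical(resolve_years("In 2006 worse than in 2003."), 2006L)
  expect_identical(resolve_years("Weaker compared to 2001."), NA_integer_)
})

test_that("relative expressions resolve against the anchor year", {
  expect_identical(resolve_years("Confused during the last 2 years.",
                                 death_year = 2010), 2008:2010)
  expect_identical(resolve_years("Confused during the last 2 years.",
                                 preceding_year = 2005, death_year = 2010),
                   2003:2005)
  expect_identical(resolve_years("Falls in the last 6 months.",
                                 death_year = 2010), 2010L)
  expect_identical(resolve_years("Deaf at birth.", death_year = 2010,
                                 age_at_death = 80), 1930L)
  expect_identical(resolve_years("Confused during the last 2 years."),
                   NA_integer_)
})

test_that("years beyond death are warned about and dropped", {
  expect_warning(ys <- resolve_years("Tremor in 2012 and 2015.",
                                     death_year = 2013),
                 "beyond death")
  expect_identical(ys, 2012L)
})

test_that("sentences without anchors are year-unknown", {
  expect_identical(resolve_years("Often anxious and withdrawn."),
                   NA_integer_)
})

test_that("history parsing honours year section headers", {
  txt <- "2005:\nTremor at rest. Memory complaints since 2003.\nFalls reported.\nNo year here at all."
  df <- parse_history("D1", txt, death_year = 2010, age_at_death = 75)
  expect_equal(df$source_order, seq_len(nrow(df)))
  expect_equal(df$years[df$text == "Tremor at rest."], "2005")
  expect_equal(df$years[df$text == "Memory complaints since 2003."], "2003")
  expect_equal(df$years[df$text == "Falls reported."], "2005")
})

test_that("history parsing marks unanchored sentences as UNKNOWN", {
  df <- parse_history("D2", "Often anxious. Tremor in 2001.",
                      death_year = 2005)
  expect_equal(df$years, c("UNKNOWN", "2001"))
  empty <- parse_history("D3", "")
  expect_equal(nrow(empty), 0)
})

test_that("parser recovers planted years from rendered synthetic sentences", {
  sent <- render_sentences(nt_cohort, seed = 3)
  anchored <- sent[!is.na(sent$year), ]
  idx <- seq_len(min(200, nrow(anchored)))
  recovered <- vapply(idx, function(i) {
    ys <- resolve_years(anchored$text[i], death_year = 2030)
    length(ys) == 1 && !is.na(ys) && ys == anchored$year[i]
  }, logical(1))
  expect_true(all(recovered))
})
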