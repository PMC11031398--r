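test_that("sentence predictions collapse to deduplicated observations", {
  meta <- data.frame(donor_id = c("d1", "d1", "d1", "d2"),
                     year = c(2000L, 2000L, NA, 2001L))
  pred <- rbind(c(1, 0), c(1, 1), c(0, 1), c(1, 0))
  colnames(pred) <- c("tremor", "falls")
  ts <- collapse_predictions(meta, pred)
  obs <- ts$observations
  # two sentences flagging tremor@2000 for d1 collapse to one row
  expect_equal(nrow(obs[obs$donor_id == "d1" & obs$year == 2000 &
                          obs$attribute_id == "tremor", ]), 1)
  expect_equal(nrow(obs), 3)
  expect_true(all(obs$present == 1) && !any(obs$imputed))
  # the year-unknown falls prediction lands in the side table
  expect_equal(ts$unknown_year$donor_id, "d1")
  expect_equal(ts$unknown_year$attribute_id, "falls")
  expect_equal(ts$unknown_year$n_sentences, 1)
})

test_that("collapse derives ages from donor metadata", {
  meta <- data.frame(donor_id = "d1", year = 2000L)
  pred <- matrix(1, 1, 1, dimnames = list(NULL, "tremor"))
  dm <- data.frame(donor_id = "d1", death_year = 2010L, death_age = 80L)
  ts <- collapse_predictions(meta, pred, dm)
  expect_equal(ts$observations$age, 70L)
})

test_that("persistence imputation fills to death, is gated and idempotent", {
  traj <- data.frame(
    donor_id = c("prog", "prog", "psych"),
    year = c(2000L, 2003L, 2000L),
    age = c(70L, 73L, 50L),
    attribute_id = c("tremor", "anxiety", "tremor"),
    present = 1L, imputed = FALSE, stringsAsFactors = FALSE)
  dm <- data.frame(donor_id = c("prog", "psych"),
                   nd_codes = c("PD", "MDD"),
                   death_year = c(2005L, 2005L),
                   death_age = c(75L, 55L), stringsAsFactors = FALSE)
  out <- impute_persistence(traj, dm, nt_attr_ont, nt_nd_ont)
  tremor_prog <- out[out$donor_id == "prog" & out$attribute_id == "tremor", ]
  expect_equal(tremor_prog$year, 2000:2005)
  expect_equal(tremor_prog$imputed, c(FALSE, rep(TRUE, 5)))
  expect_equal(tremor_prog$age, 70:75)
  # anxiety is not neurodegeneration-associated: untouched
  expect_equal(sum(out$attribute_id == "anxiety"), 1)
  # psychiatric donors are not imputed
  expect_equal(sum(out$donor_id == "psych"), 1)
  # idempotent
  expect_identical(impute_persistence(out, dm, nt_attr_ont, nt_nd_ont), out)
})

test_that("imputation warns and skips donors without a death year", {
  traj <- data.frame(donor_id = "d", year = 2000L, age = 70L,
                     attribute_id = "tremor", present = 1L, imputed = FALSE,
                     stringsAsFactors = FALSE)
  dm <- data.frame(donor_id = "d", nd_codes = "PD",
                   death_year = NA_integer_, death_age = 75L)
  expect_warning(out <- impute_persistence(traj, dm, nt_attr_ont, nt_nd_ont),
                 "death year missing")
  expect_identical(out, traj)
})

test_that("cohort filters exclude donors with recorded reasons", {
  dm <- data.frame(
    donor_id = c("ok", "short", "old", "rare", "sparse", "ctrl"),
    nd_codes = c("AD", "AD", "AD", "PTSD", "AD", "CON"),
    autopsy_year = c(2000, 2000, 1990, 2000, 2000, 2000),
    n_chars = c(900, 400, 900, 900, 900, 900),
    stringsAsFactors = FALSE)
  traj <- do.call(rbind, lapply(c("ok", "short", "old", "rare"), function(d)
    data.frame(donor_id = d, year = 2000:2006, age = 70:76,
               attribute_id = "dementia", present = 1L, imputed = FALSE,
               stringsAsFactors = FALSE)))
  traj <- rbind(traj, data.frame(
    donor_id = "sparse", year = 2000:2002, age = 70:72,
    attribute_id = "dementia", present = 1L,
    imputed = c(FALSE, TRUE, TRUE), stringsAsFactors = FALSE))
  res <- filter_cohort(dm, traj, "modeling")
  expect_setequal(res$selected, c("ok", "ctrl"))
  reason_of <- function(d) res$exclusions$reason[res$exclusions$donor_id == d]
  expect_equal(reason_of("short"), "insufficient_characters")
  expect_equal(reason_of("old"), "autopsy_before_1997")
  expect_equal(reason_of("rare"), "diagnosis_not_in_panel")
  expect_equal(reason_of("sparse"), "fewer_than_min_observations")
  # counting imputed rows rescues the sparse donor (3 + nothing... still < 5)
  res2 <- filter_cohort(dm, traj, "modeling", min_observations = 3,
                        count_imputed = TRUE)
  expect_true("sparse" %in% res2$selected)
  # PTSD is admitted for clustering but not for modeling
  res3 <- filter_cohort(dm, traj, "clustering")
  expect_true("rare" %in% res3$selected)
})

test_that("filter results partition the cohort", {
  res <- filter_cohort(nt_cohort$donors, nt_trajectory, "clustering")
  expect_setequal(c(res$selected, res$exclusions$donor_id),
                  nt_cohort$donors$donor_id)
  expect_length(intersect(res$selected, res$exclusions$donor_id), 0)
})

test_that("trajectory export coarsens ages into 5-year bin midpoints", {
  traj <- data.frame(donor_id = "d", year = 2000:2002, age = c(71L, 74L, 99L),
                     attribute_id = "tremor", present = 1L, imputed = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_trajectory(traj, path, coarsen_ages = TRUE)
  back <- read.delim(path)
  expect_equal(back$age, c(72, 72, 97))
  expect_true(all(back$age_coarsened))
  unlink(path)
})
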