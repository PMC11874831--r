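map <- read_condition_map()
wts <- weight_table(map)

test_that("ICD-10 mapping handles empty sets, lookups and hierarchies", {
  p0 <- map_icd10_to_conditions(character(0), map)
  expect_equal(p0$count, 0)
  expect_true(all(p0$indicators == 0))

  p1 <- map_icd10_to_conditions("I10", map)
  expect_equal(p1$count, 1)
  expect_equal(unname(p1$indicators["hypertension"]), 1L)

  # mild + severe liver codes: severe wins, mild forced off
  p2 <- map_icd10_to_conditions(c("K70.0", "K72.9"), map)
  expect_equal(unname(p2$indicators["severe_liver"]), 1L)
  expect_equal(unname(p2$indicators["mild_liver"]), 0L)
  expect_equal(p2$count, 1)

  # diabetes hierarchy
  p3 <- map_icd10_to_conditions(c("E11.9", "E11.2"), map)
  expect_equal(unname(p3$indicators["diabetes_comp"]), 1L)
  expect_equal(unname(p3$indicators["diabetes"]), 0L)
})

test_that("matching is case- and dot-insensitive; bad and index codes skip", {
  a <- map_icd10_to_conditions("i10", map)$indicators
  b <- map_icd10_to_conditions("I10.", map)$indicators
  expect_equal(a, b)
  expect_warning(p <- map_icd10_to_conditions(c("I10", "9xyz"), map),
                 "invalid ICD-10")
  expect_equal(p$count, 1)
  # the index cancer's own codes never count as comorbidity
  expect_equal(map_icd10_to_conditions(c("C34.9", "C50.1", "D37.1"),
                                       map)$count, 0)
})

test_that("cohort-level profiling agrees with per-patient mapping", {
  spec <- cohort_spec(n_patients = 80, seed = 13)
  adm <- generate_cohort(spec)
  patients <- collapse_to_patients(adm)
  prof <- profile_cohort(patients, map)
  for (i in sample(nrow(patients), 20)) {
    single <- map_icd10_to_conditions(patients$union_dx[[i]], map)
    expect_equal(unname(prof[i, ]), unname(single$indicators),
                 label = patients$patient_id[i])
  }
})

test_that("CCI score sums configured weights with severity grading", {
  p0 <- map_icd10_to_conditions(character(0), map)
  r0 <- compute_cci_score(p0, wts)
  expect_equal(r0$cci_score, 0L)
  expect_equal(as.character(r0$severity), "none")

  p <- map_icd10_to_conditions(c("E11.9", "N18.5"), map)  # diabetes + renal
  r <- compute_cci_score(p, wts)
  expect_equal(r$cci_score, unname(wts["diabetes"] + wts["renal"]))
  expect_equal(r$cci_score, 3L)
  expect_equal(as.character(r$severity), "moderate")

  expect_error(compute_cci_score(p, wts[setdiff(names(wts), "renal")]),
               "configuration error")
})

test_that("scores equal the brute-force oracle on random profiles", {
  ids <- condition_ids(map)
  set.seed(42)
  for (i in 1:200) {
    ind <- setNames(rbinom(length(ids), 1, 0.3), ids)
    # respect hierarchies so the profile is valid
    if (ind["severe_liver"] == 1) ind["mild_liver"] <- 0L
    if (ind["diabetes_comp"] == 1) ind["diabetes"] <- 0L
    prof <- structure(list(patient_id = "X", indicators = ind,
                           count = sum(ind)),
                      class = "comorbidity_profile")
    expect_equal(compute_cci_score(prof, wts)$cci_score,
                 oracle_score(ind, wts))
  }
})

test_that("score is additive over singleton profiles", {
  ids <- condition_ids(map)
  set.seed(7)
  for (i in 1:20) {
    ind <- setNames(rbinom(length(ids), 1, 0.3), ids)
    if (ind["severe_liver"] == 1) ind["mild_liver"] <- 0L
    if (ind["diabetes_comp"] == 1) ind["diabetes"] <- 0L
    total <- compute_cci_score(
      structure(list(patient_id = "X", indicators = ind, count = sum(ind)),
                class = "comorbidity_profile"), wts)$cci_score
    singles <- sum(vapply(names(ind)[ind == 1], function(nm) {
      s <- setNames(integer(length(ids)), ids); s[nm] <- 1L
      compute_cci_score(structure(list(patient_id = "X", indicators = s,
                                       count = 1L),
                                  class = "comorbidity_profile"),
                        wts)$cci_score
    }, integer(1)))
    expect_equal(total, singles)
  }
})

test_that("severity grading is monotone with none iff score zero", {
  g <- severity_grade(0:8)
  expect_equal(as.character(g[1]), "none")
  expect_true(all((0:8 == 0) == (g == "none")))
  expect_true(all(diff(as.integer(g)) >= 0))
  expect_error(severity_grade(-1), "non-negative")
})
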