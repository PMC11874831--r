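test_that("CSV round trip recovers the generated cohort", {
  spec <- cohort_spec(n_patients = 100, seed = 8)
  adm <- generate_cohort(spec)
  f <- tempfile(fileext = ".csv")
  write_admissions_csv(adm, f)
  back <- read_admissions(f)
  expect_equal(nrow(back), nrow(adm))
  expect_equal(length(unique(back$patient_id)), 100)
  expect_equal(back$admission_date, adm$admission_date)
  expect_equal(back$secondary_dx, adm$secondary_dx)
  expect_equal(back$total_cost, adm$total_cost)
  expect_equal(nrow(attr(back, "diagnostics")), 0)
})

test_that("empty file with valid header parses to an empty cohort", {
  f <- tempfile(fileext = ".csv")
  writeLines(paste("patient_id,admission_date,discharge_date,age,sex",
                   "cancer_type,cancer_stage,primary_dx,secondary_dx",
                   sep = ","), f)
  expect_equal(nrow(read_admissions(f)), 0)
})

test_that("schema and row-level violations are handled per contract", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,age", "P1,60"), f)
  expect_error(read_admissions(f), "schema error")

  adm <- rbind(
    make_admission(patient_id = "OK"),
    make_admission(patient_id = "OVERFLOW",
                   secondary_dx = paste(sprintf("I1%d", 0:18),
                                        collapse = ";")),
    make_admission(patient_id = "BADDATE"),
    make_admission(patient_id = "BADSEX", sex = "unknown"))
  f2 <- tempfile(fileext = ".csv")
  write_admissions_csv(adm, f2)
  txt <- readLines(f2)
  txt[4] <- sub("2018-03-01", "not-a-date", txt[4])
  writeLines(txt, f2)
  got <- read_admissions(f2)
  diag <- attr(got, "diagnostics")
  expect_equal(got$patient_id, "OK")
  expect_setequal(diag$reason,
                  c("secondary_dx overflow", "malformed admission_date",
                    "unknown sex"))
})

test_that("wide dx2..dx19 dialect is accepted", {
  f <- tempfile(fileext = ".csv")
  adm <- make_admission()
  adm$secondary_dx <- NULL
  adm$dx2 <- "I10"; adm$dx3 <- "E11.9"
  adm$admission_date <- format(adm$admission_date)
  adm$discharge_date <- format(adm$discharge_date)
  write.csv(adm, f, row.names = FALSE)
  got <- read_admissions(f, dialect = list(secondary = "wide"))
  expect_equal(got$secondary_dx, "I10;E11.9")
})

test_that("collapse_to_patients unions diagnoses and sums cost missing-aware", {
  one <- make_admission(secondary_dx = "I10")
  p1 <- collapse_to_patients(one)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$n_admissions, 1)
  expect_setequal(p1$union_dx[[1]], c("C34.9", "I10"))
  expect_equal(p1$total_cost, one$total_cost)

  two <- make_patient_admissions("P2", 2)
  two$secondary_dx <- c("I10", "I10;E11.9")
  p2 <- collapse_to_patients(two)
  expect_setequal(p2$union_dx[[1]], c("C34.9", "I10", "E11.9"))
  expect_equal(p2$total_cost, 100000)

  two$total_cost[2] <- NA
  p2m <- collapse_to_patients(two)
  expect_true(is.na(p2m$total_cost) && p2m$cost_missing)

  many <- do.call(rbind, lapply(1:50, function(i)
    make_patient_admissions(sprintf("P%02d", i), 3)))
  pm <- collapse_to_patients(many)
  expect_equal(nrow(pm), 50)
  expect_true(all(pm$n_admissions == 3))
})

test_that("conflicting demographics warn and resolve to first admission", {
  two <- make_patient_admissions("P9", 2)
  two$age <- c(60, 61)
  expect_warning(p <- collapse_to_patients(two), "first admission")
  expect_equal(p$age, 60)
})

test_that("inclusion/exclusion rules fire in order with conserved counts", {
  adm <- rbind(
    make_patient_admissions("KEEP", 2),                       # all rules pass
    make_admission(patient_id = "SINGLE"),                    # 1 admission
    make_patient_admissions("WRONGCANCER", 2,
                            cancer_type = "liver"),
    make_patient_admissions("EARLY", 2),
    make_patient_admissions("MALEBREAST", 2, sex = "male",
                            cancer_type = "breast"),
    make_patient_admissions("SMALLCELL", 2,
                            histology = "small cell carcinoma"))
  adm$admission_date[adm$patient_id == "EARLY"] <-
    as.Date(c("2016-01-01", "2016-02-10"))
  res <- apply_inclusion_exclusion(adm)
  r <- res$report
  expect_equal(res$patients$patient_id, "KEEP")
  expect_equal(r$excluded_single_admission, 1)
  expect_equal(r$excluded_cancer_type, 1)
  expect_equal(r$excluded_date_window, 1)
  expect_equal(r$excluded_histology, 2)   # male breast + small cell
  expect_equal(r$final_patients,
               r$input_patients - r$excluded_cancer_type -
                 r$excluded_date_window - r$excluded_histology -
                 r$excluded_single_admission)
})

test_that("filtering is idempotent and order independent", {
  spec <- cohort_spec(n_patients = 120, seed = 44)
  adm <- generate_cohort(spec)
  res1 <- apply_inclusion_exclusion(adm)
  res2 <- apply_inclusion_exclusion(res1$admissions)
  expect_setequal(res2$patients$patient_id, res1$patients$patient_id)
  expect_equal(res2$report$final_patients, res1$report$final_patients)

  set.seed(1)
  shuffled <- adm[sample(nrow(adm)), , drop = FALSE]
  res3 <- apply_inclusion_exclusion(shuffled)
  expect_setequal(res3$patients$patient_id, res1$patients$patient_id)
})
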