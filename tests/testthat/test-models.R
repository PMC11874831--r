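test_that("treatment recoding follows the union rule", {
  pts <- data.frame(patient_id = c("A", "B", "C", "D"),
                    surgery = c(TRUE, FALSE, FALSE, FALSE),
                    chemotherapy = c(FALSE, FALSE, TRUE, FALSE),
                    radiotherapy = FALSE,
                    targeted = c(FALSE, FALSE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  tr <- recode_treatments(pts)
  expect_equal(tr$conventional_treatment, c(1L, 0L, 1L, 0L))
  expect_equal(tr$targeted_therapy, c(0L, 0L, 1L, 0L))
  # absent flags count as zero
  tr2 <- recode_treatments(data.frame(patient_id = "X"))
  expect_equal(tr2$conventional_treatment, 0L)
})

test_that("mean imputation preserves the observed mean exactly", {
  expect_equal(as.numeric(impute_cost(c(1, 2, 3))), c(1, 2, 3))
  got <- impute_cost(c(100, NA, 300))
  expect_equal(as.numeric(got), c(100, 200, 300))
  expect_equal(attr(got, "imputed"), c(FALSE, TRUE, FALSE))
  expect_equal(attr(got, "imputation_mean"), 200)
  expect_error(impute_cost(c(NA_real_, NA_real_)), "all costs missing")

  set.seed(2)
  for (i in 1:20) {
    x <- rlnorm(200, 11, 0.7)
    x[runif(200) < 0.1] <- NA
    if (!anyNA(x) || all(is.na(x))) next
    expect_equal(mean(impute_cost(x)), mean(x, na.rm = TRUE))
  }
})

make_frame <- function(n, p_outcome_cluster, p_outcome_ref, seed = 1) {
  set.seed(seed)
  in_cl <- rep(c(1L, 0L), each = n / 2)
  data.frame(
    patient_id = as.character(seq_len(n)),
    conventional_treatment = rbinom(n, 1, ifelse(in_cl == 1,
                                                 p_outcome_cluster,
                                                 p_outcome_ref)),
    targeted_therapy = 0L, cost = rlnorm(n, 11, 0.5),
    cost_imputed = FALSE, age = round(rnorm(n, 60, 10)),
    sex = sample(c("male", "female"), n, TRUE),
    education = sample(c("primary", "secondary", "tertiary"), n, TRUE),
    insured = TRUE, married = TRUE, residency = "urban",
    cancer_type = "lung",
    cancer_stage = sample(c("I", "II", "III", "IV"), n, TRUE),
    comorbidity_count = in_cl, cluster = ifelse(in_cl == 1, "a+b", "none"),
    stringsAsFactors = FALSE)
}

test_that("unadjusted 2x2 logistic equals the closed-form odds ratio", {
  set.seed(10)
  for (i in 1:25) {
    tab <- matrix(sample(5:40, 4, replace = TRUE), 2)  # a b / c d
    y <- c(rep(1, tab[1, 1]), rep(0, tab[1, 2]),
           rep(1, tab[2, 1]), rep(0, tab[2, 2]))
    x <- c(rep(1, sum(tab[1, ])), rep(0, sum(tab[2, ])))
    frame <- data.frame(
      patient_id = as.character(seq_along(y)),
      conventional_treatment = y, targeted_therapy = 0L,
      cost = 1, cost_imputed = FALSE, age = 60, sex = "male",
      education = "primary", insured = TRUE, married = TRUE,
      residency = "urban", cancer_type = "lung", cancer_stage = "II",
      comorbidity_count = x, cluster = ifelse(x == 1, "a+b", "none"),
      stringsAsFactors = FALSE)
    res <- fit_cluster_models(frame, covariates = character(0),
                              outcomes = "conventional_treatment",
                              reference = "no_comorbidity")
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    expect_equal(res$exp_estimate, or, tolerance = 1e-6)
  }
})

test_that("constant outcomes and undersized clusters are not fitted", {
  fr <- make_frame(100, 1, 1)
  fr$conventional_treatment <- 1L
  res <- fit_cluster_models(fr, covariates = character(0),
                            outcomes = "conventional_treatment")
  expect_false(res$estimable)
  expect_match(res$note, "constant")

  small <- make_frame(100, 0.7, 0.5)
  small$cluster[small$cluster == "a+b"] <- "none"
  small$cluster[1:5] <- "a+b"
  expect_equal(nrow(fit_cluster_models(small, min_cluster_n = 10)), 0)
})

test_that("separation is flagged rather than raised", {
  fr <- make_frame(60, 1, 0.4)
  fr$conventional_treatment[fr$cluster == "a+b"] <- 1L
  res <- fit_cluster_models(fr, covariates = character(0),
                            outcomes = "conventional_treatment")
  expect_false(res$estimable)
  expect_match(res$note, "separation")
})

test_that("null-effect CIs cover zero at the nominal rate", {
  reps <- 200L
  cover <- 0L
  fitted <- 0L
  for (r in seq_len(reps)) {
    fr <- make_frame(2000, 0.6, 0.6, seed = 9000 + r)
    res <- fit_cluster_models(fr, covariates = covariate_preset("full"),
                              outcomes = "conventional_treatment")
    if (nrow(res) == 1 && res$estimable) {
      fitted <- fitted + 1L
      if (res$ci_lo <= 0 && res$ci_hi >= 0) cover <- cover + 1L
    }
  }
  expect_gt(fitted, 190)
  expect_gt(cover / fitted, 0.90)
  expect_lt(cover / fitted, 0.99)
})

test_that("estimates and CIs are ordered, exponentials positive", {
  fr <- make_frame(400, 0.75, 0.5, seed = 77)
  res <- fit_cluster_models(fr, outcomes = c("conventional_treatment",
                                             "cost"))
  ok <- res[res$estimable, ]
  expect_true(all(ok$ci_lo <= ok$estimate & ok$estimate <= ok$ci_hi))
  expect_true(all(ok$exp_estimate[ok$outcome != "cost"] > 0))
})

test_that("report table formats references, stars and gaps", {
  fr <- make_frame(400, 0.9, 0.4, seed = 3)
  res <- fit_cluster_models(fr, covariates = character(0),
                            outcomes = c("conventional_treatment",
                                         "targeted_therapy", "cost"))
  tab <- report_table(res)
  expect_equal(tab$cluster[1], "without identified cluster")
  expect_equal(tab$conventional_treatment[1], "1.00(reference)")
  expect_equal(nrow(tab), 2)  # reference + one cluster
  # targeted_therapy is constant zero -> "\" cell
  expect_equal(tab$targeted_therapy[2], "\\")
  # strongly significant conventional effect gets stars
  expect_match(tab$conventional_treatment[2], "\\*")
})
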