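#' Specify a synthetic inpatient cancer cohort
#'
#' Builds the parameter object for the synthetic electronic-health-record
#' generator. Defaults describe a five-cancer-type Chinese tertiary-hospital
#' inpatient cohort: marginal demographics (age 62.42 (SD 11.62) years,
#' ~50% female, 94.7% insured, 87.7% married, 65.0% urban), cancer-type and
#' stage mix, per-condition prevalences, four planted condition co-occurrence
#' blocks (hypertension-diabetes, CVD-PVD, mild liver-renal, CHF-COPD), a
#' log-normal total-cost model and logistic treatment assignment with
#' optional cluster-linked shifts.
#'
#' Condition co-occurrence is induced by a shared latent Bernoulli factor per
#' block: each member condition is drawn with an elevated probability when the
#' factor is on and a depressed one when it is off, calibrated so the marginal
#' prevalence is exact and the within-block pairwise correlation approaches
#' `rho` (loadings are clipped to the feasible range when a low prevalence
#' caps the attainable correlation; realized correlations are recorded in the
#' attribute `realized_rho` of the generated indicator matrix).
#'
#' @param n_patients Number of patients.
#' @param cancer_type_probs Named probability vector over
#'   lung/colon/rectal/breast/gastric; must sum to 1.
#' @param age_mean,age_sd Age distribution in years (normal, truncated to
#'   18..100).
#' @param sex_female_prob Probability of female sex, either a single number or
#'   a named vector per cancer type.
#' @param insured_prob,married_prob,urban_prob Bernoulli probabilities.
#' @param education_probs Named probability vector over
#'   primary/secondary/tertiary.
#' @param stage_probs Named probability vector over stages 0/I/II/III/IV.
#' @param condition_prevalence Named probability vector, condition id ->
#'   marginal prevalence.
#' @param blocks List of co-occurrence blocks, each
#'   `list(conditions = <ids>, rho = <target correlation in [0,1)>)`;
#'   blocks must be disjoint and all members present in
#'   `condition_prevalence`.
#' @param cost_log_mean,cost_log_sd Log-scale parameters of the log-normal
#'   total cost (log-RMB).
#' @param treatment_effects List of planted treatment shifts, each
#'   `list(conditions = <ids>, outcome = "conventional"|"targeted",
#'   shift = <log-odds>)`, applied to patients positive for all listed
#'   conditions.
#' @param cost_effects List of planted cost shifts, each
#'   `list(conditions = <ids>, shift = <RMB>)`.
#' @param missing_cost_prob Probability a patient's total cost is missing.
#' @param admissions_lambda Poisson rate: admissions per patient are
#'   `1 + Poisson(admissions_lambda)`.
#' @param date_start,date_end First-admission window (calendar dates).
#' @param seed Integer RNG seed; required for reproducible generation.
#' @return A validated object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 1000,
                        cancer_type_probs = c(lung = 0.3703, colon = 0.1222,
                                              rectal = 0.1247, breast = 0.1708,
                                              gastric = 0.2120),
                        age_mean = 62.42, age_sd = 11.62,
                        sex_female_prob = c(lung = 0.38, colon = 0.45,
                                            rectal = 0.42, breast = 0.99,
                                            gastric = 0.33),
                        insured_prob = 0.9468,
                        married_prob = 0.8774,
                        urban_prob = 0.6496,
                        education_probs = c(primary = 0.35, secondary = 0.45,
                                            tertiary = 0.20),
                        stage_probs = c(`0` = 0.0266, I = 0.2831, II = 0.2137,
                                        III = 0.2910, IV = 0.1856),
                        condition_prevalence = default_condition_prevalence(),
                        blocks = default_blocks(),
                        cost_log_mean = 10.915, cost_log_sd = 0.762,
                        treatment_effects = default_treatment_effects(),
                        cost_effects = default_cost_effects(),
                        missing_cost_prob = 0.05,
                        admissions_lambda = 2,
                        date_start = as.Date("2017-01-01"),
                        date_end = as.Date("2019-10-31"),
                        seed = 1L) {
  spec <- structure(
    list(n_patients = n_patients, cancer_type_probs = cancer_type_probs,
         age_mean = age_mean, age_sd = age_sd,
         sex_female_prob = sex_female_prob, insured_prob = insured_prob,
         married_prob = married_prob, urban_prob = urban_prob,
         education_probs = education_probs, stage_probs = stage_probs,
         condition_prevalence = condition_prevalence, blocks = blocks,
         cost_log_mean = cost_log_mean, cost_log_sd = cost_log_sd,
         treatment_effects = treatment_effects, cost_effects = cost_effects,
         missing_cost_prob = missing_cost_prob,
         admissions_lambda = admissions_lambda,
         date_start = as.Date(date_start), date_end = as.Date(date_end),
         seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Default marginal condition prevalences of the synthetic cohort
#'
#' Per-condition prevalences of the 15-condition roster in a 4,666-patient
#' inpatient cancer cohort (share of patients positive for each condition).
#' @return Named numeric vector.
#' @export
default_condition_prevalence <- function() {
  c(mi = 0.1565, chf = 0.0165, pvd = 0.0812, cvd = 0.0504,
    dementia = 0.0011, copd = 0.0767, peptic_ulcer = 0.0947,
    mild_liver = 0.2242, diabetes = 0.1590, diabetes_comp = 0.0105,
    paralysis = 0.0004, renal = 0.1760, severe_liver = 0.0193,
    aids = 0.0010, hypertension = 0.3204)
}

#' Default planted co-occurrence blocks
#'
#' The four cardiometabolic / organ-system pairs the pattern analysis is
#' expected to recover: hypertension-diabetes, cerebrovascular-peripheral
#' vascular, mild liver-renal, heart failure-COPD, each with target
#' within-block correlation 0.45.
#' @return List of blocks as used by [cohort_spec()].
#' @export
default_blocks <- function() {
  list(list(conditions = c("hypertension", "diabetes"), rho = 0.45),
       list(conditions = c("cvd", "pvd"), rho = 0.45),
       list(conditions = c("mild_liver", "renal"), rho = 0.45),
       list(conditions = c("chf", "copd"), rho = 0.45))
}

#' @rdname default_blocks
#' @export
default_treatment_effects <- function() {
  list(list(conditions = c("chf", "copd"), outcome = "conventional",
            shift = -1.38),
       list(conditions = c("cvd", "pvd"), outcome = "targeted",
            shift = -0.9))
}

#' @rdname default_blocks
#' @export
default_cost_effects <- function() {
  list(list(conditions = c("hypertension", "diabetes"), shift = 17000))
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  fail <- function(field, msg) stop("invalid cohort_spec field '", field,
                                    "': ", msg, call. = FALSE)
  if (length(spec$n_patients) != 1 || is.na(spec$n_patients) ||
      spec$n_patients < 0 || spec$n_patients != round(spec$n_patients))
    fail("n_patients", "must be a non-negative integer")
  for (f in c("cancer_type_probs", "education_probs", "stage_probs")) {
    p <- spec[[f]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      fail(f, "probabilities must be non-negative and sum to 1")
  }
  for (f in c("insured_prob", "married_prob", "urban_prob",
              "missing_cost_prob")) {
    p <- spec[[f]]
    if (length(p) != 1 || p < 0 || p > 1) fail(f, "must be in [0, 1]")
  }
  if (any(spec$sex_female_prob < 0 | spec$sex_female_prob > 1))
    fail("sex_female_prob", "must be in [0, 1]")
  if (length(spec$sex_female_prob) > 1 &&
      !all(names(spec$cancer_type_probs) %in% names(spec$sex_female_prob)))
    fail("sex_female_prob", "per-type probabilities must cover all types")
  prev <- spec$condition_prevalence
  if (is.null(names(prev)) || any(prev < 0 | prev > 1))
    fail("condition_prevalence", "must be named probabilities in [0, 1]")
  if (spec$age_sd <= 0) fail("age_sd", "must be positive")
  if (spec$cost_log_sd <= 0) fail("cost_log_sd", "must be positive")
  if (spec$admissions_lambda < 0) fail("admissions_lambda",
                                       "must be non-negative")
  seen <- character(0)
  for (b in spec$blocks) {
    if (is.null(b$conditions) || is.null(b$rho))
      fail("blocks", "each block needs 'conditions' and 'rho'")
    if (b$rho < 0 || b$rho >= 1)
      fail("blocks", "rho must lie in [0, 1)")
    miss <- setdiff(b$conditions, names(prev))
    if (length(miss))
      fail("blocks", paste0("conditions absent from condition_prevalence: ",
                            paste(miss, collapse = ", ")))
    if (length(intersect(seen, b$conditions)))
      fail("blocks", "blocks must be disjoint condition sets")
    seen <- c(seen, b$conditions)
  }
  for (e in spec$treatment_effects) {
    if (!e$outcome %in% c("conventional", "targeted"))
      fail("treatment_effects", "outcome must be conventional or targeted")
    if (!all(e$conditions %in% names(prev)))
      fail("treatment_effects", "unknown condition in effect pattern")
  }
  for (e in spec$cost_effects) {
    if (!all(e$conditions %in% names(prev)))
      fail("cost_effects", "unknown condition in effect pattern")
  }
  if (spec$date_end < spec$date_start) fail("date_end", "before date_start")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d patients, %d conditions, %d blocks, seed %d\n",
              x$n_patients, length(x$condition_prevalence),
              length(x$blocks), x$seed))
  invisible(x)
}

#' Draw a binary condition indicator matrix with planted blocks
#'
#' Low-level sampler behind [generate_cohort()]. Conditions outside any block
#' are independent Bernoulli draws at their marginal prevalence; conditions
#' within a block share a latent Bernoulli factor (on with probability equal
#' to the mean block prevalence) whose loadings are calibrated so marginals
#' are exact and pairwise within-block correlation approaches the block `rho`.
#'
#' @param n Number of patients (rows).
#' @param prevalence Named prevalence vector.
#' @param blocks Block list as in [cohort_spec()].
#' @return Integer 0/1 matrix `n x length(prevalence)` with condition ids as
#'   column names and attribute `realized_rho`: the calibrated within-block
#'   correlations actually attainable after loading clipping.
#' @export
simulate_condition_matrix <- function(n, prevalence, blocks = list()) {
  k <- length(prevalence)
  x <- matrix(0L, nrow = n, ncol = k,
              dimnames = list(NULL, names(prevalence)))
  in_block <- unlist(lapply(blocks, `[[`, "conditions"))
  free <- setdiff(names(prevalence), in_block)
  for (j in free) x[, j] <- stats::rbinom(n, 1L, prevalence[[j]])
  realized <- list()
  for (b in blocks) {
    p <- prevalence[b$conditions]
    q <- mean(p)
    delta <- sqrt(b$rho * p * (1 - p) / (q * (1 - q)))
    delta <- pmin(delta, p / q, (1 - p) / (1 - q))
    p_hi <- p + (1 - q) * delta
    p_lo <- p - q * delta
    L <- stats::rbinom(n, 1L, q)
    for (i in seq_along(b$conditions)) {
      pj <- ifelse(L == 1L, p_hi[i], p_lo[i])
      x[, b$conditions[i]] <- stats::rbinom(n, 1L, pj)
    }
    # calibrated pairwise correlation after clipping
    cp <- outer(delta, delta) * q * (1 - q) /
      outer(sqrt(p * (1 - p)), sqrt(p * (1 - p)))
    diag(cp) <- 1
    realized[[paste(b$conditions, collapse = "+")]] <- cp
  }
  attr(x, "realized_rho") <- realized
  x
}

# exemplar ICD-10 code emitted into diagnosis lists per active condition
condition_exemplar_codes <- function() {
  c(mi = "I21.9", chf = "I50.0", pvd = "I70.2", cvd = "I63.9",
    dementia = "F03", copd = "J44.1", peptic_ulcer = "K25.9",
    mild_liver = "K73.9", diabetes = "E11.9", diabetes_comp = "E11.2",
    paralysis = "G81.9", renal = "N18.5", severe_liver = "K72.1",
    aids = "B20", hypertension = "I10", connective_tissue = "M05.9")
}

cancer_primary_codes <- function() {
  c(lung = "C34.9", colon = "C18.9", rectal = "C20", breast = "C50.9",
    gastric = "C16.9")
}

cancer_departments <- function() {
  c(lung = "thoracic surgery", colon = "general surgery",
    rectal = "colorectal oncology", breast = "breast surgery",
    gastric = "oncology")
}

#' Generate a patient-level synthetic cohort table
#'
#' Draws one row per patient: demographics, cancer characteristics, binary
#' condition indicators (columns `cond_<id>`), treatment flags, total cost
#' and number of admissions. [generate_cohort()] expands this table to
#' admission level.
#'
#' @param spec A [cohort_spec()].
#' @param set_seed Seed the RNG from `spec$seed` first? Default `TRUE`.
#' @return A data.frame with `spec$n_patients` rows.
#' @export
generate_patients <- function(spec, set_seed = TRUE) {
  validate_cohort_spec(spec)
  if (set_seed) set.seed(spec$seed)
  n <- spec$n_patients
  types <- names(spec$cancer_type_probs)
  empty <- data.frame(patient_id = character(0))
  if (n == 0) return(empty)

  cancer_type <- sample(types, n, replace = TRUE,
                        prob = spec$cancer_type_probs)
  # truncated normal age via inverse-CDF on [18, 100]
  lo <- stats::pnorm(18, spec$age_mean, spec$age_sd)
  hi <- stats::pnorm(100, spec$age_mean, spec$age_sd)
  age <- round(stats::qnorm(stats::runif(n, lo, hi),
                            spec$age_mean, spec$age_sd))
  pf <- spec$sex_female_prob
  p_female <- if (length(pf) == 1) rep(pf, n) else unname(pf[cancer_type])
  sex <- ifelse(stats::runif(n) < p_female, "female", "male")
  insured <- stats::runif(n) < spec$insured_prob
  married <- stats::runif(n) < spec$married_prob
  residency <- ifelse(stats::runif(n) < spec$urban_prob, "urban", "rural")
  education <- sample(names(spec$education_probs), n, replace = TRUE,
                      prob = spec$education_probs)
  cancer_stage <- sample(names(spec$stage_probs), n, replace = TRUE,
                         prob = spec$stage_probs)

  ind <- simulate_condition_matrix(n, spec$condition_prevalence, spec$blocks)

  has_pattern <- function(conds) {
    if (!length(conds)) return(rep(TRUE, n))
    rowSums(ind[, conds, drop = FALSE]) == length(conds)
  }
  # treatment assignment: logistic baselines plus planted pattern shifts
  eta_conv <- rep(2.0, n)
  eta_targ <- -1.5 + 1.0 * (cancer_stage == "IV")
  for (e in spec$treatment_effects) {
    hit <- has_pattern(e$conditions)
    if (e$outcome == "conventional") eta_conv <- eta_conv + e$shift * hit
    else eta_targ <- eta_targ + e$shift * hit
  }
  conventional <- stats::runif(n) < stats::plogis(eta_conv)
  targeted <- stats::runif(n) < stats::plogis(eta_targ)
  # decompose conventional treatment into its component flags
  surgery <- conventional & (stats::runif(n) < 0.75)
  chemotherapy <- conventional & (stats::runif(n) < 0.60)
  radiotherapy <- conventional & (stats::runif(n) < 0.30)
  none <- conventional & !(surgery | chemotherapy | radiotherapy)
  surgery[none] <- TRUE

  cost <- stats::rlnorm(n, spec$cost_log_mean, spec$cost_log_sd)
  for (e in spec$cost_effects) {
    cost <- cost + e$shift * has_pattern(e$conditions)
  }
  cost <- pmax(cost, 0)
  cost[stats::runif(n) < spec$missing_cost_prob] <- NA_real_

  n_admissions <- 1L + stats::rpois(n, spec$admissions_lambda)

  out <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = age, sex = sex, insured = insured, married = married,
    residency = residency, education = education,
    cancer_type = cancer_type, histology = "adenocarcinoma",
    cancer_stage = cancer_stage,
    department = unname(cancer_departments()[cancer_type]),
    surgery = surgery, chemotherapy = chemotherapy,
    radiotherapy = radiotherapy, targeted = targeted,
    total_cost = cost, n_admissions = n_admissions,
    stringsAsFactors = FALSE)
  indf <- as.data.frame(ind)
  names(indf) <- paste0("cond_", colnames(ind))
  cbind(out, indf)
}

#' Generate an admission-level synthetic cohort
#'
#' Expands [generate_patients()] to one row per hospital admission. Each
#' admission carries the patient's demographics, a cancer primary diagnosis
#' code, the exemplar ICD-10 codes of the patient's active conditions as
#' secondary diagnoses (semicolon-joined, at most 18), per-admission dates
#' within the configured window and an even split of the patient's total cost
#' across admissions (all admissions of a patient missing-cost when the
#' patient's cost is missing).
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame of admissions, one row per admission, ordered by
#'   patient then admission date.
#' @export
generate_cohort <- function(spec) {
  pts <- generate_patients(spec, set_seed = TRUE)
  if (nrow(pts) == 0) {
    return(admissions_skeleton())
  }
  n <- nrow(pts)
  exemplar <- condition_exemplar_codes()
  cond_cols <- grep("^cond_", names(pts), value = TRUE)
  ids <- sub("^cond_", "", cond_cols)
  code_list <- apply(pts[, cond_cols, drop = FALSE] == 1, 1,
                     function(r) unname(exemplar[ids[r]]), simplify = FALSE)

  first_day <- as.integer(spec$date_start)
  last_day <- as.integer(spec$date_end)
  diag_day <- first_day + floor(stats::runif(n) * (last_day - first_day + 1))

  rows <- rep.int(seq_len(n), pts$n_admissions)
  adm_index <- sequence(pts$n_admissions)
  gaps <- floor(stats::runif(length(rows), 20, 80))
  gaps[adm_index == 1L] <- 0
  adm_day <- diag_day[rows] + ave(gaps, rows, FUN = cumsum)
  los <- floor(stats::runif(length(rows), 4, 15))

  cost_share <- pts$total_cost[rows] / pts$n_admissions[rows]

  adm <- data.frame(
    patient_id = pts$patient_id[rows],
    admission_date = as.Date(adm_day, origin = "1970-01-01"),
    discharge_date = as.Date(adm_day + los, origin = "1970-01-01"),
    age = pts$age[rows], sex = pts$sex[rows],
    insured = pts$insured[rows], married = pts$married[rows],
    residency = pts$residency[rows], education = pts$education[rows],
    cancer_type = pts$cancer_type[rows], histology = pts$histology[rows],
    cancer_stage = pts$cancer_stage[rows],
    department = pts$department[rows],
    primary_dx = unname(cancer_primary_codes()[pts$cancer_type[rows]]),
    secondary_dx = vapply(code_list[rows], paste, character(1),
                          collapse = ";"),
    surgery = pts$surgery[rows], chemotherapy = pts$chemotherapy[rows],
    radiotherapy = pts$radiotherapy[rows], targeted = pts$targeted[rows],
    total_cost = round(cost_share, 2),
    stringsAsFactors = FALSE)
  adm[order(adm$patient_id, adm$admission_date), , drop = FALSE]
}

admissions_skeleton <- function() {
  data.frame(patient_id = character(0), admission_date = as.Date(character(0)),
             discharge_date = as.Date(character(0)), age = integer(0),
             sex = character(0), insured = logical(0), married = logical(0),
             residency = character(0), education = character(0),
             cancer_type = character(0), histology = character(0),
             cancer_stage = character(0), department = character(0),
             primary_dx = character(0), secondary_dx = character(0),
             surgery = logical(0), chemotherapy = logical(0),
             radiotherapy = logical(0), targeted = logical(0),
             total_cost = numeric(0), stringsAsFactors = FALSE)
}

#' Pairwise correlation of condition indicators within a block
#'
#' Verification helper for planted co-occurrence structure: computes the
#' Pearson correlation matrix of the condition indicator columns named in
#' `block`, either from a patient-level table carrying `cond_<id>` columns
#' (as produced by [generate_patients()]) or from a bare 0/1 indicator
#' matrix with condition ids as column names.
#'
#' @param x Patient table or indicator matrix.
#' @param block Character vector of condition ids.
#' @return Symmetric correlation matrix over `block`. A zero-variance column
#'   yields `NA` off-diagonals; the diagonal is always 1.
#' @export
planted_block_correlation <- function(x, block) {
  if (is.data.frame(x)) {
    cols <- paste0("cond_", block)
    miss <- setdiff(cols, names(x))
    if (length(miss))
      stop("unknown condition(s): ",
           paste(sub("^cond_", "", miss), collapse = ", "))
    m <- as.matrix(x[, cols, drop = FALSE])
    colnames(m) <- block
  } else {
    m <- as.matrix(x)
    miss <- setdiff(block, colnames(m))
    if (length(miss))
      stop("unknown condition(s): ", paste(miss, collapse = ", "))
    m <- m[, block, drop = FALSE]
  }
  if (length(block) == 1) {
    return(matrix(1, 1, 1, dimnames = list(block, block)))
  }
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  r
}
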