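#' Recode treatment flags to binary outcomes
#'
#' Conventional treatment is positive if the patient received any of surgery,
#' chemotherapy or radiotherapy; targeted therapy is its own binary outcome.
#' Both may be positive.
#'
#' @param patients Patient-level data.frame with logical `surgery`,
#'   `chemotherapy`, `radiotherapy`, `targeted` columns (absent columns count
#'   as all-FALSE).
#' @return data.frame with `patient_id`, `conventional_treatment`,
#'   `targeted_therapy` (0/1 integers).
#' @export
recode_treatments <- function(patients) {
  get <- function(col) {
    if (col %in% names(patients)) isTRUE_vec(patients[[col]])
    else rep(FALSE, nrow(patients))
  }
  data.frame(
    patient_id = patients$patient_id,
    conventional_treatment =
      as.integer(get("surgery") | get("chemotherapy") | get("radiotherapy")),
    targeted_therapy = as.integer(get("targeted")),
    stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Mean-impute missing costs
#'
#' Missing entries are replaced by the mean of the observed entries, so the
#' post-imputation mean equals the observed mean exactly.
#'
#' @param costs Numeric vector (RMB), possibly with `NA`.
#' @return Numeric vector with attributes `imputed` (logical vector) and
#'   `imputation_mean`.
#' @export
impute_cost <- function(costs) {
  obs <- !is.na(costs)
  if (!any(obs)) stop("all costs missing; nothing to impute from")
  m <- mean(costs[obs])
  out <- costs
  out[!obs] <- m
  attr(out, "imputed") <- !obs
  attr(out, "imputation_mean") <- m
  out
}

#' Covariate adjustment presets
#'
#' `"full"` adjusts for age, sex, education level, insurance status,
#' marriage status and cancer stage (the default); `"core"` for age, sex,
#' education level, living area (residency) and marriage status.
#'
#' @param name Preset name.
#' @return Character vector of covariate column names.
#' @export
covariate_preset <- function(name = c("full", "core")) {
  switch(match.arg(name),
         full = c("age", "sex", "education", "insured", "married",
                  "cancer_stage"),
         core = c("age", "sex", "education", "residency", "married"))
}

#' Assemble the per-patient outcome frame
#'
#' Joins binary treatment outcomes, (optionally mean-imputed) cost, the
#' covariates and the patient's comorbidity-cluster membership into the
#' modelling frame.
#'
#' @param patients Patient-level data.frame.
#' @param profiles 0/1 indicator matrix aligned with `patients`.
#' @param cluster_set A [assign_patients()] result (exclusive assignment), or
#'   `NULL` for a frame with all memberships "none".
#' @param impute Mean-impute missing costs? Default `TRUE`; otherwise
#'   missing costs stay `NA` and cost models use observed costs only.
#' @return data.frame of class `outcome_frame`.
#' @export
build_outcome_frame <- function(patients, profiles, cluster_set = NULL,
                                impute = TRUE) {
  tr <- recode_treatments(patients)
  cost <- patients$total_cost
  imputed <- rep(FALSE, length(cost))
  if (impute && any(is.na(cost)) && any(!is.na(cost))) {
    cost <- impute_cost(cost)
    imputed <- attr(cost, "imputed")
  }
  membership <- if (is.null(cluster_set)) rep("none", nrow(patients))
                else unname(cluster_set$membership[patients$patient_id])
  out <- data.frame(
    patient_id = patients$patient_id,
    conventional_treatment = tr$conventional_treatment,
    targeted_therapy = tr$targeted_therapy,
    cost = as.numeric(cost), cost_imputed = imputed,
    age = patients$age, sex = patients$sex,
    education = patients$education, insured = patients$insured,
    married = patients$married, residency = patients$residency,
    cancer_type = patients$cancer_type,
    cancer_stage = patients$cancer_stage,
    comorbidity_count = as.integer(rowSums(profiles)),
    cluster = membership,
    stringsAsFactors = FALSE)
  class(out) <- c("outcome_frame", "data.frame")
  out
}

#' Fit per-cluster treatment and cost models
#'
#' Within one cancer-type stratum, each comorbidity cluster is compared
#' against the reference group on the subset cluster-members plus reference:
#' maximum-likelihood logistic regression for the binary treatment outcomes
#' (reporting the cluster log-odds coefficient with Wald 95% CI and its
#' exponential) and least-squares linear regression for cost (RMB
#' difference), adjusted for the configured covariates. Covariates constant
#' within a subset are dropped from that fit and recorded. A fit is flagged
#' not estimable when the outcome is constant in the subset or the fit shows
#' signs of separation.
#'
#' @param frame An [build_outcome_frame()] result.
#' @param stratum Cancer type to analyse (`NULL` = all patients as one
#'   stratum).
#' @param covariates Covariate column names; see [covariate_preset()].
#' @param outcomes Outcomes to fit.
#' @param min_cluster_n Minimum cluster size to attempt a fit (default 10).
#' @param reference `"no_comorbidity"` (default: patients with zero
#'   identified conditions) or `"no_cluster"` (patients outside every
#'   cluster).
#' @return data.frame of class `association_results`, one row per
#'   (cluster, outcome).
#' @export
fit_cluster_models <- function(frame, stratum = NULL,
                               covariates = covariate_preset("full"),
                               outcomes = c("conventional_treatment",
                                            "targeted_therapy", "cost"),
                               min_cluster_n = 10L,
                               reference = c("no_comorbidity",
                                             "no_cluster")) {
  reference <- match.arg(reference)
  dat <- if (is.null(stratum)) frame
         else frame[frame$cancer_type == stratum, , drop = FALSE]
  ref_sel <- if (reference == "no_comorbidity") dat$comorbidity_count == 0
             else dat$cluster == "none"
  clusters <- setdiff(unique(dat$cluster), "none")
  clusters <- clusters[order(match(clusters, dat$cluster))]
  rows <- list()
  for (cl in clusters) {
    in_cl <- dat$cluster == cl
    n_cl <- sum(in_cl)
    n_ref <- sum(ref_sel & !in_cl)
    if (n_cl < min_cluster_n || n_ref == 0) next
    sub <- dat[in_cl | (ref_sel & !in_cl), , drop = FALSE]
    sub$in_cluster <- as.integer(sub$cluster == cl)
    for (oc in outcomes) {
      rows[[paste(cl, oc)]] <-
        fit_one_model(sub, oc, covariates, cl,
                      stratum %||% "all", n_cl, n_ref)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stratum = character(0), cluster = character(0),
               outcome = character(0), estimate = numeric(0),
               ci_lo = numeric(0), ci_hi = numeric(0),
               exp_estimate = numeric(0), p_value = numeric(0),
               n_cluster = integer(0), n_reference = integer(0),
               estimable = logical(0), note = character(0))
  rownames(out) <- NULL
  class(out) <- c("association_results", "data.frame")
  out
}

fit_one_model <- function(sub, outcome, covariates, cluster_label,
                          stratum, n_cl, n_ref) {
  binary <- outcome != "cost"
  row <- data.frame(stratum = stratum, cluster = cluster_label,
                    outcome = outcome, estimate = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_,
                    exp_estimate = NA_real_, p_value = NA_real_,
                    n_cluster = n_cl, n_reference = n_ref,
                    estimable = FALSE, note = "",
                    stringsAsFactors = FALSE)
  y <- sub[[outcome]]
  if (!binary) {
    keep <- !is.na(y)
    sub <- sub[keep, , drop = FALSE]; y <- y[keep]
  }
  if (length(unique(y)) < 2) {
    row$note <- "not estimable: outcome constant"
    return(row)
  }
  # drop covariates without variation in this subset
  usable <- covariates[vapply(covariates, function(v)
    length(unique(sub[[v]][!is.na(sub[[v]])])) > 1, logical(1))]
  dropped <- setdiff(covariates, usable)
  fml <- stats::reformulate(c("in_cluster", usable), response = outcome)
  ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
  fit <- tryCatch({
    if (binary) stats::glm(fml, data = sub, family = stats::binomial(),
                           control = ctrl)
    else stats::lm(fml, data = sub)
  }, error = function(e) e, warning = function(w) {
    # refit while keeping the warning as a separation signal
    f <- suppressWarnings(
      if (binary) stats::glm(fml, data = sub, family = stats::binomial(),
                             control = ctrl)
      else stats::lm(fml, data = sub))
    attr(f, "fit_warning") <- conditionMessage(w)
    f
  })
  if (inherits(fit, "error")) {
    row$note <- paste("not estimable:", conditionMessage(fit))
    return(row)
  }
  co <- summary(fit)$coefficients
  if (!"in_cluster" %in% rownames(co) ||
      anyNA(co["in_cluster", 1:2])) {
    row$note <- "not estimable: singular design (in_cluster aliased)"
    return(row)
  }
  aliased <- names(which(is.na(stats::coef(fit))))
  est <- co["in_cluster", 1]; se <- co["in_cluster", 2]
  separated <- binary && (abs(est) > 10 || se > 50 ||
                            !is.null(attr(fit, "fit_warning")) &&
                              grepl("fitted probabilities",
                                    attr(fit, "fit_warning")))
  if (separated) {
    row$note <- "not estimable: separation"
    return(row)
  }
  z <- stats::qnorm(0.975)
  row$estimate <- est
  row$ci_lo <- est - z * se
  row$ci_hi <- est + z * se
  row$exp_estimate <- if (binary) exp(est) else NA_real_
  row$p_value <- co["in_cluster", 4]
  row$estimable <- TRUE
  notes <- character(0)
  if (length(dropped))
    notes <- c(notes, paste0("covariate(s) without variation dropped: ",
                             paste(dropped, collapse = ", ")))
  if (length(aliased))
    notes <- c(notes, paste0("collinear column(s) aliased: ",
                             paste(aliased, collapse = ", ")))
  row$note <- paste(notes, collapse = "; ")
  row
}

#' Format association results as a report table
#'
#' One row per cluster and outcome column layout: estimate (95% CI) with
#' significance stars at 0.05 / 0.01 / 0.001, a "1.00(reference)" row for
#' the reference group of binary outcomes, and "\\" for cells that are not
#' estimable.
#'
#' @param results An `association_results` data.frame.
#' @param digits Decimal places for estimates.
#' @return data.frame of formatted strings (class `association_table`), one
#'   row per (stratum, cluster) plus the reference row.
#' @export
report_table <- function(results, digits = 2) {
  stars <- function(p) {
    ifelse(is.na(p), "",
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", ""))))
  }
  fmt <- function(r) {
    if (nrow(r) == 0 || !r$estimable) return("\\")
    sprintf(paste0("%.", digits, "f(%.", digits, "f,%.", digits, "f)%s"),
            r$estimate, r$ci_lo, r$ci_hi, stars(r$p_value))
  }
  outcomes <- unique(results$outcome)
  keys <- unique(results[, c("stratum", "cluster")])
  ref <- data.frame(stratum = "", cluster = "without identified cluster",
                    n = NA_integer_, stringsAsFactors = FALSE)
  for (oc in outcomes)
    ref[[oc]] <- if (oc == "cost") "\\" else "1.00(reference)"
  body <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- results$stratum == keys$stratum[i] &
      results$cluster == keys$cluster[i]
    row <- data.frame(stratum = keys$stratum[i],
                      cluster = keys$cluster[i],
                      n = results$n_cluster[sel][1],
                      stringsAsFactors = FALSE)
    for (oc in outcomes)
      row[[oc]] <- fmt(results[sel & results$outcome == oc, , drop = FALSE])
    row
  })
  out <- rbind(ref, do.call(rbind, body))
  rownames(out) <- NULL
  class(out) <- c("association_table", "data.frame")
  out
}

#' @export
print.association_table <- function(x, ...) {
  print.data.frame(x, right = FALSE)
  invisible(x)
}
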