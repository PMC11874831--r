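#' Map a set of ICD-10 codes to the comorbidity condition roster
#'
#' Prefix matching is case- and dot-insensitive. Severity hierarchies are
#' applied: a patient coded for both mild and moderate/severe liver disease
#' (or diabetes and diabetes with complications) is positive only for the
#' more severe member. Malignancy codes (C00-C97, D00-D48) never count as
#' comorbidity: cancer is the index disease. Syntactically invalid codes are
#' skipped with a warning.
#'
#' @param union_dx Character vector of ICD-10 codes (a patient's deduplicated
#'   diagnosis set).
#' @param map A [read_condition_map()] object.
#' @param patient_id Optional id carried into the result (and into warnings).
#' @return An object of class `comorbidity_profile`: list with `patient_id`,
#'   `indicators` (named 0/1 integer vector over the roster) and `count`.
#' @export
map_icd10_to_conditions <- function(union_dx, map = read_condition_map(),
                                    patient_id = NA_character_) {
  codes <- normalize_icd10(union_dx)
  codes <- codes[nzchar(codes)]
  bad <- !is_valid_icd10(codes)
  if (any(bad)) {
    warning("skipping syntactically invalid ICD-10 code(s)",
            if (!is.na(patient_id)) paste0(" for patient ", patient_id),
            ": ", paste(codes[bad], collapse = ", "))
    codes <- codes[!bad]
  }
  codes <- codes[!is_malignancy_code(codes)]
  ind <- indicator_row(codes, map)
  structure(list(patient_id = patient_id, indicators = ind,
                 count = sum(ind)), class = "comorbidity_profile")
}

#' @export
print.comorbidity_profile <- function(x, ...) {
  pos <- names(x$indicators)[x$indicators == 1]
  cat(sprintf("<comorbidity_profile> %s: %d condition(s)%s\n",
              x$patient_id, x$count,
              if (length(pos)) paste0(" [", paste(pos, collapse = ", "), "]")
              else ""))
  invisible(x)
}

is_malignancy_code <- function(codes) {
  grepl("^C", codes) | grepl("^D[0-4]", codes)
}

# indicator vector for one normalized code set
indicator_row <- function(codes, map) {
  ids <- condition_ids(map)
  ind <- stats::setNames(integer(length(ids)), ids)
  for (id in ids) {
    pref <- map$conditions[[id]]$icd10
    if (any(vapply(pref, function(p) any(startsWith(codes, p)), logical(1))))
      ind[id] <- 1L
  }
  apply_hierarchy(ind, map)
}

apply_hierarchy <- function(ind, map) {
  for (h in map$hierarchy) {
    mild <- h[[1]]; severe <- h[[2]]
    if (mild %in% names(ind) && severe %in% names(ind) &&
        ind[severe] == 1L) ind[mild] <- 0L
  }
  ind
}

#' Profile a whole cohort
#'
#' Vectorized form of [map_icd10_to_conditions()]: maps every patient's
#' diagnosis set to condition indicators. Unique codes across the cohort are
#' classified once, so cost scales with distinct codes rather than patients.
#'
#' @param patients Patient-level data.frame with a `union_dx` list-column
#'   (see [collapse_to_patients()]).
#' @param map A condition map.
#' @return Integer 0/1 matrix, patients x conditions, with `patient_id` row
#'   names.
#' @export
profile_cohort <- function(patients, map = read_condition_map()) {
  ids <- condition_ids(map)
  n <- nrow(patients)
  out <- matrix(0L, n, length(ids),
                dimnames = list(patients$patient_id, ids))
  if (n == 0) return(out)
  all_codes <- lapply(patients$union_dx, normalize_icd10)
  uniq <- unique(unlist(all_codes, use.names = FALSE))
  uniq <- uniq[nzchar(uniq)]
  bad <- uniq[!is_valid_icd10(uniq)]
  if (length(bad))
    warning("skipping syntactically invalid ICD-10 code(s): ",
            paste(utils::head(bad, 10), collapse = ", "),
            if (length(bad) > 10) " ...")
  uniq <- setdiff(uniq, bad)
  uniq <- uniq[!is_malignancy_code(uniq)]
  # classify each unique code -> condition id (or NA)
  code_cond <- rep(NA_character_, length(uniq))
  for (id in ids) {
    pref <- map$conditions[[id]]$icd10
    hit <- Reduce(`|`, lapply(pref, function(p) startsWith(uniq, p)),
                  accumulate = FALSE, init = logical(length(uniq)))
    code_cond[hit] <- id
  }
  lut <- stats::setNames(code_cond, uniq)
  for (i in seq_len(n)) {
    conds <- unique(stats::na.omit(lut[intersect(all_codes[[i]], uniq)]))
    out[i, conds] <- 1L
  }
  # hierarchy, vectorized over patients
  for (h in map$hierarchy) {
    out[out[, h[[2]]] == 1L, h[[1]]] <- 0L
  }
  out
}

#' Charlson comorbidity score and severity grade
#'
#' The score is the sum of the Charlson weights of the patient's positive
#' conditions (hypertension contributes weight 0 by default). Severity is
#' graded by [severity_grade()].
#'
#' @param profile A `comorbidity_profile` or a 0/1 indicator matrix
#'   (patients x conditions).
#' @param weights Named integer weight vector; defaults to the map's
#'   [weight_table()].
#' @param thresholds Severity thresholds, see [severity_grade()].
#' @return For a single profile, a list of class `index_result`
#'   (`patient_id`, `cci_score`, `severity`); for a matrix, a data.frame with
#'   one row per patient.
#' @export
compute_cci_score <- function(profile,
                              weights = weight_table(read_condition_map()),
                              thresholds = c(3L, 5L)) {
  if (inherits(profile, "comorbidity_profile")) {
    ind <- profile$indicators
    missing_w <- setdiff(names(ind)[ind == 1L], names(weights))
    if (length(missing_w))
      stop("configuration error: no weight for condition(s): ",
           paste(missing_w, collapse = ", "))
    score <- sum(weights[names(ind)[ind == 1L]])
    return(structure(list(patient_id = profile$patient_id,
                          cci_score = as.integer(score),
                          severity = severity_grade(score, thresholds)),
                     class = "index_result"))
  }
  ind <- as.matrix(profile)
  missing_w <- setdiff(colnames(ind), names(weights))
  if (length(missing_w))
    stop("configuration error: no weight for condition(s): ",
         paste(missing_w, collapse = ", "))
  score <- as.integer(ind %*% weights[colnames(ind)])
  data.frame(patient_id = rownames(ind) %||% as.character(seq_len(nrow(ind))),
             comorbidity_count = as.integer(rowSums(ind)),
             cci_score = score,
             severity = severity_grade(score, thresholds),
             stringsAsFactors = FALSE)
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf("<index_result> %s: CCI score %d (%s)\n",
              x$patient_id, x$cci_score, as.character(x$severity)))
  invisible(x)
}

#' Prevalence and burden tables for a scored cohort
#'
#' Computes, per condition, the total count and the count per cancer type
#' with row percentages (each cancer type's share of that condition's
#' patients); per cancer type, the comorbidity rate (share of patients with
#' at least one condition); the distribution of comorbidity counts (1, 2, 3,
#' >3) among patients with comorbidity; and severity shares.
#'
#' @param patients Patient-level data.frame (needs `cancer_type`).
#' @param profiles 0/1 indicator matrix aligned with `patients`.
#' @param thresholds Severity thresholds passed to [compute_cci_score()].
#' @param weights Weight vector passed to [compute_cci_score()].
#' @return Object of class `prevalence_table`; see Details.
#' @export
prevalence_table <- function(patients, profiles,
                             weights = weight_table(read_condition_map()),
                             thresholds = c(3L, 5L)) {
  if (nrow(patients) == 0) stop("empty cohort")
  stopifnot(nrow(patients) == nrow(profiles))
  types <- sort(unique(patients$cancer_type))
  cond_total <- colSums(profiles)
  by_type <- vapply(types, function(tt)
    colSums(profiles[patients$cancer_type == tt, , drop = FALSE]),
    numeric(ncol(profiles)))
  by_type <- matrix(by_type, nrow = ncol(profiles),
                    dimnames = list(colnames(profiles), types))
  row_pct <- 100 * sweep(by_type, 1, pmax(cond_total, 1), "/")
  by_type_counts <- by_type

  has_any <- rowSums(profiles) >= 1
  n_type <- table(factor(patients$cancer_type, levels = types))
  with_type <- table(factor(patients$cancer_type[has_any], levels = types))
  type_tab <- data.frame(cancer_type = types,
                         n = as.integer(n_type),
                         n_with = as.integer(with_type),
                         rate_pct = 100 * as.integer(with_type) /
                           as.integer(n_type),
                         stringsAsFactors = FALSE)

  cnt <- rowSums(profiles)[has_any]
  count_dist <- c(`1` = sum(cnt == 1), `2` = sum(cnt == 2),
                  `3` = sum(cnt == 3), `>3` = sum(cnt > 3))
  scored <- compute_cci_score(profiles, weights, thresholds)
  sev_shares <- 100 * prop.table(table(scored$severity[has_any]))

  structure(list(
    n_total = nrow(patients), n_with = sum(has_any),
    overall_rate_pct = 100 * sum(has_any) / nrow(patients),
    condition = data.frame(condition = colnames(profiles),
                           total = as.integer(cond_total),
                           prevalence_pct = 100 * cond_total /
                             nrow(patients),
                           stringsAsFactors = FALSE, row.names = NULL),
    by_type_counts = by_type_counts, by_type_row_pct = row_pct,
    cancer_type = type_tab,
    count_distribution = count_dist,
    count_distribution_pct = 100 * count_dist / max(sum(has_any), 1),
    severity_pct = sev_shares), class = "prevalence_table")
}

#' Build a prevalence table from aggregate count tables
#'
#' Same percentage arithmetic as [prevalence_table()], but starting from
#' published aggregate counts rather than patient-level data: a per-condition
#' count table (total and per-cancer-type counts) and a per-cancer-type
#' cohort table (`n_patients`, `n_with_comorbidity`).
#'
#' @param condition_counts data.frame: `condition`, `total`, one column per
#'   cancer type.
#' @param cohort_counts data.frame: `cancer_type`, `n_patients`,
#'   `n_with_comorbidity`.
#' @return Object of class `prevalence_table` (condition prevalences, row
#'   percentages, per-type and overall comorbidity rates).
#' @export
prevalence_from_counts <- function(condition_counts, cohort_counts) {
  stopifnot(all(c("condition", "total") %in% names(condition_counts)),
            all(c("cancer_type", "n_patients", "n_with_comorbidity") %in%
                  names(cohort_counts)))
  n_total <- sum(cohort_counts$n_patients)
  n_with <- sum(cohort_counts$n_with_comorbidity)
  types <- cohort_counts$cancer_type
  cnt <- as.matrix(condition_counts[, types, drop = FALSE])
  rownames(cnt) <- condition_counts$condition
  structure(list(
    n_total = n_total, n_with = n_with,
    overall_rate_pct = 100 * n_with / n_total,
    condition = data.frame(condition = condition_counts$condition,
                           total = condition_counts$total,
                           prevalence_pct = 100 * condition_counts$total /
                             n_total,
                           stringsAsFactors = FALSE),
    by_type_counts = cnt,
    by_type_row_pct = 100 * sweep(cnt, 1,
                                  pmax(condition_counts$total, 1), "/"),
    cancer_type = data.frame(cancer_type = types,
                             n = cohort_counts$n_patients,
                             n_with = cohort_counts$n_with_comorbidity,
                             rate_pct = 100 *
                               cohort_counts$n_with_comorbidity /
                               cohort_counts$n_patients,
                             stringsAsFactors = FALSE),
    count_distribution = NULL, count_distribution_pct = NULL,
    severity_pct = NULL), class = "prevalence_table")
}

#' @export
print.prevalence_table <- function(x, digits = 2, ...) {
  cat(sprintf("<prevalence_table> N = %d, with comorbidity %d (%.2f%%)\n",
              x$n_total, x$n_with, x$overall_rate_pct))
  cat("  comorbidity rate by cancer type:\n")
  for (i in seq_len(nrow(x$cancer_type))) {
    cat(sprintf("    %-8s %5d / %5d  (%.2f%%)\n",
                x$cancer_type$cancer_type[i], x$cancer_type$n_with[i],
                x$cancer_type$n[i], x$cancer_type$rate_pct[i]))
  }
  top <- x$condition[order(-x$condition$total), ]
  cat("  most prevalent conditions:\n")
  for (i in seq_len(min(5, nrow(top)))) {
    cat(sprintf("    %-18s %5d  (%.2f%%)\n", top$condition[i],
                top$total[i], top$prevalence_pct[i]))
  }
  invisible(x)
}

#' Compare patient characteristics between comorbidity groups
#'
#' Mirrors a baseline-characteristics table: continuous variables are
#' summarized as mean (SD) per group and compared with the two-sample
#' pooled-variance t test; categorical variables as n (%) and compared with
#' the Pearson chi-square test (no continuity correction).
#'
#' @param patients Patient-level data.frame.
#' @param profiles 0/1 indicator matrix aligned with `patients`.
#' @param grouping One of `"comorbidity"` (with vs without any condition),
#'   `"count3"` (<=3 vs >3 conditions, within patients with comorbidity) or
#'   `"severity"` (severe vs below-severe, within patients with comorbidity).
#' @param continuous,categorical Variable names to compare; defaults cover
#'   the standard baseline table.
#' @param thresholds,weights Passed to [compute_cci_score()] for the severity
#'   grouping.
#' @return data.frame with one row per variable: `variable`, `kind`,
#'   `statistic`, `df`, `p_value`, plus a `details` attribute holding the
#'   per-group summaries.
#' @export
compare_groups <- function(patients, profiles,
                           grouping = c("comorbidity", "count3", "severity"),
                           continuous = c("age", "total_cost"),
                           categorical = c("sex", "insured", "married",
                                           "residency", "cancer_type",
                                           "cancer_stage"),
                           weights = weight_table(read_condition_map()),
                           thresholds = c(3L, 5L)) {
  grouping <- match.arg(grouping)
  cnt <- rowSums(profiles)
  if (grouping == "comorbidity") {
    sel <- rep(TRUE, nrow(patients))
    grp <- factor(ifelse(cnt >= 1, "with", "without"),
                  levels = c("with", "without"))
  } else if (grouping == "count3") {
    sel <- cnt >= 1
    grp <- factor(ifelse(cnt[sel] <= 3, "le3", "gt3"),
                  levels = c("le3", "gt3"))
  } else {
    sel <- cnt >= 1
    sev <- compute_cci_score(profiles, weights, thresholds)$severity
    grp <- factor(ifelse(sev[sel] == "severe", "severe", "below_severe"),
                  levels = c("below_severe", "severe"))
  }
  dat <- patients[sel, , drop = FALSE]
  if (any(table(grp) == 0)) stop("both comparison groups must be non-empty")

  rows <- list(); details <- list()
  for (v in continuous) {
    x <- dat[[v]]
    m <- tapply(x, grp, mean, na.rm = TRUE)
    s <- tapply(x, grp, stats::sd, na.rm = TRUE)
    details[[v]] <- data.frame(group = levels(grp), mean = as.numeric(m),
                               sd = as.numeric(s))
    if (any(is.na(s)) || all(s == 0, na.rm = TRUE)) {
      rows[[v]] <- data.frame(variable = v, kind = "continuous",
                              statistic = NA_real_, df = NA_real_,
                              p_value = NA_real_,
                              note = "undefined: zero variance")
    } else {
      tt <- stats::t.test(x ~ grp, var.equal = TRUE)
      rows[[v]] <- data.frame(variable = v, kind = "continuous",
                              statistic = unname(tt$statistic),
                              df = unname(tt$parameter),
                              p_value = tt$p.value, note = "")
    }
  }
  for (v in categorical) {
    tab <- table(dat[[v]], grp)
    details[[v]] <- tab
    ct <- tryCatch(suppressWarnings(stats::chisq.test(tab, correct = FALSE)),
                   error = function(e) NULL)
    rows[[v]] <- if (is.null(ct)) {
      data.frame(variable = v, kind = "categorical", statistic = NA_real_,
                 df = NA_real_, p_value = NA_real_,
                 note = "undefined: degenerate table")
    } else {
      data.frame(variable = v, kind = "categorical",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value, note = "")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  attr(out, "grouping") <- grouping
  out
}
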