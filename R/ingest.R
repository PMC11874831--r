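#' Read admission-level records from CSV
#'
#' Parses one row per hospital admission. Two dialects are supported for the
#' secondary diagnoses: a single semicolon-joined `secondary_dx` column
#' (default) or wide columns `dx2`..`dx19`. Rows violating row-level
#' invariants (malformed or reversed dates, unknown sex or stage, more than
#' 18 secondary diagnoses) are rejected, not fatal; the rejections are
#' returned in the `diagnostics` attribute and surfaced in the downstream
#' [filter_report].
#'
#' @param path CSV file path (UTF-8, header row).
#' @param dialect List: `sep` (default ","), `secondary` ("joined" or
#'   "wide"), `date_format` (default "%Y-%m-%d").
#' @return A data.frame of admissions with a `diagnostics` attribute
#'   (data.frame of `row`, `reason` for rejected input rows).
#' @export
read_admissions <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- dialect$sep %||% ","
  secondary <- dialect$secondary %||% "joined"
  date_format <- dialect$date_format %||% "%Y-%m-%d"

  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"),
                           quote = "\"", comment.char = "")
  required <- c("patient_id", "admission_date", "discharge_date", "age",
                "sex", "cancer_type", "cancer_stage", "primary_dx")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (secondary == "joined") {
    if (!"secondary_dx" %in% names(raw))
      stop("schema error: missing required column(s): secondary_dx")
    sec <- raw$secondary_dx
    sec[is.na(sec)] <- ""
  } else if (secondary == "wide") {
    wide <- grep("^dx([2-9]|1[0-9])$", names(raw), value = TRUE)
    if (!length(wide))
      stop("schema error: wide dialect requires dx2..dx19 columns")
    sec <- apply(raw[, wide, drop = FALSE], 1, function(r)
      paste(r[!is.na(r) & nzchar(r)], collapse = ";"))
  } else stop("unknown secondary-dx dialect: ", secondary)

  n <- nrow(raw)
  if (n == 0) {
    out <- admissions_skeleton()
    attr(out, "diagnostics") <- data.frame(row = integer(0),
                                           reason = character(0))
    return(out)
  }
  adm_date <- as.Date(raw$admission_date, format = date_format)
  dis_date <- as.Date(raw$discharge_date, format = date_format)
  age <- suppressWarnings(as.numeric(raw$age))
  n_sec <- lengths(strsplit(sec, ";", fixed = TRUE))
  n_sec[!nzchar(sec)] <- 0L

  reasons <- rep(NA_character_, n)
  flag <- function(bad, why) {
    reasons[bad & is.na(reasons)] <<- why
  }
  flag(is.na(adm_date), "malformed admission_date")
  flag(is.na(dis_date), "malformed discharge_date")
  flag(!is.na(adm_date) & !is.na(dis_date) & adm_date > dis_date,
       "admission_date after discharge_date")
  flag(!(tolower(raw$sex) %in% c("male", "female")), "unknown sex")
  flag(!(raw$cancer_stage %in% c("0", "I", "II", "III", "IV")),
       "unknown cancer_stage")
  flag(is.na(age) | age < 0, "invalid age")
  flag(n_sec > 18, "secondary_dx overflow")

  keep <- is.na(reasons)
  pick <- function(col, default = NA_character_) {
    if (col %in% names(raw)) raw[[col]][keep] else rep(default, sum(keep))
  }
  as_bool <- function(x) tolower(x) %in% c("true", "1", "yes", "t")
  out <- data.frame(
    patient_id = raw$patient_id[keep],
    admission_date = adm_date[keep], discharge_date = dis_date[keep],
    age = age[keep], sex = tolower(raw$sex[keep]),
    insured = as_bool(pick("insured", "TRUE")),
    married = as_bool(pick("married", "TRUE")),
    residency = pick("residency"), education = pick("education"),
    cancer_type = tolower(raw$cancer_type[keep]),
    histology = pick("histology"),
    cancer_stage = raw$cancer_stage[keep],
    department = pick("department"),
    primary_dx = raw$primary_dx[keep], secondary_dx = sec[keep],
    surgery = as_bool(pick("surgery", "FALSE")),
    chemotherapy = as_bool(pick("chemotherapy", "FALSE")),
    radiotherapy = as_bool(pick("radiotherapy", "FALSE")),
    targeted = as_bool(pick("targeted", "FALSE")),
    total_cost = suppressWarnings(as.numeric(pick("total_cost"))),
    stringsAsFactors = FALSE)
  attr(out, "diagnostics") <- data.frame(row = which(!keep),
                                         reason = reasons[!keep],
                                         stringsAsFactors = FALSE)
  out
}

#' Write admissions to the standard CSV dialect
#'
#' @param admissions Admission data.frame as produced by [generate_cohort()]
#'   or [read_admissions()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_admissions_csv <- function(admissions, path) {
  df <- admissions
  df$admission_date <- format(df$admission_date, "%Y-%m-%d")
  df$discharge_date <- format(df$discharge_date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Collapse admissions to one analysis row per patient
#'
#' Demographics come from the first admission (by date); diagnoses are the
#' deduplicated union of primary and secondary codes across admissions;
#' treatment flags are unioned; cost is summed missing-aware (the patient
#' total is missing, and `cost_missing` set, if any admission cost is
#' missing). Conflicting demographics within a patient trigger a warning and
#' the first-admission value wins.
#'
#' @param admissions Admission data.frame.
#' @return Patient-level data.frame with a list-column `union_dx` and columns
#'   `n_admissions`, `first_admission`, `cost_missing`.
#' @export
collapse_to_patients <- function(admissions) {
  if (nrow(admissions) == 0) {
    out <- admissions[, !(names(admissions) %in%
                            c("admission_date", "discharge_date",
                              "primary_dx", "secondary_dx"))]
    out$n_admissions <- integer(0)
    out$first_admission <- as.Date(character(0))
    out$union_dx <- I(list())
    out$cost_missing <- logical(0)
    return(out)
  }
  ord <- order(admissions$patient_id, admissions$admission_date)
  adm <- admissions[ord, , drop = FALSE]
  idx <- split(seq_len(nrow(adm)), adm$patient_id)

  demo_cols <- c("age", "sex", "insured", "married", "residency",
                 "education", "cancer_type", "histology", "cancer_stage",
                 "department")
  conflicts <- 0L
  rows <- lapply(idx, function(i) {
    first <- adm[i[1], , drop = FALSE]
    if (length(i) > 1) {
      for (col in demo_cols) {
        v <- adm[[col]][i]
        if (length(unique(v[!is.na(v)])) > 1) conflicts <<- conflicts + 1L
      }
    }
    codes <- unlist(strsplit(adm$secondary_dx[i], ";", fixed = TRUE))
    codes <- unique(c(adm$primary_dx[i], codes[nzchar(codes)]))
    costs <- adm$total_cost[i]
    data.frame(
      patient_id = first$patient_id,
      age = first$age, sex = first$sex, insured = first$insured,
      married = first$married, residency = first$residency,
      education = first$education, cancer_type = first$cancer_type,
      histology = first$histology, cancer_stage = first$cancer_stage,
      department = first$department,
      n_admissions = length(i),
      first_admission = first$admission_date,
      surgery = any(adm$surgery[i]), chemotherapy = any(adm$chemotherapy[i]),
      radiotherapy = any(adm$radiotherapy[i]),
      targeted = any(adm$targeted[i]),
      total_cost = if (anyNA(costs)) NA_real_ else sum(costs),
      cost_missing = anyNA(costs),
      union_dx = I(list(codes)),
      stringsAsFactors = FALSE)
  })
  if (conflicts > 0)
    warning(conflicts, " conflicting demographic value(s) resolved to the ",
            "first admission")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default cohort inclusion/exclusion rules
#'
#' Included cancers: lung, colon, rectal, breast, gastric. Diagnosis (first
#' admission) within a half-open window from January 2017 to the end of
#' October 2019. Histology exclusions per cancer type (special breast
#' histologies and non-invasive breast cancer, male breast cancer,
#' non-adenocarcinoma colorectal histologies, small cell lung cancer).
#' Patients with only a single admission are excluded to keep treatment
#' trajectories interpretable.
#'
#' @return A list of rule settings, each overridable.
#' @export
default_filter_rules <- function() {
  list(
    cancer_types = c("lung", "colon", "rectal", "breast", "gastric"),
    date_start = as.Date("2017-01-01"),
    date_end = as.Date("2019-11-01"),   # half-open [start, end)
    excluded_histology = list(
      breast = c("non-invasive", "mucinous adenocarcinoma",
                 "medullary carcinoma", "adenoid cystic carcinoma",
                 "paget disease"),
      colon = c("lymphoma", "sarcoma", "squamous cell carcinoma"),
      rectal = c("lymphoma", "sarcoma", "squamous cell carcinoma"),
      lung = c("small cell carcinoma")),
    exclude_male_breast = TRUE,
    min_admissions = 2L,
    single_admission_window_days = 90L)
}

#' Apply cohort inclusion/exclusion rules
#'
#' Filters patients in a fixed rule order -- cancer type, diagnosis-date
#' window, histology, single admission -- counting each excluded patient once
#' at the first failing rule, and returns the retained patients together with
#' a [filter_report] whose stage counts are exhaustive and mutually
#' exclusive.
#'
#' @param admissions Admission data.frame (parsed).
#' @param rules Rule list as from [default_filter_rules()]; partial overrides
#'   are merged over the defaults.
#' @return A list with elements `patients` (patient-level data.frame),
#'   `admissions` (admissions of retained patients) and `report`
#'   (`filter_report`).
#' @export
apply_inclusion_exclusion <- function(admissions, rules = list()) {
  r <- utils::modifyList(default_filter_rules(), rules)
  diag_in <- attr(admissions, "diagnostics")
  patients <- collapse_to_patients(admissions)
  n_pat <- nrow(patients)

  status <- rep(NA_character_, n_pat)
  fail <- function(bad, stage) {
    status[bad & is.na(status)] <<- stage
  }
  if (n_pat > 0) {
    fail(!(patients$cancer_type %in% r$cancer_types), "cancer_type")
    fail(patients$first_admission < r$date_start |
           patients$first_admission >= r$date_end, "date_window")
    hist_bad <- rep(FALSE, n_pat)
    for (ct in names(r$excluded_histology)) {
      hist_bad <- hist_bad |
        (patients$cancer_type == ct &
           tolower(patients$histology) %in%
             tolower(r$excluded_histology[[ct]]))
    }
    if (isTRUE(r$exclude_male_breast)) {
      hist_bad <- hist_bad |
        (patients$cancer_type == "breast" & patients$sex == "male")
    }
    fail(hist_bad, "histology")
    fail(patients$n_admissions < r$min_admissions, "single_admission")
  }
  keep <- is.na(status)
  report <- structure(list(
    input_admissions = nrow(admissions) +
      if (is.null(diag_in)) 0L else nrow(diag_in),
    rejected_rows = if (is.null(diag_in)) 0L else nrow(diag_in),
    input_patients = n_pat,
    excluded_cancer_type = sum(status == "cancer_type", na.rm = TRUE),
    excluded_date_window = sum(status == "date_window", na.rm = TRUE),
    excluded_histology = sum(status == "histology", na.rm = TRUE),
    excluded_single_admission = sum(status == "single_admission",
                                    na.rm = TRUE),
    final_patients = sum(keep)), class = "filter_report")
  stopifnot(report$final_patients ==
              report$input_patients - report$excluded_cancer_type -
              report$excluded_date_window - report$excluded_histology -
              report$excluded_single_admission)
  kept_ids <- patients$patient_id[keep]
  list(patients = patients[keep, , drop = FALSE],
       admissions = admissions[admissions$patient_id %in% kept_ids, ,
                               drop = FALSE],
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat(sprintf("  input admissions        %6d (rejected rows: %d)\n",
              x$input_admissions, x$rejected_rows))
  cat(sprintf("  input patients          %6d\n", x$input_patients))
  cat(sprintf("  - cancer type           %6d\n", x$excluded_cancer_type))
  cat(sprintf("  - date window           %6d\n", x$excluded_date_window))
  cat(sprintf("  - histology             %6d\n", x$excluded_histology))
  cat(sprintf("  - single admission      %6d\n",
              x$excluded_single_admission))
  cat(sprintf("  final patients          %6d\n", x$final_patients))
  invisible(x)
}
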