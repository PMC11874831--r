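#' Condition roster, ICD-10 mapping tables and Charlson weights
#'
#' The comorbidity roster used throughout the package is the cancer-specific
#' adaptation of the Charlson index: solid tumors, leukemias and lymphomas are
#' removed (cancer is the index disease, never its own comorbidity) and the
#' remaining Charlson conditions are consolidated to 14, to which hypertension
#' is added because of its high prevalence in inpatient cancer cohorts.
#' Connective tissue disease is shipped as an optional 16th condition, off by
#' default.
#'
#' @name conditions
NULL

#' Load a condition map from a YAML dictionary
#'
#' A condition map associates each comorbid condition with a list of ICD-10
#' code prefixes (dot-free, case-insensitive), an integer Charlson weight in
#' 0..6, and optional severity hierarchies (mild vs moderate/severe pairs in
#' which the more severe assignment wins).
#'
#' @param path Path to a YAML file; defaults to the map shipped with the
#'   package (the published Quan et al. ICD-10 coding of the Charlson
#'   conditions, relabeled to this roster).
#' @param include_connective_tissue Include the optional connective tissue
#'   disease condition? Default `FALSE`.
#' @return An object of class `condition_map`: a named list with elements
#'   `conditions` (named list of `label`, `weight`, `icd10` prefix vectors),
#'   `hierarchy` (list of mild/severe id pairs) and `dialect`.
#' @export
read_condition_map <- function(path = NULL, include_connective_tissue = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "condition_map_nci15.yaml",
                        package = "comorbid", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  conds <- raw$conditions
  if (!include_connective_tissue) {
    conds <- conds[!vapply(conds, function(x) isTRUE(x$optional), logical(1))]
  }
  conds <- lapply(conds, function(x) {
    x$icd10 <- toupper(gsub(".", "", as.character(x$icd10), fixed = TRUE))
    x
  })
  map <- structure(
    list(conditions = conds,
         hierarchy = raw$hierarchy,
         dialect = raw$dialect %||% "custom"),
    class = "condition_map")
  validate_condition_map(map)
  map
}

#' @export
print.condition_map <- function(x, ...) {
  cat(sprintf("<condition_map> dialect '%s': %d conditions\n",
              x$dialect, length(x$conditions)))
  for (id in names(x$conditions)) {
    c0 <- x$conditions[[id]]
    cat(sprintf("  %-18s w=%d  %s (%d prefixes)\n",
                id, c0$weight, c0$label, length(c0$icd10)))
  }
  invisible(x)
}

validate_condition_map <- function(map) {
  stopifnot(inherits(map, "condition_map"), length(map$conditions) >= 1)
  w <- vapply(map$conditions, function(x) as.integer(x$weight), integer(1))
  if (any(w < 0 | w > 6)) {
    stop("condition weights must lie in 0..6: ",
         paste(names(w)[w < 0 | w > 6], collapse = ", "))
  }
  # identical prefixes must not be claimed by two conditions
  pref <- unlist(lapply(map$conditions, `[[`, "icd10"), use.names = FALSE)
  owner <- rep(names(map$conditions),
               vapply(map$conditions, function(x) length(x$icd10), integer(1)))
  dup <- pref[duplicated(pref)]
  if (length(dup)) {
    stop("ICD-10 prefix mapped to more than one condition: ",
         paste(unique(dup), collapse = ", "),
         " (", paste(unique(owner[pref %in% dup]), collapse = ", "), ")")
  }
  for (h in map$hierarchy) {
    if (!all(h %in% names(map$conditions))) {
      stop("hierarchy names unknown condition: ", paste(h, collapse = ", "))
    }
  }
  invisible(map)
}

#' Condition identifiers of a condition map
#' @param map A `condition_map`.
#' @return Character vector of condition ids in roster order.
#' @export
condition_ids <- function(map) names(map$conditions)

#' Human-readable condition labels
#' @param map A `condition_map`.
#' @return Named character vector, ids as names.
#' @export
condition_labels <- function(map) {
  vapply(map$conditions, `[[`, character(1), "label")
}

#' Charlson weight table of a condition map
#'
#' Hypertension carries weight 0 by default: it sits outside the Charlson
#' index and is carried for prevalence and pattern analysis only.
#'
#' @param map A `condition_map`.
#' @return Named integer vector of weights (0..6).
#' @export
weight_table <- function(map) {
  vapply(map$conditions, function(x) as.integer(x$weight), integer(1))
}

#' Grade a Charlson score into severity categories
#'
#' Default thresholds follow a widely used convention: none = 0,
#' mild = 1-2, moderate = 3-4, severe >= 5.
#'
#' @param score Integer vector of Charlson comorbidity scores.
#' @param thresholds Length-2 increasing integer vector `c(moderate, severe)`:
#'   scores below `moderate` (but > 0) are mild, scores in
#'   `[moderate, severe)` moderate, scores `>= severe` severe.
#' @return Factor with levels none < mild < moderate < severe.
#' @export
severity_grade <- function(score, thresholds = c(3L, 5L)) {
  stopifnot(length(thresholds) == 2, thresholds[1] >= 1,
            thresholds[2] > thresholds[1])
  if (any(score < 0, na.rm = TRUE)) stop("scores must be non-negative")
  lev <- c("none", "mild", "moderate", "severe")
  out <- ifelse(score == 0, "none",
         ifelse(score < thresholds[1], "mild",
         ifelse(score < thresholds[2], "moderate", "severe")))
  factor(out, levels = lev, ordered = TRUE)
}

# normalize ICD-10 codes: uppercase, strip dots and whitespace
normalize_icd10 <- function(codes) {
  toupper(gsub("[. ]", "", as.character(codes)))
}

# syntactic validity: letter followed by two digits, then up to 4 more chars
is_valid_icd10 <- function(codes) {
  grepl("^[A-Z][0-9]{2}[0-9A-Z]{0,4}$", normalize_icd10(codes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
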