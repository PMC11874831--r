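#' Estimate the comorbidity burden of an inpatient cancer cohort
#'
#' The package's central analysis. Starting from admission-level records it
#' runs the four-step pipeline: (1) inclusion/exclusion filtering to one row
#' per patient, (2) ICD-10 to condition mapping, Charlson scoring and
#' severity grading with prevalence tables, (3) comorbidity pattern
#' discovery per cancer-type stratum -- rare-condition filtering,
#' Pearson-correlation distance, bottom-up agglomerative clustering, cluster
#' extraction and patient assignment -- and (4) covariate-adjusted logistic
#' and linear models comparing each cluster against the no-comorbidity
#' reference on treatment options and cost.
#'
#' @param admissions Admission-level data.frame ([read_admissions()] /
#'   [generate_cohort()] schema).
#' @param map Condition map; default the shipped roster.
#' @param rules Inclusion/exclusion rule overrides
#'   (see [default_filter_rules()]).
#' @param min_count Rare-condition threshold per stratum (default 3).
#' @param linkage Linkage rule for the clustering (default "average").
#' @param cut_height Dendrogram cut height on the 1 - r scale (default 0.9:
#'   groups conditions whose mutual correlation is materially positive).
#' @param n_clusters Optional per-stratum named vector of cluster counts;
#'   overrides `cut_height` where given.
#' @param covariates Covariate set for the association models
#'   (default [covariate_preset()]`("full")`).
#' @param min_cluster_n Minimum cluster size to fit models on (default 10).
#' @param reference Reference-group definition, see [fit_cluster_models()].
#' @param impute Mean-impute missing costs (default TRUE).
#' @param severity_thresholds Passed to [severity_grade()].
#' @return Object of class `comorbidity_burden` with components `report`,
#'   `patients`, `profiles`, `index`, `prevalence`, `strata` (per cancer
#'   type: indicator matrix, dendrogram, cut, cluster set), `associations`,
#'   `table` and `settings`.
#' @examples
#' adm <- generate_cohort(cohort_spec(n_patients = 300, seed = 7))
#' fit <- comorbidity_burden(adm)
#' print(fit)
#' coef(fit)
#' @export
comorbidity_burden <- function(admissions,
                               map = read_condition_map(),
                               rules = list(),
                               min_count = 3L,
                               linkage = "average",
                               cut_height = 0.9,
                               n_clusters = NULL,
                               covariates = covariate_preset("full"),
                               min_cluster_n = 10L,
                               reference = "no_comorbidity",
                               impute = TRUE,
                               severity_thresholds = c(3L, 5L)) {
  step1 <- apply_inclusion_exclusion(admissions, rules)
  patients <- step1$patients
  if (nrow(patients) == 0) stop("no patients remain after filtering")

  profiles <- profile_cohort(patients, map)
  weights <- weight_table(map)
  index <- compute_cci_score(profiles, weights, severity_thresholds)
  prevalence <- prevalence_table(patients, profiles, weights,
                                 severity_thresholds)

  strata <- list()
  membership_all <- stats::setNames(rep("none", nrow(patients)),
                                    patients$patient_id)
  for (tt in sort(unique(patients$cancer_type))) {
    sel <- patients$cancer_type == tt
    m <- profiles[sel, , drop = FALSE]
    st <- list(cancer_type = tt, n = sum(sel))
    st$matrix <- tryCatch(filter_rare_conditions(m, min_count),
                          error = function(e) NULL)
    if (!is.null(st$matrix) && ncol(st$matrix) >= 2) {
      st$distance <- correlation_distance(st$matrix)
      st$tree <- agglomerative_cluster(st$distance, linkage)
      st$cut <- if (!is.null(n_clusters) && tt %in% names(n_clusters))
        extract_clusters(st$tree, n_clusters = n_clusters[[tt]])
      else extract_clusters(st$tree, height = cut_height)
      st$cluster_set <- assign_patients(st$cut, st$matrix)
      membership_all[rownames(st$matrix)] <- st$cluster_set$membership
    }
    strata[[tt]] <- st
  }

  cluster_set_all <- list(membership = membership_all, exclusive = TRUE)
  frame <- build_outcome_frame(patients, profiles, cluster_set_all,
                               impute = impute)
  assoc <- list()
  for (tt in names(strata)) {
    if (is.null(strata[[tt]]$cluster_set)) next
    assoc[[tt]] <- fit_cluster_models(frame, stratum = tt,
                                      covariates = covariates,
                                      min_cluster_n = min_cluster_n,
                                      reference = reference)
  }
  associations <- if (length(assoc)) do.call(rbind, assoc) else
    fit_cluster_models(frame[0, , drop = FALSE])
  rownames(associations) <- NULL
  class(associations) <- c("association_results", "data.frame")

  structure(list(
    report = step1$report, patients = patients, profiles = profiles,
    index = index, prevalence = prevalence, strata = strata,
    frame = frame, associations = associations,
    table = if (nrow(associations)) report_table(associations) else NULL,
    settings = list(min_count = min_count, linkage = linkage,
                    cut_height = cut_height, n_clusters = n_clusters,
                    covariates = covariates, min_cluster_n = min_cluster_n,
                    reference = reference, impute = impute,
                    severity_thresholds = severity_thresholds,
                    dialect = map$dialect)),
    class = "comorbidity_burden")
}

#' @export
print.comorbidity_burden <- function(x, ...) {
  cat("Comorbidity burden analysis\n")
  cat(sprintf("  patients: %d (of %d before filtering)\n",
              x$report$final_patients, x$report$input_patients))
  cat(sprintf("  with comorbidity: %d (%.2f%%)\n",
              x$prevalence$n_with, x$prevalence$overall_rate_pct))
  n_cl <- sum(vapply(x$strata, function(s)
    if (is.null(s$cluster_set)) 0L else length(s$cluster_set$clusters),
    integer(1)))
  cat(sprintf("  comorbidity clusters: %d across %d cancer-type strata (%s linkage)\n",
              n_cl, length(x$strata), x$settings$linkage))
  cat(sprintf("  association models: %d fits (%d estimable)\n",
              nrow(x$associations), sum(x$associations$estimable)))
  invisible(x)
}

#' @export
summary.comorbidity_burden <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$prevalence)
  for (tt in names(object$strata)) {
    cs <- object$strata[[tt]]$cluster_set
    if (is.null(cs)) next
    cat(sprintf("\n%s cancer clusters:\n", tt))
    for (cl in cs$clusters)
      cat(sprintf("  %-40s n = %d\n", cl$label, cl$n))
  }
  if (!is.null(object$table)) {
    cat("\nAssociation table:\n")
    print(object$table)
  }
  invisible(object)
}

#' @export
coef.comorbidity_burden <- function(object, ...) {
  a <- object$associations
  stats::setNames(a$estimate,
                  paste(a$stratum, a$cluster, a$outcome, sep = "/"))
}

#' @export
plot.comorbidity_burden <- function(x, stratum = NULL, ...) {
  strata <- if (is.null(stratum)) names(x$strata) else stratum
  strata <- Filter(function(tt) !is.null(x$strata[[tt]]$tree), strata)
  if (!length(strata)) {
    warning("no stratum with a dendrogram to plot")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(strata)))
  on.exit(graphics::par(old))
  for (tt in strata) {
    plot(x$strata[[tt]]$tree,
         main = sprintf("%s cancer (%s linkage)", tt,
                        x$strata[[tt]]$tree$linkage), ...)
  }
  invisible(x)
}

#' Run the pipeline end-to-end with file artifacts
#'
#' Executes ingest, scoring, clustering and association modelling from a
#' config, writing every stage's artifact plus a provenance manifest into a
#' content-addressed (timestamp-free) run directory so that reruns with the
#' same config are byte-identical and diffable.
#'
#' @param config A list (or path to a YAML file) with entries: `input`
#'   (admissions CSV path), `out_dir`, optional `dialect`, `rules`,
#'   `min_count`, `linkage`, `cut_height`, `covariate_preset`,
#'   `min_cluster_n`, `reference`, `impute`, `seed`.
#' @return The `comorbidity_burden` object, invisibly; artifacts on disk in
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("input", "out_dir")) {
    if (is.null(config[[f]])) stop("config validation error: missing '", f,
                                   "'")
  }
  if (!file.exists(config$input))
    stop("config validation error: input file not found: ", config$input)
  if (!is.null(config$map) && !file.exists(config$map))
    stop("config validation error: map file not found: ", config$map)
  map <- read_condition_map(config$map)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)

  stage <- "ingest"
  fit <- tryCatch({
    adm <- read_admissions(config$input, config$dialect %||% list())
    stage <- "analysis"
    comorbidity_burden(
      adm, map = map, rules = config$rules %||% list(),
      min_count = config$min_count %||% 3L,
      linkage = config$linkage %||% "average",
      cut_height = config$cut_height %||% 0.9,
      covariates = covariate_preset(config$covariate_preset %||% "full"),
      min_cluster_n = config$min_cluster_n %||% 10L,
      reference = config$reference %||% "no_comorbidity",
      impute = config$impute %||% TRUE)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  jsonlite::write_json(unclass(fit$report), out("filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  pts <- fit$patients
  pts$union_dx <- vapply(pts$union_dx, paste, character(1), collapse = ";")
  pts$first_admission <- format(pts$first_admission, "%Y-%m-%d")
  utils::write.csv(pts, out("patients.csv"), row.names = FALSE)
  utils::write.csv(cbind(fit$index, as.data.frame(fit$profiles)),
                   out("scored.csv"), row.names = FALSE)
  utils::write.csv(fit$prevalence$condition,
                   out("prevalence_conditions.csv"), row.names = FALSE)
  utils::write.csv(fit$prevalence$cancer_type,
                   out("prevalence_types.csv"), row.names = FALSE)
  for (tt in names(fit$strata)) {
    if (is.null(fit$strata[[tt]]$tree)) next
    write_newick(fit$strata[[tt]]$tree,
                 out(sprintf("dendrogram_%s.nwk", tt)))
    write_merge_table(fit$strata[[tt]]$tree,
                      out(sprintf("merges_%s.csv", tt)))
  }
  utils::write.csv(data.frame(patient_id = fit$frame$patient_id,
                              cluster = fit$frame$cluster),
                   out("memberships.csv"), row.names = FALSE)
  utils::write.csv(fit$associations, out("associations.csv"),
                   row.names = FALSE)
  if (!is.null(fit$table))
    utils::write.csv(fit$table, out("association_table.csv"),
                     row.names = FALSE)

  artifacts <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("comorbid")),
    seed = config$seed %||% NA,
    settings = fit$settings[c("min_count", "linkage", "cut_height",
                              "min_cluster_n", "reference", "impute",
                              "dialect")],
    files = as.list(tools::md5sum(file.path(config$out_dir, artifacts))))
  names(manifest$files) <- artifacts
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(fit)
}

#' Simulate an admissions CSV from a cohort specification
#'
#' Front door to the synthetic generator: generates the admission table and
#' writes it in the standard CSV dialect.
#'
#' @param spec A [cohort_spec()].
#' @param path Output CSV path.
#' @return The admissions data.frame, invisibly.
#' @export
simulate_admissions <- function(spec, path) {
  if (spec$n_patients < 1)
    stop("config validation error: n_patients must be >= 1 to simulate")
  adm <- generate_cohort(spec)
  write_admissions_csv(adm, path)
  invisible(adm)
}
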