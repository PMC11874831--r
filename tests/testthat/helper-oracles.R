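# Independent oracles and small fixture builders shared across tests.

# Brute-force bottom-up agglomeration computed from the ORIGINAL distance
# matrix at every step (no Lance-Williams recurrences): inter-cluster
# distance is min / max / mean over all member pairs. Ties broken by the
# lexicographically smallest pair of (smallest-leaf) labels, matching the
# package's documented convention.
oracle_agglomerate <- function(d, linkage) {
  k <- nrow(d)
  clusters <- as.list(seq_len(k))
  nodes <- -seq_len(k)
  merges <- matrix(0L, k - 1L, 2L)
  heights <- numeric(k - 1L)
  cluster_dist <- function(A, B) {
    vals <- d[A, B, drop = FALSE]
    switch(linkage, single = min(vals), complete = max(vals),
           average = mean(vals))
  }
  for (step in seq_len(k - 1L)) {
    best <- NULL
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in (a + 1L):length(clusters)) {
        dd <- cluster_dist(clusters[[a]], clusters[[b]])
        key <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
        take <- is.null(best) || dd < best$d - 1e-12 ||
          (abs(dd - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
                (key[1] == best$key[1] && key[2] < best$key[2])))
        if (take) best <- list(a = a, b = b, d = dd, key = key)
      }
    }
    merges[step, ] <- sort(c(nodes[best$a], nodes[best$b]))
    heights[step] <- best$d
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    nodes[best$a] <- step
    clusters[[best$b]] <- NULL
    nodes <- nodes[-best$b]
  }
  list(merge = merges, height = heights)
}

# random symmetric distance matrix with zero diagonal
random_distance <- function(k) {
  d <- matrix(0, k, k)
  d[upper.tri(d)] <- runif(k * (k - 1) / 2, 0.05, 2)
  d <- d + t(d)
  dimnames(d) <- list(letters[seq_len(k)], letters[seq_len(k)])
  d
}

# brute-force weighted score of a 0/1 profile vector
oracle_score <- function(ind, weights) {
  s <- 0L
  for (nm in names(ind)) if (ind[[nm]] == 1L) s <- s + weights[[nm]]
  as.integer(s)
}

# one toy admission row with overridable fields
make_admission <- function(...) {
  row <- list(patient_id = "P1", admission_date = as.Date("2018-03-01"),
              discharge_date = as.Date("2018-03-08"), age = 60,
              sex = "male", insured = TRUE, married = TRUE,
              residency = "urban", education = "secondary",
              cancer_type = "lung", histology = "adenocarcinoma",
              cancer_stage = "II", department = "oncology",
              primary_dx = "C34.9", secondary_dx = "",
              surgery = TRUE, chemotherapy = FALSE, radiotherapy = FALSE,
              targeted = FALSE, total_cost = 50000)
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

# n admissions for one patient, spaced 40 days apart
make_patient_admissions <- function(pid, n = 2, ...) {
  do.call(rbind, lapply(seq_len(n), function(i)
    make_admission(patient_id = pid,
                   admission_date = as.Date("2018-03-01") + 40 * (i - 1),
                   discharge_date = as.Date("2018-03-08") + 40 * (i - 1),
                   ...)))
}

# minimal two-condition spec used by model-recovery simulations: two
# conditions at prevalence 0.40 forming one block
two_condition_spec <- function(n, rho, seed,
                               treatment_effects = list(),
                               cost_effects = list()) {
  cohort_spec(
    n_patients = n,
    condition_prevalence = c(hypertension = 0.4, diabetes = 0.4),
    blocks = list(list(conditions = c("hypertension", "diabetes"),
                       rho = rho)),
    treatment_effects = treatment_effects,
    cost_effects = cost_effects,
    missing_cost_prob = 0,
    seed = seed)
}
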