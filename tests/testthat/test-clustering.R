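test_that("rare-condition filtering drops below-threshold columns only", {
  m <- cbind(common = rep(1:0, c(30, 20)),
             boundary = rep(1:0, c(3, 47)),
             rare = rep(1:0, c(2, 48)),
             absent = rep(0L, 50))
  out <- filter_rare_conditions(m, min_count = 3)
  expect_equal(colnames(out), c("common", "boundary"))
  expect_equal(attr(out, "dropped"), c(rare = 2, absent = 0))
  expect_error(filter_rare_conditions(m[, "absent", drop = FALSE], 1),
               "no conditions remain")
})

test_that("a 15-condition matrix with 2 rare columns keeps 13", {
  set.seed(31)
  prev <- setNames(rep(0.3, 15), paste0("c", 1:15))
  prev[c("c5", "c11")] <- 0.0005
  m <- simulate_condition_matrix(400, prev)
  out <- filter_rare_conditions(m, min_count = 3)
  expect_equal(ncol(out), 13)
  expect_false(any(c("c5", "c11") %in% colnames(out)))
})

test_that("correlation distance matches direct formula and edge cases", {
  x <- c(1, 0, 1, 1, 0, 0)
  m <- cbind(a = x, b = x, c = 1 - x)
  d <- correlation_distance(m)
  expect_equal(d["a", "b"], 0)            # identical columns, r = 1
  expect_equal(d["a", "c"], 2)            # complementary, r = -1
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))

  toy <- cbind(p = c(1, 1, 0, 0), q = c(1, 0, 1, 0), r = c(1, 1, 1, 0))
  dt <- correlation_distance(toy)
  # brute-force Pearson r from first principles
  bf <- function(u, v) {
    1 - sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_equal(dt["p", "q"], bf(toy[, "p"], toy[, "q"]))
  expect_equal(dt["p", "r"], bf(toy[, "p"], toy[, "r"]))
  expect_equal(dt["q", "r"], bf(toy[, "q"], toy[, "r"]))

  expect_error(correlation_distance(cbind(a = x, flat = rep(1, 6))),
               "flat")
})

test_that("distance axioms and permutation equivariance hold", {
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(rbinom(40 * 5, 1, 0.4), 40, 5,
                dimnames = list(NULL, letters[1:5]))
    m <- m[, colSums(m) > 0 & colSums(m) < 40, drop = FALSE]
    if (ncol(m) < 2) next
    d <- correlation_distance(m)
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 2 + 1e-12))
    perm <- sample(nrow(m))
    expect_equal(correlation_distance(m[perm, ]), d)
  }
})

test_that("two leaves merge once at their distance for every linkage", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  for (lk in c("average", "complete", "single")) {
    tr <- agglomerative_cluster(d, lk)
    expect_equal(tr$height, 0.4)
    expect_equal(tr$merge, matrix(c(-2L, -1L), 1, 2))
  }
})

test_that("merge sequences equal the brute-force oracle for k <= 6", {
  set.seed(123)
  for (k in 3:6) {
    for (rep in 1:5) {
      d <- random_distance(k)
      for (lk in c("average", "complete", "single")) {
        got <- agglomerative_cluster(d, lk)
        want <- oracle_agglomerate(d, lk)
        expect_equal(got$merge, want$merge,
                     label = sprintf("merge k=%d %s", k, lk))
        expect_equal(got$height, want$height, tolerance = 1e-10,
                     label = sprintf("height k=%d %s", k, lk))
      }
    }
  }
})

test_that("partitions agree with stats::hclust on tie-free matrices", {
  set.seed(321)
  for (rep in 1:5) {
    d <- random_distance(7)
    for (lk in c("average", "complete", "single")) {
      ours <- agglomerative_cluster(d, lk)
      ref <- hclust(as.dist(d), method = lk)
      expect_equal(sort(ours$height), sort(ref$height), tolerance = 1e-10)
      for (kk in 2:6) {
        got <- extract_clusters(ours, n_clusters = kk)$groups
        want <- split(names(cutree(ref, k = kk)), cutree(ref, k = kk))
        norm <- function(gr) sort(vapply(gr, function(g)
          paste(sort(g), collapse = ","), character(1)))
        expect_equal(norm(got), unname(norm(want)),
                     label = sprintf("cut k=%d %s", kk, lk))
      }
    }
  }
})

test_that("invalid distance matrices are rejected", {
  d <- random_distance(4)
  d2 <- d; d2[1, 2] <- d2[1, 2] + 0.5
  expect_error(agglomerative_cluster(d2), "symmetric")
  d3 <- d; d3[1, 2] <- d3[2, 1] <- -0.1
  expect_error(agglomerative_cluster(d3), "non-negative")
  expect_error(agglomerative_cluster(d[1, 1, drop = FALSE]), "2 leaves")
})

test_that("column permutation does not alter the recovered partition", {
  set.seed(55)
  m <- simulate_condition_matrix(
    800, c(a = 0.4, b = 0.4, c = 0.4, d = 0.4),
    blocks = list(list(conditions = c("a", "b"), rho = 0.6),
                  list(conditions = c("c", "d"), rho = 0.6)))
  cut1 <- extract_clusters(
    agglomerative_cluster(correlation_distance(m)), n_clusters = 2)
  m2 <- m[, c("d", "b", "a", "c")]
  cut2 <- extract_clusters(
    agglomerative_cluster(correlation_distance(m2)), n_clusters = 2)
  norm <- function(cut) sort(vapply(cut$groups, function(g)
    paste(sort(g), collapse = ","), character(1)))
  expect_equal(norm(cut1), norm(cut2))
})

test_that("cluster extraction honours its cut rules", {
  d <- random_distance(5)
  tr <- agglomerative_cluster(d)
  all_single <- extract_clusters(tr, height = 0)
  expect_equal(length(all_single$groups), 5)
  expect_equal(length(all_single$clusters), 0)
  one <- extract_clusters(tr, n_clusters = 1)
  expect_equal(sort(one$groups[[1]]), sort(tr$labels))
  expect_error(extract_clusters(tr, n_clusters = 9), "n_clusters")
  expect_error(extract_clusters(tr), "exactly one")

  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
               dimnames = list(c("u", "v"), c("u", "v")))
  pair <- extract_clusters(agglomerative_cluster(d2), n_clusters = 1)
  expect_equal(pair$clusters, list(c("u", "v")))
})

test_that("patient assignment matches a brute-force membership scan", {
  set.seed(14)
  m <- simulate_condition_matrix(
    500, c(hypertension = 0.35, diabetes = 0.3, mild_liver = 0.25,
           renal = 0.2),
    blocks = list(list(conditions = c("hypertension", "diabetes"),
                       rho = 0.5),
                  list(conditions = c("mild_liver", "renal"), rho = 0.5)))
  rownames(m) <- sprintf("P%03d", seq_len(nrow(m)))
  clusters <- list(c("hypertension", "diabetes"), c("mild_liver", "renal"))
  cs <- assign_patients(clusters, m)
  # brute-force scan: all conditions positive; ties -> earlier cluster
  for (i in seq_len(nrow(m))) {
    match1 <- all(m[i, clusters[[1]]] == 1)
    match2 <- all(m[i, clusters[[2]]] == 1)
    want <- if (match1) "hypertension+diabetes"
            else if (match2) "mild_liver+renal" else "none"
    expect_equal(unname(cs$membership[i]), want)
  }
  expect_equal(vapply(cs$clusters, `[[`, integer(1), "n"),
               vapply(cs$clusters, function(cl) length(cl$patient_ids),
                      integer(1)))

  # no conditions -> no membership
  empty <- matrix(0L, 1, 4,
                  dimnames = list("Z", colnames(m)))
  expect_equal(unname(assign_patients(clusters, empty)$membership), "none")
  expect_error(assign_patients(list(c("a", "b"), c("b", "c")), m),
               "disjoint")
})

test_that("newick and merge-table exports round-trip through ape", {
  d <- random_distance(5)
  tr <- agglomerative_cluster(d)
  nwk <- write_newick(tr)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, tr$labels)
  f <- tempfile(fileext = ".csv")
  write_merge_table(tr, f)
  mt <- read.csv(f)
  expect_equal(nrow(mt), 4)
  expect_equal(mt$height, tr$height)
})
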