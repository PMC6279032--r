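# Dataset pipeline: pairwise matrices, distance transform, clustering,
# Newick export, mode-count scan, reference map and TM-score table.

make_small_dataset <- function(seeds, sigma = 0.35) {
  unit <- make_bundle(3, 10)
  dataset_spec(lapply(seq_along(seeds), function(i) list(
    structure = perturb(unit, sigma, seed = seeds[i]),
    scope = NULL, label = paste0("s", i))))
}

test_that("identical and rigidly moved entries give degenerate matrices", {
  unit <- extract_nodes(make_bundle(3, 10))
  ds <- dataset_spec(list(
    list(structure = unit, scope = NULL, label = "orig"),
    list(structure = transform_nodes(unit, random_rotation(7), c(9, -3, 2)),
         scope = NULL, label = "moved")))
  p <- align_params(n = 6)
  m <- dss_matrix(ds, p)
  expect_equal(dim(m$dss), c(2L, 2L))
  expect_equal(m$dss[1, 2], m$dss[2, 1])
  expect_equal(m$dss[1, 2], m$dss[1, 1], tolerance = 1e-6)
  expect_equal(m$tm[1, 2], 1, tolerance = 1e-6)
})

test_that("dss_matrix equals pair-by-pair composition", {
  ds <- make_small_dataset(1:4)
  p <- align_params(n = 6)
  m <- dss_matrix(ds, p)
  expect_lt(max(abs(m$dss - t(m$dss))), 1e-9)
  for (i in 1:3) for (j in (i + 1):4) {
    direct <- dss(ds$entries[[i]]$structure, ds$entries[[j]]$structure, p)
    expect_equal(m$dss[i, j], direct$dss, tolerance = 1e-9)
    expect_equal(m$tm[i, j], direct$tm, tolerance = 1e-9)
  }
  # diagonal self-DSS dominates its row for a well-posed dataset
  expect_true(all(diag(m$dss) >= apply(m$dss, 1, max) - 1e-9))
})

test_that("distance transform reverses DSS ranking and imputes failures", {
  S <- matrix(c(4, 1, 1, 4), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  d <- to_distance(S)
  expect_equal(d, matrix(c(0, 3, 3, 0), 2, 2, dimnames = dimnames(S)))
  set.seed(3)
  S2 <- matrix(runif(25, 0, 5), 5, 5); S2 <- (S2 + t(S2)) / 2
  diag(S2) <- 6
  d2 <- to_distance(S2)
  o <- upper.tri(S2)
  expect_true(all(diff(d2[o][order(S2[o])]) <= 0))   # strict monotone reversal
  expect_true(all(d2 >= 0) && all(diag(d2) == 0))
  S2[1, 2] <- S2[2, 1] <- NA
  expect_warning(d3 <- to_distance(S2), "imputed")
  expect_equal(d3[1, 2], max(d3))
  inv <- to_distance(S, style = "inverse")
  expect_equal(inv[1, 2], 1 / 2)
})

test_that("complete-linkage clustering follows the hand-computed tree", {
  d <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3, 3,
              dimnames = list(c("p1", "p2", "p3"), c("p1", "p2", "p3")))
  t1 <- hierarchical_cluster(d)
  expect_equal(t1$height, c(1, 5))
  expect_equal(sort(cutree(t1, 2)[c("p1", "p2")]), c(p1 = 1, p2 = 1))
  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  deg <- matrix(1, 4, 4); diag(deg) <- 0
  td <- hierarchical_cluster(deg)
  expect_equal(td$height, rep(1, 3))
})

test_that("newick export follows the h/2 convention and quotes labels", {
  d <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tree <- hierarchical_cluster(d)
  expect_equal(write_newick(tree), "(A:1.5,B:1.5);")
  d3 <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3, 3,
               dimnames = list(c("a 1", "b", "c"), c("a 1", "b", "c")))
  s <- write_newick(hierarchical_cluster(d3))
  expect_match(s, "'a 1'", fixed = TRUE)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hierarchical_cluster(d3), path)
  back <- ape::read.tree(path)                 # independent parser
  back$tip.label <- gsub("^'|'$", "", back$tip.label)
  expect_setequal(back$tip.label, c("a 1", "b", "c"))
  # topology: the shallow pair stays together
  expect_equal(sort(ape::cophenetic.phylo(back)["a 1", ])[2], c(b = 1))
})

test_that("planted two-family datasets are recovered by the 2-cluster cut", {
  ds <- planted_dataset(seed = 1, n_per_family = 3L)
  m <- dss_matrix(ds, align_params(n = 8))
  cut <- cutree(hierarchical_cluster(to_distance(m)), 2)
  fam <- rep(1:2, each = 3L)
  agree <- max(mean(cut == fam), mean(cut == 3 - fam))
  expect_equal(agree, 1)
})

test_that("mode-count scan correlations match a textbook Pearson oracle", {
  ds <- make_small_dataset(1:4)
  n_values <- c(2L, 4L, 6L)
  tab <- modecount_scan(ds, n_values, align_params())
  expect_equal(tab$n, c(4L, 6L))
  # recompute each matrix independently through the pairwise front end
  vec <- function(n) {
    p <- align_params(n = n)
    M <- matrix(NA_real_, 4, 4)
    for (i in 1:3) for (j in (i + 1):4)
      M[i, j] <- dss(ds$entries[[i]]$structure, ds$entries[[j]]$structure, p)$dss
    M[upper.tri(M)]
  }
  v <- lapply(n_values, vec)
  expect_equal(tab$correlation[1], oracle_pearson(v[[1]], v[[2]]),
               tolerance = 1e-9)
  expect_equal(tab$correlation[2], oracle_pearson(v[[2]], v[[3]]),
               tolerance = 1e-9)
  # permuting the dataset leaves correlations unchanged
  perm <- dataset_spec(ds$entries[c(3, 1, 4, 2)])
  tab2 <- modecount_scan(perm, n_values, align_params())
  expect_equal(tab2$correlation, tab$correlation, tolerance = 1e-9)
})

test_that("reference maps equal direct recomputation from the matrix", {
  ds <- make_small_dataset(1:5)
  m <- dss_matrix(ds, align_params(n = 6))
  map <- reference_map(m, refs_A = c("s1", "s2"), refs_B = "s4")
  expect_equal(map$mean_A[map$label == "s3"],
               mean(m$dss["s3", c("s1", "s2")]), tolerance = 1e-12)
  expect_equal(map$mean_B[map$label == "s3"], m$dss["s3", "s4"],
               tolerance = 1e-12)
  # a reference's own mean excludes the self pair
  expect_equal(map$mean_A[map$label == "s1"], m$dss["s1", "s2"],
               tolerance = 1e-12)
  same <- reference_map(m, refs_A = c("s1", "s5"), refs_B = c("s1", "s5"))
  expect_equal(same$mean_A, same$mean_B)
  expect_error(reference_map(m, character(0), "s1"))
  expect_error(reference_map(m, "nope", "s1"), "not in dataset")
})

test_that("the DSS/TM table is consistent with its source matrices", {
  ds <- make_small_dataset(1:4)
  m <- dss_matrix(ds, align_params(n = 6))
  tab <- dss_vs_tmscore(m)
  expect_equal(nrow(tab), 6L)                    # K(K-1)/2
  for (r in seq_len(nrow(tab))) {
    expect_equal(tab$dss[r], m$dss[tab$label_i[r], tab$label_j[r]])
    expect_equal(tab$tm_score[r], m$tm[tab$label_i[r], tab$label_j[r]])
  }
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, tsv, "dss")
  back <- as.matrix(read.delim(tsv, row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(m$dss), tolerance = 1e-9)
})
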