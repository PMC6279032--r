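# Mode-pair scoring, gapless match extraction, sign disambiguation and the
# scalar DSS.

test_that("cosine scores hit their analytic values", {
  expect_equal(residue_score(c(1, 0, 0), c(1, 0, 0), 0.7), 0.3,
               tolerance = 1e-12)
  expect_equal(residue_score(c(1, 0, 0), c(0, 1, 0), 0.7), -0.7,
               tolerance = 1e-12)
  expect_equal(residue_score(c(1, 0, 0), c(-1, 0, 0), 0.7), -1.7,
               tolerance = 1e-12)
  expect_equal(residue_score(c(2, 0, 0), c(5, 0, 0), 0.7), 0.3,
               tolerance = 1e-12)                      # magnitude-free
  expect_error(residue_score(c(0, 0, 0), c(1, 0, 0)), "zero-length")
})

test_that("distance constraint forces -1 beyond Rc, boundary inclusive", {
  u <- c(1, 0, 0)
  expect_equal(constrained_score(u, u, 5, 0.7, 10), 0.3, tolerance = 1e-12)
  expect_identical(constrained_score(u, u, 12, 0.7, 10), -1)
  expect_equal(constrained_score(u, u, 10, 0.7, 10), 0.3, tolerance = 1e-12)
})

test_that("score matrices match cell-by-cell scalar recomputation", {
  set.seed(31)
  uA <- matrix(rnorm(24), 8, 3); uB <- matrix(rnorm(18), 6, 3)
  cA <- matrix(rnorm(24, sd = 4), 8, 3); cB <- matrix(rnorm(18, sd = 4), 6, 3)
  p <- align_params(C = 0.6, Rc = 6)
  for (sgn in c(1, -1)) {
    S <- score_matrix(uA, uB, cA, cB, sign = sgn, params = p)
    for (i in 1:8) for (j in 1:6) {
      r <- sqrt(sum((cA[i, ] - cB[j, ])^2))
      expect_equal(S[i, j],
                   constrained_score(uA[i, ], sgn * uB[j, ], r, 0.6, 6),
                   tolerance = 1e-12)
    }
  }
  # self-comparison diagonals
  pd <- align_params()
  coords <- node_xyz(make_helix(9))
  u <- matrix(rnorm(27), 9, 3)
  expect_equal(diag(score_matrix(u, u, coords, coords, 1, pd)), rep(0.3, 9),
               tolerance = 1e-12)
  expect_equal(diag(score_matrix(u, u, coords, coords, -1, pd)),
               rep(-1.7, 9), tolerance = 1e-12)
})

test_that("seeded diagonal runs are extracted exactly", {
  p <- align_params()
  S <- matrix(-1, 10, 10)
  diag(S) <- -1
  for (t in 0:7) S[2 + t, 3 + t] <- 0.3       # run of 8 on one diagonal
  m <- extract_matches(S, p)
  expect_equal(nrow(m), 1L)
  expect_equal(m$i0, 2L); expect_equal(m$j0, 3L); expect_equal(m$len, 8L)
  expect_equal(m$score, 2.4, tolerance = 1e-12)
  # positive run of 6 on a length-6 diagonal: below min_len, no match
  S6 <- matrix(-1, 10, 10)
  for (t in 0:5) S6[5 + t, 1 + t] <- 0.3
  expect_equal(nrow(extract_matches(S6, p)), 0L)
})

test_that("greedy extraction equals the exhaustive oracle on random matrices", {
  p <- align_params(min_len = 4, max_matches = 10)
  set.seed(77)
  for (trial in 1:30) {
    S <- matrix(runif(144, -0.6, 0.4), 12, 12)
    got <- extract_matches(S, p)
    want <- oracle_extract_matches(S, 4L, 10L)
    expect_equal(got$i0, want$i0)
    expect_equal(got$j0, want$j0)
    expect_equal(got$len, want$len)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("sign disambiguation keeps the better variant", {
  nodes <- random_nodes(seed = 41)
  m <- slow_modes(build_hessian(nodes), n_keep = 4, nodes = nodes)
  xyz <- node_xyz(nodes)
  u <- mode_vectors(m, 1)
  self <- align_mode_pair(u, u, xyz, xyz)
  expect_equal(self$sign, 1)
  flip <- align_mode_pair(u, -u, xyz, xyz)
  expect_equal(flip$sign, -1)
  expect_equal(flip$matches, self$matches)
  # chosen variant's best score >= the other variant's best
  set.seed(55)
  for (trial in 1:10) {
    uA <- matrix(rnorm(90), 30, 3); uB <- matrix(rnorm(90), 30, 3)
    p0 <- align_params(min_len = 5, use_distance_constraint = FALSE)
    pick <- align_mode_pair(uA, uB, params = p0)
    other <- extract_matches(score_matrix(uA, uB, sign = -pick$sign,
                                          params = p0), p0)
    best <- function(m) if (nrow(m)) max(m$score) else 0
    expect_gte(best(pick$matches) + 1e-12, best(other))
  }
})

test_that("self-comparison DSS respects the n(1-C) lower bound", {
  nodes <- random_nodes(seed = 51)
  m <- slow_modes(build_hessian(nodes), n_keep = 12, nodes = nodes)
  xyz <- node_xyz(nodes)
  r <- compute_dss(m, m, xyz, xyz)
  expect_gte(r$dss, 12 * 0.3)
  # every (k,k) full diagonal is a selected match
  sel <- r$matches[r$matches$selected, ]
  kk <- sel[sel$k == sel$l, ]
  expect_equal(nrow(kk), 12L)
  expect_true(all(kk$len == nrow(nodes)))
  # profile means reproduce the DSS by definition
  expect_equal((mean(r$r1) + mean(r$r2)) / 2, r$dss, tolerance = 1e-12)
})

test_that("DSS is invariant to mode sign flips and rescaling", {
  nodesA <- random_nodes(seed = 61)
  nodesB <- perturb(random_nodes(seed = 61), 0.4, seed = 62)
  mA <- slow_modes(build_hessian(nodesA), n_keep = 12, nodes = nodesA)
  mB <- slow_modes(build_hessian(nodesB), n_keep = 12, nodes = nodesB)
  xa <- node_xyz(nodesA); xb <- node_xyz(nodesB)
  base <- compute_dss(mA, mB, xa, xb)$dss
  flipped <- mB
  flipped$vectors[, c(2, 5, 9)] <- -flipped$vectors[, c(2, 5, 9)]
  expect_equal(compute_dss(mA, flipped, xa, xb)$dss, base, tolerance = 1e-9)
  scaled <- mB
  scaled$vectors <- scaled$vectors * 7.3
  expect_equal(compute_dss(mA, scaled, xa, xb)$dss, base, tolerance = 1e-9)
})

test_that("DSS is symmetric and invariant under joint rigid motion", {
  for (s in 1:5) {
    nodesA <- random_nodes(seed = 70 + s)
    nodesB <- perturb(random_nodes(seed = 70 + s), 0.5, seed = 80 + s)
    mA <- slow_modes(build_hessian(nodesA), n_keep = 8, nodes = nodesA)
    mB <- slow_modes(build_hessian(nodesB), n_keep = 8, nodes = nodesB)
    xa <- node_xyz(nodesA); xb <- node_xyz(nodesB)
    p <- align_params(n = 8)
    ab <- compute_dss(mA, mB, xa, xb, p)$dss
    ba <- compute_dss(mB, mA, xb, xa, p)$dss
    expect_lt(abs(ab - ba), 1e-9)
    R <- random_rotation(90 + s); tv <- c(10, 20, -5)
    rot <- function(modes) {
      modes$vectors <- dssalign:::.rotate_mode_vectors(modes$vectors, R)
      modes
    }
    moved <- compute_dss(rot(mA), rot(mB),
                         sweep(xa %*% t(R), 2, tv, "+"),
                         sweep(xb %*% t(R), 2, tv, "+"), p)$dss
    expect_lt(abs(moved - ab), 1e-9)
  }
})

test_that("zero deformation vectors are treated as unalignable", {
  set.seed(92)
  uA <- matrix(rnorm(30), 10, 3); uB <- matrix(rnorm(30), 10, 3)
  uA[4, ] <- 0
  p <- align_params(use_distance_constraint = FALSE)
  S <- score_matrix(uA, uB, sign = 1, params = p)
  expect_true(all(S[4, ] == -1))
})

test_that("residue profiles carry labels and uncovered residues score zero", {
  nodes <- random_nodes(seed = 95)
  m <- slow_modes(build_hessian(nodes), n_keep = 12, nodes = nodes)
  xyz <- node_xyz(nodes)
  r <- compute_dss(m, m, xyz, xyz)
  prof <- residue_profiles(r, nodes, nodes)
  expect_equal(nrow(prof$A), nrow(nodes))
  expect_equal(prof$A$r, r$r1)
  expect_equal(mean(prof$A$r) / 2 + mean(prof$B$r) / 2, r$dss,
               tolerance = 1e-12)
  # a residue no selected match covers contributes exactly 0
  covered <- rep(FALSE, nrow(nodes))
  sel <- r$matches[r$matches$selected, ]
  for (q in seq_len(nrow(sel)))
    covered[sel$i0[q] + 0:(sel$len[q] - 1)] <- TRUE
  if (any(!covered)) expect_true(all(r$r1[!covered] == 0))
})

test_that("end-to-end dss() handles scopes and superposition", {
  unit <- make_bundle(3, 12)
  r <- dss(unit, unit)
  expect_s3_class(r, "dss")
  expect_gte(r$dss, 3.6)
  expect_equal(r$tm, 1, tolerance = 1e-6)
  dimer <- make_multimer(unit, 2)
  rc <- dss(dimer, dimer, scopeA = "A", scopeB = "A_2")
  expect_equal(rc$n_nodes, c(36L, 36L))
  tab <- withr::local_tempfile(fileext = ".tsv")
  write_match_table(r, tab)
  expect_true(nrow(read.delim(tab)) >= 12)
})
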