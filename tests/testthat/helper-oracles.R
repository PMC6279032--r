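# Independent oracles and small fixture builders shared across tests.

# --- fixed-width PDB record writer for hand-built parsing fixtures --------
pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          occ = 1, alt = " ", type = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          type, serial, paste0(" ", name), alt, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0)
}

# --- brute-force global alignment score ----------------------------------
# Enumerates every strictly increasing set of matched columns; gap columns
# are whatever is left. Exact optimum for short sequences.
oracle_nw_score <- function(seqA, seqB, match = 1, mismatch = 0, gap = -0.5) {
  a <- strsplit(seqA, "")[[1]]; b <- strsplit(seqB, "")[[1]]
  n <- length(a); m <- length(b)
  best <- gap * (n + m)                      # align nothing
  for (k in seq_len(min(n, m))) {
    ia <- utils::combn(n, k, simplify = FALSE)
    ib <- utils::combn(m, k, simplify = FALSE)
    for (sa in ia) for (sb in ib) {
      sc <- sum(ifelse(a[sa] == b[sb], match, mismatch)) +
        gap * ((n - k) + (m - k))
      if (sc > best) best <- sc
    }
  }
  best
}

# --- exhaustive greedy match extraction ----------------------------------
# Same greedy rule as the package implementation, by full enumeration of
# every (i0, j0, len) diagonal segment at every round.
oracle_extract_matches <- function(S, min_len = 7L, max_matches = 200L) {
  nr <- nrow(S); nc <- ncol(S)
  rmask <- rep(FALSE, nr); cmask <- rep(FALSE, nc)
  out <- data.frame(i0 = integer(0), j0 = integer(0), len = integer(0),
                    score = numeric(0))
  while (nrow(out) < max_matches) {
    best <- NULL
    for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
      maxL <- min(nr - i0, nc - j0) + 1L
      if (maxL < min_len) next
      for (L in seq.int(min_len, maxL)) {
        ii <- i0 + 0:(L - 1L); jj <- j0 + 0:(L - 1L)
        if (any(rmask[ii]) || any(cmask[jj])) break
        sc <- 0
        for (t in seq_len(L)) sc <- sc + S[ii[t], jj[t]]
        if (sc <= 0) next
        if (is.null(best) || sc > best$score ||
            (sc == best$score &&
             (i0 < best$i0 || (i0 == best$i0 && j0 < best$j0))))
          best <- list(i0 = i0, j0 = j0, len = L, score = sc)
      }
    }
    if (is.null(best)) break
    out <- rbind(out, as.data.frame(best))
    rmask[best$i0 + 0:(best$len - 1L)] <- TRUE
    cmask[best$j0 + 0:(best$len - 1L)] <- TRUE
  }
  out
}

# --- textbook Pearson correlation ----------------------------------------
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# --- random connected node cloud (perturbed bundle) ----------------------
random_nodes <- function(n_helices = 3, len = 10, seed = 1, sigma = 0.4) {
  s <- perturb(make_bundle(n_helices, len), sigma, seed)
  extract_nodes(s)
}

# rigid transform helpers
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}
random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
transform_nodes <- function(nodes, R, tvec) {
  xyz <- node_xyz(nodes) %*% t(R)
  nodes$x <- xyz[, 1] + tvec[1]
  nodes$y <- xyz[, 2] + tvec[2]
  nodes$z <- xyz[, 3] + tvec[3]
  nodes
}

# two-family planted dataset: monomeric bundles vs the chain-A scope of
# dimerized copies of the same bundle (quaternary-structure effect in
# miniature), with mild coordinate noise
planted_dataset <- function(seed, n_per_family = 6L, sigma = 0.3) {
  unit <- make_bundle(3, 12)
  entries <- list()
  for (s in seq_len(n_per_family)) {
    entries[[length(entries) + 1L]] <- list(
      structure = perturb(unit, sigma, seed * 1000L + s),
      scope = NULL, label = sprintf("mono_%d", s))
  }
  for (s in seq_len(n_per_family)) {
    entries[[length(entries) + 1L]] <- list(
      structure = perturb(make_multimer(unit, 2), sigma,
                          seed * 1000L + 100L + s),
      scope = "A", label = sprintf("dimer_%d", s))
  }
  dataset_spec(entries)
}
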