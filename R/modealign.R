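# Local alignment of ANM modes and the dynamics similarity score (DSS).
#
# For residues i of protein A and j of protein B and a mode pair (k, l), the
# cell score is the cosine between the two per-residue deformation vectors
# minus a threshold C, optionally forced to -1 when the superposed residues
# are further apart than R_c (distance-constrained variant for homologous
# proteins). Because the overall sign of a mode is arbitrary each mode pair
# is aligned twice (original and negated second mode) and the better variant
# kept. High-scoring gapless diagonal segments ("matches") are extracted
# greedily per mode-pair matrix; the best 2n matches across all n x n mode
# combinations define per-residue similarity profiles whose two means
# average to the scalar DSS.

#' Alignment parameters for DSS computation
#'
#' @param C cosine threshold subtracted from each cosine, in `[0, 1]`
#'   (default 0.7: vectors closer than ~45 degrees score positively).
#' @param Rc distance constraint, Angstrom (default 10): superposed residue
#'   pairs further apart score -1 exactly.
#' @param n number of slowest non-trivial modes aligned (default 12).
#' @param min_len minimal match length, residues (default 7).
#' @param max_matches maximal matches kept per mode-pair matrix (default 200).
#' @param use_distance_constraint apply the `Rc` constraint? (default `TRUE`;
#'   disable for structurally dissimilar proteins).
#' @param sign_rule how the mode-sign variant is chosen: `"best_match"`
#'   (default) compares the best single match of each variant, `"total"`
#'   compares the summed score of all matches.
#' @return an `AlignParams` list.
#' @export
align_params <- function(C = 0.7, Rc = 10, n = 12L, min_len = 7L,
                         max_matches = 200L, use_distance_constraint = TRUE,
                         sign_rule = c("best_match", "total")) {
  stopifnot(C >= 0, C <= 1, min_len >= 1L, n >= 1L, Rc >= 0, max_matches >= 1L)
  structure(list(C = C, Rc = Rc, n = as.integer(n),
                 min_len = as.integer(min_len),
                 max_matches = as.integer(max_matches),
                 use_distance_constraint = isTRUE(use_distance_constraint),
                 sign_rule = match.arg(sign_rule)),
            class = "AlignParams")
}

#' Cosine score of two deformation vectors
#'
#' `u . v / (|u| |v|) - C`: positive when the cosine exceeds the threshold.
#'
#' @param u,v non-zero 3-vectors.
#' @param C cosine threshold.
#' @return score in `[-1 - C, 1 - C]`.
#' @export
residue_score <- function(u, v, C = 0.7) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("undefined direction: zero-length deformation vector")
  sum(u * v) / (nu * nv) - C
}

#' Distance-constrained cosine score
#'
#' [residue_score()] when the superposed residues are within `Rc`, `-1`
#' exactly beyond it (boundary inclusive).
#'
#' @param u,v non-zero 3-vectors.
#' @param r_ij superposed inter-residue distance, Angstrom.
#' @param C cosine threshold.
#' @param Rc distance cutoff, Angstrom.
#' @return score.
#' @export
constrained_score <- function(u, v, r_ij, C = 0.7, Rc = 10) {
  stopifnot(r_ij >= 0)
  if (r_ij <= Rc) residue_score(u, v, C) else -1
}

# cross pairwise distances between rows of a (NA x 3) and b (NB x 3)
.crossdist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# rows normalized to unit length; near-zero rows flagged via attribute
.unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  bad <- nrm < 1e-15
  nrm[bad] <- 1
  out <- m / nrm
  attr(out, "zero") <- bad
  out
}

# signed, masked score matrix from unit-row mode matrices and a precomputed
# distance matrix (NULL disables the constraint)
.score_from_units <- function(uA, uB, sign, C, dmat, Rc) {
  S <- sign * tcrossprod(uA, uB) - C
  if (!is.null(dmat)) S[dmat > Rc] <- -1
  zA <- attr(uA, "zero"); zB <- attr(uB, "zero")
  if (any(zA)) S[zA, ] <- -1
  if (any(zB)) S[, zB] <- -1
  S
}

#' Score matrix for one mode pair
#'
#' Cell (i, j) holds the (optionally distance-constrained) cosine score of
#' residue i's deformation vector in mode k of A against residue j's in mode
#' l of B, with `sign` applied to the second mode. Nodes with a zero
#' deformation vector are treated as unalignable (score -1).
#'
#' @param modeA_k,modeB_l N x 3 deformation-vector matrices.
#' @param coordsA,coordsB N x 3 superposed node coordinates (only used when
#'   the distance constraint is enabled).
#' @param sign `+1` or `-1`, applied to the second mode.
#' @param params an [align_params()] list.
#' @return numeric matrix (rows: A nodes, columns: B nodes).
#' @export
score_matrix <- function(modeA_k, modeB_l, coordsA = NULL, coordsB = NULL,
                         sign = 1, params = align_params()) {
  stopifnot(sign %in% c(-1, 1))
  if (!is.null(coordsA) && nrow(coordsA) != nrow(modeA_k))
    stop("coordinates and mode vectors of A disagree in length")
  if (!is.null(coordsB) && nrow(coordsB) != nrow(modeB_l))
    stop("coordinates and mode vectors of B disagree in length")
  dmat <- NULL
  if (params$use_distance_constraint) {
    if (is.null(coordsA) || is.null(coordsB))
      stop("distance constraint enabled but coordinates missing")
    dmat <- .crossdist(coordsA, coordsB)
  }
  .score_from_units(.unit_rows(modeA_k), .unit_rows(modeB_l),
                    sign, params$C, dmat, params$Rc)
}

#' Extract the best non-overlapping gapless matches
#'
#' Greedy high-scoring-segment extraction on one score matrix: repeatedly
#' take the diagonal segment of length at least `min_len` with the largest
#' positive total score among cells whose rows and columns are still
#' unmasked (ties: smallest `(i0, j0)` lexicographically), then mask its
#' rows and columns. Stops when no qualifying positive segment remains or
#' `max_matches` is reached.
#'
#' @param S numeric score matrix.
#' @param params an [align_params()] list.
#' @return data frame (`i0`, `j0`, `len`, `score`), ordered by decreasing
#'   score (the greedy extraction order).
#' @export
extract_matches <- function(S, params = align_params()) {
  .extract_matches_cpp(S, params$min_len, params$max_matches)
}

#' Align one mode pair with sign disambiguation
#'
#' The sign of a normal mode is arbitrary, so the pair is aligned twice
#' (second mode as-is and negated); the variant with the better score under
#' `params$sign_rule` wins (ties: `+1`).
#'
#' @inheritParams score_matrix
#' @return list with `sign` (chosen) and `matches` (data frame as returned
#'   by [extract_matches()]).
#' @export
align_mode_pair <- function(modeA_k, modeB_l, coordsA = NULL, coordsB = NULL,
                            params = align_params()) {
  dmat <- NULL
  if (params$use_distance_constraint) {
    if (is.null(coordsA) || is.null(coordsB))
      stop("distance constraint enabled but coordinates missing")
    dmat <- .crossdist(coordsA, coordsB)
  }
  .align_pair_units(.unit_rows(modeA_k), .unit_rows(modeB_l), dmat, params)
}

.align_pair_units <- function(uA, uB, dmat, params) {
  mp <- extract_matches(
    .score_from_units(uA, uB, 1, params$C, dmat, params$Rc), params)
  mm <- extract_matches(
    .score_from_units(uA, uB, -1, params$C, dmat, params$Rc), params)
  crit <- function(m) {
    if (nrow(m) == 0L) return(0)
    if (params$sign_rule == "best_match") max(m$score) else sum(m$score)
  }
  if (crit(mm) > crit(mp)) list(sign = -1, matches = mm)
  else list(sign = 1, matches = mp)
}

#' Dynamics similarity score of two superposed mode sets
#'
#' Runs [align_mode_pair()] for all `n x n` combinations of the `n` slowest
#' modes, pools every extracted match and selects the `2n` with the highest
#' total score (ties: `(k, l, i0, j0)` lexicographic). For each mode
#' combination, each residue keeps its single best cell score over the
#' selected matches covering it; the per-residue profile is the sum of these
#' best scores over combinations (uncovered residues contribute 0), and
#'
#' `DSS = (mean_i r1_i + mean_j r2_j) / 2`.
#'
#' @param modesA,modesB `ModeSet`s with at least `params$n` modes, already
#'   expressed in the common superposed frame.
#' @param coordsA,coordsB N x 3 superposed node coordinates.
#' @param params an [align_params()] list.
#' @param labels optional length-2 character vector naming the proteins.
#' @return a `dss` object: list with `dss` (scalar), `r1`, `r2` (per-residue
#'   profiles), `matches` (all pooled matches with a `selected` flag),
#'   `params`, `labels`, `n_nodes`.
#' @export
compute_dss <- function(modesA, modesB, coordsA, coordsB,
                        params = align_params(), labels = c("A", "B")) {
  n <- params$n
  if (length(modesA$values) < n || length(modesB$values) < n)
    stop("fewer than n = ", n, " non-trivial modes available")
  nA <- nrow(coordsA); nB <- nrow(coordsB)
  uA <- lapply(seq_len(n), function(k) .unit_rows(mode_vectors(modesA, k)))
  uB <- lapply(seq_len(n), function(l) .unit_rows(mode_vectors(modesB, l)))
  if (nrow(uA[[1]]) != nA || nrow(uB[[1]]) != nB)
    stop("mode vectors and coordinates disagree in node count")
  dmat <- if (params$use_distance_constraint) .crossdist(coordsA, coordsB)
          else NULL
  pool <- vector("list", n * n)
  signs <- matrix(1, n, n)
  p <- 0L
  for (k in seq_len(n)) for (l in seq_len(n)) {
    p <- p + 1L
    al <- .align_pair_units(uA[[k]], uB[[l]], dmat, params)
    signs[k, l] <- al$sign
    m <- al$matches
    if (nrow(m) > 0L) {
      m$k <- k; m$l <- l; m$sign <- al$sign
      pool[[p]] <- m
    }
  }
  pool <- do.call(rbind, pool)
  r1 <- numeric(nA); r2 <- numeric(nB)
  if (!is.null(pool) && nrow(pool) > 0L) {
    ord <- order(-pool$score, pool$k, pool$l, pool$i0, pool$j0)
    pool <- pool[ord, , drop = FALSE]
    rownames(pool) <- NULL
    pool$selected <- seq_len(nrow(pool)) <= 2L * n
    sel <- pool[pool$selected, , drop = FALSE]
    for (combo in unique(paste(sel$k, sel$l))) {
      sub <- sel[paste(sel$k, sel$l) == combo, , drop = FALSE]
      k <- sub$k[1]; l <- sub$l[1]
      S <- .score_from_units(uA[[k]], uB[[l]], signs[k, l], params$C,
                             dmat, params$Rc)
      bestA <- rep(-Inf, nA); bestB <- rep(-Inf, nB)
      for (r in seq_len(nrow(sub))) {
        ii <- sub$i0[r] + 0:(sub$len[r] - 1L)
        jj <- sub$j0[r] + 0:(sub$len[r] - 1L)
        v <- S[cbind(ii, jj)]
        bestA[ii] <- pmax(bestA[ii], v)
        bestB[jj] <- pmax(bestB[jj], v)
      }
      covA <- is.finite(bestA); covB <- is.finite(bestB)
      r1[covA] <- r1[covA] + bestA[covA]
      r2[covB] <- r2[covB] + bestB[covB]
    }
  } else {
    pool <- data.frame(i0 = integer(0), j0 = integer(0), len = integer(0),
                       score = numeric(0), k = integer(0), l = integer(0),
                       sign = numeric(0), selected = logical(0))
  }
  structure(list(dss = (mean(r1) + mean(r2)) / 2,
                 r1 = r1, r2 = r2,
                 matches = pool, params = params, labels = labels,
                 n_nodes = c(nA, nB)),
            class = "dss")
}

#' @export
print.dss <- function(x, ...) {
  cat("DSS(", x$labels[1], ", ", x$labels[2], ") = ",
      format(x$dss, digits = 6), "  [", sum(x$matches$selected),
      " selected matches over ", x$params$n, " slowest modes]\n", sep = "")
  invisible(x)
}

#' @export
summary.dss <- function(object, ...) {
  sel <- object$matches[object$matches$selected, , drop = FALSE]
  cat("Dynamics similarity between", object$labels[1], "(",
      object$n_nodes[1], "nodes ) and", object$labels[2], "(",
      object$n_nodes[2], "nodes )\n")
  cat("  DSS:", format(object$dss, digits = 6), "\n")
  cat("  mean residue profile:", format(mean(object$r1), digits = 4), "/",
      format(mean(object$r2), digits = 4), "\n")
  cat("  selected matches:", nrow(sel), "of", nrow(object$matches),
      "pooled;", "mode pairs used:",
      length(unique(paste(sel$k, sel$l))), "\n")
  if (nrow(sel) > 0L) {
    cat("  top matches:\n")
    print(head(sel[, c("k", "l", "sign", "i0", "j0", "len", "score")], 5L),
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.dss <- function(x, which = c("both", "A", "B"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "A"))
    graphics::plot(x$r1, type = "h", xlab = paste("residue of", x$labels[1]),
                   ylab = "similarity", main = x$labels[1], ...)
  if (which %in% c("both", "B"))
    graphics::plot(x$r2, type = "h", xlab = paste("residue of", x$labels[2]),
                   ylab = "similarity", main = x$labels[2], ...)
  invisible(x)
}

#' Per-residue dynamical similarity profiles
#'
#' @param result a `dss` object.
#' @param nodesA,nodesB optional `NodeModel`s supplying residue labels.
#' @return list of two data frames (`A`, `B`) with node labels (when
#'   available) and the per-residue score `r`.
#' @export
residue_profiles <- function(result, nodesA = NULL, nodesB = NULL) {
  mk <- function(r, nodes, label) {
    df <- if (!is.null(nodes))
      data.frame(chain = nodes$chain, resno = nodes$resno, kind = nodes$kind,
                 r = r, stringsAsFactors = FALSE)
    else data.frame(node = seq_along(r), r = r)
    df
  }
  list(A = mk(result$r1, nodesA, result$labels[1]),
       B = mk(result$r2, nodesB, result$labels[2]))
}

#' Write a match table as TSV
#' @param result a `dss` object.
#' @param path output file.
#' @export
write_match_table <- function(result, path) {
  write.table(result$matches[, c("k", "l", "sign", "i0", "j0", "len",
                                 "score", "selected")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise dynamics comparison of two structures
#'
#' End-to-end comparison: extract node models (if given structures), compute
#' the slowest modes of each full input, optionally restrict to a chain
#' scope, superpose the compared scopes with [superpose_iterative()], rotate
#' A's coordinates and mode vectors into B's frame, and run [compute_dss()].
#' Computing modes before rotation is exact: the eigenvectors of a rigidly
#' rotated network are the rotated eigenvectors.
#'
#' @param A,B `NodeModel`s or `StructureModel`s. Modes are computed on the
#'   full input (the biological unit as provided).
#' @param params an [align_params()] list.
#' @param scopeA,scopeB optional chain id vectors: modes are restricted to
#'   these chains after computation, and superposition uses only them.
#' @param superposition optional externally supplied `Superposition`
#'   (e.g. from [load_external_superposition()]); when given, the internal
#'   superposition is skipped.
#' @param labels length-2 character vector naming the two inputs.
#' @return a `dss` object, with `superposition` and `tm` fields added.
#' @export
dss <- function(A, B, params = align_params(), scopeA = NULL, scopeB = NULL,
                superposition = NULL, labels = c("A", "B")) {
  prep <- function(x) {
    if (inherits(x, "StructureModel")) extract_nodes(x)
    else if (inherits(x, "NodeModel")) x
    else stop("inputs must be NodeModel or StructureModel objects")
  }
  nodesA <- prep(A); nodesB <- prep(B)
  modesA <- slow_modes(build_hessian(nodesA), n_keep = params$n, nodes = nodesA)
  modesB <- slow_modes(build_hessian(nodesB), n_keep = params$n, nodes = nodesB)
  if (!is.null(scopeA)) { modesA <- restrict_modes(modesA, scopeA)
                          nodesA <- modesA$nodes }
  if (!is.null(scopeB)) { modesB <- restrict_modes(modesB, scopeB)
                          nodesB <- modesB$nodes }
  sp <- if (is.null(superposition)) superpose_iterative(nodesA, nodesB)
        else superposition
  xa <- apply_superposition(sp, node_xyz(nodesA))
  xb <- node_xyz(nodesB)
  # rotate A's mode vectors into B's frame
  modesA$vectors <- .rotate_mode_vectors(modesA$vectors, sp$R)
  out <- compute_dss(modesA, modesB, xa, xb, params, labels = labels)
  out$superposition <- sp
  out$tm <- sp$tm_score
  out
}

# apply a 3x3 rotation to every per-node 3-vector of a 3N x k vector matrix
.rotate_mode_vectors <- function(vectors, R) {
  n3 <- nrow(vectors)
  out <- vectors
  for (k in seq_len(ncol(vectors))) {
    m <- matrix(vectors[, k], ncol = 3L, byrow = TRUE) %*% t(R)
    out[, k] <- as.numeric(t(m))
  }
  out
}
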