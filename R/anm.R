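# Anisotropic Network Model: sparse Hessian and slow modes.
#
# Nodes within the cutoff are connected by identical harmonic springs; the
# 3N x 3N Hessian super-element for a contacting pair (i, j) is
# -(gamma / d_ij^2) * outer(r_ij, r_ij) and diagonal super-elements cancel
# the row sums (translation invariance). A connected network has exactly six
# zero modes (rigid translations and rotations); the slowest non-trivial
# modes approximate the collective motions used for dynamics comparison.

#' Build the ANM Hessian
#'
#' @param nodes a `NodeModel` (or N x 3 coordinate matrix), N >= 2.
#' @param cutoff contact cutoff, Angstrom (default 15).
#' @param gamma uniform spring constant (arbitrary units; default 1).
#' @return a `Hessian`: list with `H` (sparse symmetric 3N x 3N
#'   `Matrix`), `cutoff`, `gamma`, `n_nodes`, `xyz`, `n_components`.
#' @export
build_hessian <- function(nodes, cutoff = 15, gamma = 1) {
  xyz <- if (is.matrix(nodes)) nodes else node_xyz(nodes)
  n <- nrow(xyz)
  stopifnot(n >= 2L)
  D <- as.matrix(dist(xyz))
  off <- D[upper.tri(D)]
  if (any(off < 1e-6))
    stop("degenerate geometry: coincident nodes (distance < 1e-6 Angstrom)")
  idx <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no contacts within cutoff")
  i <- idx[, 1]; j <- idx[, 2]
  rij <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
  d2 <- rowSums(rij^2)
  ii <- jj <- xx <- vector("list", 9L)
  p <- 0L
  for (a in 1:3) for (b in 1:3) {
    p <- p + 1L
    val <- -gamma * rij[, a] * rij[, b] / d2
    # off-diagonal blocks (i,j) and (j,i); diagonal blocks accumulate -val
    ii[[p]] <- c(3L * (i - 1L) + a, 3L * (j - 1L) + a,
                 3L * (i - 1L) + a, 3L * (j - 1L) + a)
    jj[[p]] <- c(3L * (j - 1L) + b, 3L * (i - 1L) + b,
                 3L * (i - 1L) + b, 3L * (j - 1L) + b)
    xx[[p]] <- c(val, val, -val, -val)
  }
  H <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(3L * n, 3L * n))
  H <- Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
  comp <- check_connectivity(xyz, cutoff = cutoff)
  structure(list(H = H, cutoff = cutoff, gamma = gamma, n_nodes = n,
                 xyz = xyz, n_components = max(comp)),
            class = "Hessian")
}

#' @export
print.Hessian <- function(x, ...) {
  cat("ANM Hessian:", x$n_nodes, "nodes, cutoff", x$cutoff,
      "Angstrom, gamma", x$gamma, ",", x$n_components, "component(s)\n")
  invisible(x)
}

#' Connected components of the contact network
#'
#' @param nodes a `NodeModel` or N x 3 coordinate matrix.
#' @param cutoff contact cutoff, Angstrom.
#' @return integer component label per node (1-based, by first occurrence).
#' @export
check_connectivity <- function(nodes, cutoff = 15) {
  xyz <- if (is.matrix(nodes)) nodes else node_xyz(nodes)
  n <- nrow(xyz)
  if (n == 1L) return(1L)
  A <- as.matrix(dist(xyz)) <= cutoff
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

#' Slowest non-trivial ANM modes
#'
#' Computes the `n_keep + 6` algebraically smallest eigenpairs of the
#' Hessian with a shift-invert Lanczos solver (ARPACK via igraph) on a
#' sparse Cholesky factor of `H + sigma I`, polishes eigenvalues by Rayleigh
#' quotients, removes exactly the six rigid-body modes (eigenvalue below
#' 1e-8 times the largest computed eigenvalue) and returns the remaining
#' modes in ascending order. `method = "dense"` runs a full dense
#' eigendecomposition instead (used as an independent cross-check).
#'
#' @param hessian a `Hessian` (connected network).
#' @param n_keep number of non-trivial modes to keep (default 40).
#' @param method `"lanczos"` (default) or `"dense"`.
#' @param nodes optional `NodeModel` carried along for scope bookkeeping.
#' @return a `ModeSet`: list with `values` (ascending, length `n_keep`),
#'   `vectors` (3N x n_keep, orthonormal unit columns), `n_trivial_removed`,
#'   `nodes`.
#' @export
slow_modes <- function(hessian, n_keep = 40L, method = c("lanczos", "dense"),
                       nodes = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(hessian, "Hessian"))
  if (hessian$n_components > 1L)
    stop("contact network is disconnected (", hessian$n_components,
         " components); modes are not well defined")
  n3 <- 3L * hessian$n_nodes
  m <- n_keep + 6L
  if (m > n3) stop("n_keep + 6 exceeds 3N (", n3, ")")
  H <- hessian$H
  if (method == "dense") {
    ev <- eigen(as.matrix(H), symmetric = TRUE)
    ord <- order(ev$values)[seq_len(m)]
    lam <- ev$values[ord]; V <- ev$vectors[, ord, drop = FALSE]
  } else {
    sigma <- 1e-6 * max(Matrix::diag(H))
    ch <- NULL
    for (try_sigma in sigma * c(1, 100, 1e4)) {
      ch <- tryCatch(Matrix::Cholesky(H + try_sigma * Matrix::Diagonal(n3)),
                     error = function(e) NULL)
      if (!is.null(ch)) { sigma <- try_sigma; break }
    }
    if (is.null(ch)) stop("numerical failure: could not factor shifted Hessian")
    op <- function(x, extra = NULL) as.numeric(Matrix::solve(ch, x))
    ncv <- min(n3, max(2L * m + 1L, 40L))
    res <- tryCatch(
      igraph::arpack(op, sym = TRUE,
                     options = list(n = n3, nev = m, ncv = ncv, which = "LA",
                                    maxiter = 10000L, tol = 1e-10)),
      error = function(e) stop("eigensolver did not converge: ",
                               conditionMessage(e), call. = FALSE))
    V <- res$vectors
    lam <- colSums(V * as.matrix(H %*% V))   # Rayleigh polish
    ord <- order(lam)
    lam <- lam[ord]; V <- V[, ord, drop = FALSE]
  }
  tol <- 1e-8 * max(lam)
  n_trivial <- sum(lam < tol)
  if (n_trivial > 6L)
    stop("more than 6 near-zero modes (", n_trivial,
         "): disconnected or degenerate network")
  if (n_trivial < 6L)
    stop("fewer than 6 near-zero modes computed (", n_trivial,
         "): eigensolver accuracy problem")
  keep <- seq.int(7L, m)
  V <- V[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude entry of each mode is positive
  for (k in seq_len(ncol(V))) {
    piv <- which.max(abs(V[, k]))
    if (V[piv, k] < 0) V[, k] <- -V[, k]
  }
  structure(list(values = lam[keep], vectors = V,
                 n_trivial_removed = 6L, nodes = nodes),
            class = "ModeSet")
}

#' @export
print.ModeSet <- function(x, ...) {
  cat("ModeSet:", length(x$values), "non-trivial modes over",
      nrow(x$vectors) / 3L, "nodes; eigenvalues",
      format(x$values[1], digits = 4), "..",
      format(x$values[length(x$values)], digits = 4), "\n")
  invisible(x)
}

#' Per-node deformation vectors of one mode
#' @param modes a `ModeSet`.
#' @param k mode index (1 = slowest non-trivial).
#' @return N x 3 matrix of deformation vectors.
#' @export
mode_vectors <- function(modes, k) {
  v <- modes$vectors[, k]
  matrix(v, ncol = 3L, byrow = TRUE)
}

#' Restrict a mode set to a chain scope
#'
#' Drops the per-node 3-vectors of nodes outside the scope. Eigenvalues and
#' mode identity are preserved and vectors are deliberately not
#' re-normalized: the cosine score normalizes per-residue vectors, so global
#' scale is irrelevant.
#'
#' @param modes a `ModeSet` whose `nodes` field is set.
#' @param chains character vector of chain ids to keep.
#' @return a `ModeSet` over the restricted nodes.
#' @export
restrict_modes <- function(modes, chains) {
  stopifnot(inherits(modes, "ModeSet"))
  if (is.null(modes$nodes))
    stop("mode set carries no node model; cannot restrict")
  keep <- modes$nodes$chain %in% chains
  if (!any(keep)) stop("empty selection: no nodes in scope ",
                       paste(chains, collapse = ","))
  rows <- as.vector(t(outer(which(keep) - 1L, 1:3, function(i, a) 3L * i + a)))
  nodes <- .new_nodes(as.data.frame(modes$nodes)[keep, , drop = FALSE],
                      scope = chains)
  structure(list(values = modes$values,
                 vectors = modes$vectors[rows, , drop = FALSE],
                 n_trivial_removed = modes$n_trivial_removed, nodes = nodes),
            class = "ModeSet")
}

#' Export modes in NMD format
#'
#' Minimal NMD (normal mode data) file: a `coordinates` record followed by
#' one `mode` record per mode (index, eigenvalue, then the 3N components),
#' loadable by molecular viewers for animation.
#'
#' @param modes a `ModeSet` with `nodes`.
#' @param path output file.
#' @export
write_nmd <- function(modes, path) {
  stopifnot(!is.null(modes$nodes))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("coordinates",
                   paste(formatC(t(node_xyz(modes$nodes)), format = "f",
                                 digits = 3), collapse = " ")), con)
  for (k in seq_along(modes$values))
    writeLines(paste("mode", k, formatC(modes$values[k], format = "g",
                                        digits = 10),
                     paste(formatC(modes$vectors[, k], format = "g",
                                   digits = 6), collapse = " ")), con)
  invisible(path)
}

#' Write eigenvalues as TSV
#' @param modes a `ModeSet`.
#' @param path output file.
#' @export
write_eigenvalues <- function(modes, path) {
  write.table(data.frame(mode = seq_along(modes$values),
                         eigenvalue = modes$values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
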