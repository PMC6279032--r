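# Rigid superposition and structural similarity.
#
# Mode comparison requires both structures in one frame. The pipeline seeds
# a residue correspondence by global sequence alignment, refines it by
# iterated Kabsch fitting under a shrinking distance cutoff, and reports the
# transform maximizing the TM-score. Externally computed rotation matrices
# (the plain-text layout emitted by common structure-alignment tools) can be
# imported instead.

#' Global sequence alignment (linear gap penalty)
#'
#' Needleman-Wunsch dynamic programming over one-letter residue codes with a
#' linear gap penalty. Traceback ties prefer the diagonal move, then the
#' vertical (gap in the second sequence). Only matched (non-gap) columns are
#' returned.
#'
#' @param seqA,seqB non-empty character strings.
#' @param match,mismatch,gap scores (defaults 1, 0, -0.5).
#' @return a `Correspondence`: two-column integer matrix (`i`, `j`) of
#'   1-based matched positions, strictly increasing in both columns.
#' @export
align_sequences <- function(seqA, seqB, match = 1, mismatch = 0, gap = -0.5) {
  a <- strsplit(seqA, "")[[1]]; b <- strsplit(seqB, "")[[1]]
  n <- length(a); m <- length(b)
  stopifnot(n >= 1L, m >= 1L)
  F <- matrix(0, n + 1L, m + 1L)
  F[, 1] <- gap * (0:n); F[1, ] <- gap * (0:m)
  ptr <- matrix(0L, n + 1L, m + 1L)   # 1 diag, 2 up, 3 left
  ptr[, 1] <- 2L; ptr[1, ] <- 3L; ptr[1, 1] <- 0L
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      d <- F[i, j] + sub[j]; u <- F[i, j + 1L] + gap; l <- F[i + 1L, j] + gap
      best <- max(d, u, l)
      F[i + 1L, j + 1L] <- best
      ptr[i + 1L, j + 1L] <- if (d == best) 1L else if (u == best) 2L else 3L
    }
  }
  i <- n + 1L; j <- m + 1L; pi_ <- integer(0); pj <- integer(0)
  while (i > 1L || j > 1L) {
    p <- ptr[i, j]
    if (p == 1L) { pi_ <- c(i - 1L, pi_); pj <- c(j - 1L, pj); i <- i - 1L; j <- j - 1L }
    else if (p == 2L) i <- i - 1L
    else j <- j - 1L
  }
  structure(cbind(i = pi_, j = pj), score = F[n + 1L, m + 1L],
            class = "Correspondence")
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Closed-form SVD solution for the proper rotation and translation
#' minimizing the RMSD of corresponded points of A onto B.
#'
#' @param coordsA,coordsB N x 3 coordinate matrices (Angstrom).
#' @param correspondence two-column index matrix (rows of A, rows of B);
#'   defaults to the identity pairing.
#' @return a `Superposition`: list with `R` (3x3, det +1), `t` (length 3),
#'   `correspondence`, `rmsd`. Apply as `x %*% t(R) + t`.
#' @export
kabsch <- function(coordsA, coordsB, correspondence = NULL) {
  if (is.null(correspondence))
    correspondence <- cbind(seq_len(nrow(coordsA)), seq_len(nrow(coordsA)))
  A <- coordsA[correspondence[, 1], , drop = FALSE]
  B <- coordsB[correspondence[, 2], , drop = FALSE]
  if (nrow(A) < 3L) stop("degenerate superposition: fewer than 3 pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  s <- svd(crossprod(Ac, Bc))          # t(Ac) %*% Bc
  if (min(s$d) < 1e-10 && s$d[2] < 1e-10)
    stop("degenerate superposition: collinear points")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- unname(cb - as.numeric(R %*% ca))
  fitted <- Ac %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Bc)^2)))
  structure(list(R = R, t = tvec, correspondence = correspondence,
                 rmsd = rmsd, tm_score = NA_real_),
            class = "Superposition")
}

#' Apply a superposition to coordinates
#' @param sp a `Superposition`.
#' @param coords N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(coords %*% t(sp$R), 2, sp$t, "+")
}

#' TM-score of a superposed correspondence
#'
#' `TM = (1/L) * sum over matched pairs of 1 / (1 + (d_i/d0)^2)` with
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, floored at 0.5 Angstrom; `L` is the
#' normalization length.
#'
#' @param coordsA,coordsB N x 3 matrices; `coordsA` already transformed into
#'   B's frame (or pass `superposition`).
#' @param correspondence two-column index matrix.
#' @param L_norm normalization residue count (>= 1).
#' @param superposition optional `Superposition` applied to `coordsA` first.
#' @return score in (0, 1].
#' @export
tm_score <- function(coordsA, coordsB, correspondence, L_norm,
                     superposition = NULL) {
  stopifnot(L_norm >= 1)
  if (!is.null(superposition))
    coordsA <- apply_superposition(superposition, coordsA)
  d <- sqrt(rowSums((coordsA[correspondence[, 1], , drop = FALSE] -
                     coordsB[correspondence[, 2], , drop = FALSE])^2))
  d0 <- max(1.24 * sign(L_norm - 15) * abs(L_norm - 15)^(1/3) - 1.8, 0.5)
  sum(1 / (1 + (d / d0)^2)) / L_norm
}

#' Sequence-guided iterative superposition maximizing TM-score
#'
#' Seeds a correspondence between the C-alpha nodes of two node models by
#' global sequence alignment, then iterates: Kabsch fit on the current pairs,
#' re-filter the seed pairs by a distance cutoff shrinking linearly from 8 to
#' 4 Angstrom over 20 iterations. The transform with the best TM-score
#' (normalized by the shorter structure's C-alpha count) is returned.
#'
#' @param nodesA,nodesB `NodeModel`s with at least 7 C-alpha nodes each.
#' @return a `Superposition` with `tm_score` filled in.
#' @export
superpose_iterative <- function(nodesA, nodesB) {
  caA <- nodesA[nodesA$kind == "CA", , drop = FALSE]
  caB <- nodesB[nodesB$kind == "CA", , drop = FALSE]
  if (nrow(caA) < 7L || nrow(caB) < 7L)
    stop("need at least 7 C-alpha nodes per structure")
  xa <- cbind(caA$x, caA$y, caA$z); xb <- cbind(caB$x, caB$y, caB$z)
  seqA <- paste(bio3d::aa321(caA$resid), collapse = "")
  seqB <- paste(bio3d::aa321(caB$resid), collapse = "")
  seed <- align_sequences(seqA, seqB)
  if (nrow(seed) < 3L)
    stop("superposition failure: seed correspondence below 3 pairs")
  L_norm <- min(nrow(caA), nrow(caB))
  corr <- seed
  best <- NULL
  n_iter <- 20L
  for (it in seq_len(n_iter)) {
    sp <- tryCatch(kabsch(xa, xb, corr), error = function(e) NULL)
    if (is.null(sp)) break
    sp$tm_score <- tm_score(xa, xb, corr, L_norm, superposition = sp)
    if (is.null(best) || sp$tm_score > best$tm_score) best <- sp
    cutoff <- 8 - (it - 1L) * 4 / (n_iter - 1L)
    xat <- apply_superposition(sp, xa)
    d <- sqrt(rowSums((xat[seed[, 1], , drop = FALSE] -
                       xb[seed[, 2], , drop = FALSE])^2))
    nxt <- seed[d <= cutoff, , drop = FALSE]
    if (nrow(nxt) < 3L) break
    if (nrow(nxt) == nrow(corr) && all(nxt == corr) && it > 1L &&
        cutoff <= 4) break
    corr <- nxt
  }
  if (is.null(best))
    stop("superposition failure: correspondence collapsed below 3 pairs ",
         "(structures too dissimilar)")
  best
}

#' @export
print.Superposition <- function(x, ...) {
  cat("Superposition:", nrow(x$correspondence), "pairs, RMSD",
      format(x$rmsd, digits = 4), "Angstrom")
  if (!is.na(x$tm_score)) cat(", TM-score", format(x$tm_score, digits = 4))
  cat("\n")
  invisible(x)
}

#' Rotation angle of a superposition, degrees
#' @param R a 3x3 rotation matrix.
#' @return rotation angle in degrees.
#' @export
rotation_angle <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Read an external superposition matrix
#'
#' Plain-text layout: three rows of `t_i r_i1 r_i2 r_i3` (translation then
#' the rotation row), as emitted by common structure-alignment tools. Lines
#' starting with `#` are ignored. The rotation must be proper (det +1 within
#' 1e-4, orthonormal within 1e-4).
#'
#' @param path file path.
#' @return a transform-only `Superposition` (empty correspondence, NA rmsd).
#' @export
load_external_superposition <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 3L) stop("malformed matrix file: expected 3 data rows")
  vals <- lapply(lines[1:3], function(l) as.numeric(strsplit(l, "\\s+")[[1]]))
  if (any(vapply(vals, length, 1L) != 4L) || anyNA(unlist(vals)))
    stop("malformed matrix file: each row must hold 4 numbers")
  m <- do.call(rbind, vals)
  R <- m[, 2:4, drop = FALSE]; tvec <- m[, 1]
  if (max(abs(crossprod(R) - diag(3))) > 1e-4)
    stop("invalid rotation: not orthonormal within 1e-4")
  if (abs(det(R) - 1) > 1e-4)
    stop("invalid rotation: determinant ", format(det(R)), " (expected +1)")
  structure(list(R = R, t = tvec,
                 correspondence = cbind(i = integer(0), j = integer(0)),
                 rmsd = NA_real_, tm_score = NA_real_),
            class = "Superposition")
}

#' Write a superposition matrix in the external plain-text layout
#' @param sp a `Superposition`.
#' @param path output file.
#' @export
write_external_superposition <- function(sp, path) {
  rows <- vapply(1:3, function(i)
    paste(formatC(c(sp$t[i], sp$R[i, ]), format = "g", digits = 17),
          collapse = " "), "")
  writeLines(rows, path)
  invisible(path)
}
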