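# Dataset-level pipeline: pairwise DSS matrices, dynamics-based clustering,
# mode-count selection scan, reference-state 2-D mapping and the
# DSS-vs-TM-score table.

#' Define a dataset for pairwise dynamics comparison
#'
#' @param entries list of entries, each a list with `structure` (file path,
#'   `StructureModel` or `NodeModel`), optional `scope` (chain id vector;
#'   `NULL` compares the whole assembly) and `label` (unique).
#' @return a `DatasetSpec`.
#' @export
dataset_spec <- function(entries) {
  labels <- vapply(entries, function(e) as.character(e$label), "")
  if (anyDuplicated(labels)) stop("dataset labels must be unique")
  structure(list(entries = entries, labels = labels), class = "DatasetSpec")
}

#' @export
print.DatasetSpec <- function(x, ...) {
  cat("DatasetSpec:", length(x$entries), "entries:",
      paste(head(x$labels, 8L), collapse = ", "),
      if (length(x$labels) > 8L) "..." else "", "\n")
  invisible(x)
}

# load + node-extract + mode-compute one entry; modes on the full input
# (biological unit as provided), then restricted to the entry scope
.prepare_entry <- function(entry, n_keep) {
  x <- entry$structure
  if (is.character(x)) x <- read_structure(x)
  nodes <- if (inherits(x, "NodeModel")) x else extract_nodes(x)
  modes <- slow_modes(build_hessian(nodes), n_keep = n_keep, nodes = nodes)
  if (!is.null(entry$scope)) {
    modes <- restrict_modes(modes, entry$scope)
    nodes <- modes$nodes
  }
  list(nodes = nodes, modes = modes, label = as.character(entry$label))
}

# one prepared pair -> dss object (A rotated into B's frame)
.pair_dss <- function(pa, pb, sp, params) {
  modesA <- pa$modes
  modesA$vectors <- .rotate_mode_vectors(modesA$vectors, sp$R)
  compute_dss(modesA, pb$modes,
              apply_superposition(sp, node_xyz(pa$nodes)),
              node_xyz(pb$nodes),
              params, labels = c(pa$label, pb$label))
}

#' Pairwise DSS matrix over a dataset
#'
#' For every unordered pair of entries: superpose the compared scopes
#' ([superpose_iterative()]), carry A's modes into B's frame and compute the
#' DSS; the diagonal holds each entry's self-DSS and a companion matrix
#' holds the pairwise TM-scores. Pair-level superposition failures are
#' recorded (`NA` in the matrix) and reported, not silently dropped.
#'
#' @param dataset a `DatasetSpec` with at least 2 entries.
#' @param params an [align_params()] list.
#' @return a `dss_matrix` object: list with `dss` (symmetric, labelled),
#'   `tm`, `labels`, `params`, `failures` (data frame of failed pairs).
#' @export
dss_matrix <- function(dataset, params = align_params()) {
  stopifnot(inherits(dataset, "DatasetSpec"), length(dataset$entries) >= 2L)
  prep <- lapply(dataset$entries, .prepare_entry, n_keep = params$n)
  .pairwise_dss(prep, params, dataset$labels)
}

.pairwise_dss <- function(prep, params, labels, with_self = TRUE) {
  K <- length(prep)
  M <- matrix(NA_real_, K, K, dimnames = list(labels, labels))
  TM <- matrix(NA_real_, K, K, dimnames = list(labels, labels))
  fails <- list()
  for (i in seq_len(K)) {
    if (with_self) {
      idsp <- structure(list(R = diag(3), t = c(0, 0, 0),
                             correspondence = cbind(i = integer(0),
                                                    j = integer(0)),
                             rmsd = 0, tm_score = 1),
                        class = "Superposition")
      M[i, i] <- .pair_dss(prep[[i]], prep[[i]], idsp, params)$dss
      TM[i, i] <- 1
    }
    for (j in if (i < K) seq.int(i + 1L, K) else integer(0)) {
      sp <- tryCatch(superpose_iterative(prep[[i]]$nodes, prep[[j]]$nodes),
                     error = function(e) e)
      if (inherits(sp, "error")) {
        warning("pair (", labels[i], ", ", labels[j], ") failed: ",
                conditionMessage(sp), call. = FALSE)
        fails[[length(fails) + 1L]] <-
          data.frame(a = labels[i], b = labels[j],
                     reason = conditionMessage(sp))
        next
      }
      r <- .pair_dss(prep[[i]], prep[[j]], sp, params)
      M[i, j] <- M[j, i] <- r$dss
      TM[i, j] <- TM[j, i] <- sp$tm_score
    }
  }
  structure(list(dss = M, tm = TM, labels = labels, params = params,
                 failures = if (length(fails)) do.call(rbind, fails)
                            else NULL),
            class = "dss_matrix")
}

#' @export
print.dss_matrix <- function(x, ...) {
  cat("DSS matrix over", length(x$labels), "entries (n =", x$params$n,
      "modes); off-diagonal range",
      paste(format(range(x$dss[upper.tri(x$dss)], na.rm = TRUE), digits = 4),
            collapse = " .. "), "\n")
  if (!is.null(x$failures))
    cat(" ", nrow(x$failures), "pair(s) failed superposition\n")
  invisible(x)
}

#' @export
plot.dss_matrix <- function(x, ...) {
  K <- length(x$labels)
  graphics::image(seq_len(K), seq_len(K), x$dss, axes = FALSE,
                  xlab = "", ylab = "", main = "pairwise DSS", ...)
  graphics::axis(1, seq_len(K), x$labels, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(K), x$labels, las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Convert a DSS matrix to a distance matrix
#'
#' `d_ij = max(DSS) - DSS_ij` off the diagonal, `d_ii = 0`: an affine,
#' rank-reversing, non-negative transform. `style = "inverse"` uses
#' `1 / (1 + DSS)` instead (for strictly positive similarity scales).
#' Missing pairs (failed superpositions) are imputed at the maximum distance
#' with a warning.
#'
#' @param m a `dss_matrix` or plain symmetric similarity matrix.
#' @param style `"max_minus"` (default) or `"inverse"`.
#' @return symmetric non-negative distance matrix with zero diagonal.
#' @export
to_distance <- function(m, style = c("max_minus", "inverse")) {
  style <- match.arg(style)
  S <- if (inherits(m, "dss_matrix")) m$dss else m
  nas <- is.na(S); diag(nas) <- FALSE
  hi <- max(S, na.rm = TRUE)
  d <- if (style == "max_minus") hi - S else 1 / (1 + S)
  if (any(nas)) {
    warning(sum(nas) / 2, " missing pair(s) imputed at maximum distance",
            call. = FALSE)
    d[nas] <- max(d, na.rm = TRUE)
  }
  diag(d) <- 0
  d
}

#' Hierarchical clustering of a distance matrix
#'
#' Standard agglomerative clustering (`stats::hclust`); the default complete
#' linkage matches the default of the reference clustering function.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal (e.g.
#'   from [to_distance()]).
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @return an `hclust` tree with the matrix labels as leaves.
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "average",
                                                "single")) {
  linkage <- match.arg(linkage)
  if (!is.matrix(d) || nrow(d) != ncol(d) ||
      max(abs(d - t(d))) > 1e-9 || any(d < 0))
    stop("expected a symmetric non-negative distance matrix")
  hclust(as.dist(d), method = linkage)
}

#' Write a dendrogram as a Newick file
#'
#' Branch lengths follow the ultrametric dendrogram convention: each leaf
#' sits at depth `height / 2` below its merge (so a 2-leaf tree merged at
#' height 3 is written `(A:1.5,B:1.5);`). Labels containing spaces or
#' Newick metacharacters are single-quoted, with internal quotes doubled.
#'
#' @param tree an `hclust` object.
#' @param path output file, or `NULL` to return the string.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  lab <- tree$labels
  if (is.null(lab)) lab <- as.character(seq_len(nrow(tree$merge) + 1L))
  esc <- function(s) {
    if (grepl("[][ \t():;,']", s))
      paste0("'", gsub("'", "''", s, fixed = TRUE), "'")
    else s
  }
  rec <- function(node) {
    h <- tree$height[node]
    parts <- vapply(tree$merge[node, ], function(child) {
      if (child < 0) paste0(esc(lab[-child]), ":", format(h / 2, digits = 15))
      else paste0(rec(child), ":",
                  format((h - tree$height[child]) / 2, digits = 15))
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  s <- paste0(rec(nrow(tree$merge)), ";")
  if (!is.null(path)) { writeLines(s, path); return(invisible(s)) }
  s
}

#' Mode-count selection scan
#'
#' Computes the pairwise DSS matrix for each mode count in `n_values` and
#' the Pearson correlation between the strict-upper-triangle DSS vectors of
#' successive counts. Rows are labelled by the larger count of each pair, so
#' the row for `n = 4` holds the correlation between the DSS computed with
#' the 2 and with the 4 slowest modes. A plateau in the correlation
#' indicates that further modes no longer change the score ranking.
#'
#' @param dataset a `DatasetSpec` with at least 3 entries.
#' @param n_values increasing mode counts (default `seq(2, 20, 2)`).
#' @param params an [align_params()] list (its `n` is overridden per scan
#'   point).
#' @return data frame (`n`, `correlation`); a zero-variance DSS vector
#'   yields `NA` with a warning for that row. The per-`n` upper-triangle DSS
#'   vectors are attached as attribute `"dss_vectors"` (a named list).
#' @export
modecount_scan <- function(dataset, n_values = seq(2L, 20L, 2L),
                           params = align_params()) {
  stopifnot(inherits(dataset, "DatasetSpec"), length(dataset$entries) >= 3L,
            length(n_values) >= 2L, !is.unsorted(n_values))
  prep <- lapply(dataset$entries, .prepare_entry, n_keep = max(n_values))
  K <- length(prep)
  # superpositions are mode-count independent: compute once per pair
  sps <- vector("list", K * K)
  vecs <- vector("list", length(n_values))
  for (v in seq_along(n_values)) {
    pn <- params; pn$n <- as.integer(n_values[v])
    M <- matrix(NA_real_, K, K)
    for (i in seq_len(K - 1L)) for (j in seq.int(i + 1L, K)) {
      id <- (i - 1L) * K + j
      if (is.null(sps[[id]]))
        sps[[id]] <- superpose_iterative(prep[[i]]$nodes, prep[[j]]$nodes)
      M[i, j] <- .pair_dss(prep[[i]], prep[[j]], sps[[id]], pn)$dss
    }
    vecs[[v]] <- M[upper.tri(M)]
  }
  out <- data.frame(n = n_values[-1L], correlation = NA_real_)
  for (v in seq.int(2L, length(n_values))) {
    a <- vecs[[v - 1L]]; b <- vecs[[v]]
    if (sd(a) == 0 || sd(b) == 0) {
      warning("zero-variance DSS vector at n = ", n_values[v],
              "; correlation undefined", call. = FALSE)
    } else out$correlation[v - 1L] <- cor(a, b)
  }
  names(vecs) <- n_values
  attr(out, "dss_vectors") <- vecs
  out
}

#' Reference-state similarity map
#'
#' For each entry, the arithmetic mean of its DSS against two reference
#' label sets (e.g. representatives of the tense and fully liganded relaxed
#' quaternary states of hemoglobin); self-pairs are excluded from the mean
#' when the entry is itself a reference. Plotting `mean_B` against `mean_A`
#' gives a 2-D map locating every structure between the two states.
#'
#' @param m a `dss_matrix`.
#' @param refs_A,refs_B non-empty character vectors of dataset labels.
#' @return data frame (`label`, `mean_A`, `mean_B`).
#' @export
reference_map <- function(m, refs_A, refs_B) {
  stopifnot(inherits(m, "dss_matrix"),
            length(refs_A) >= 1L, length(refs_B) >= 1L)
  missing <- setdiff(c(refs_A, refs_B), m$labels)
  if (length(missing))
    stop("reference label(s) not in dataset: ", paste(missing, collapse = ", "))
  avg <- function(label, refs) {
    refs <- setdiff(refs, label)
    if (length(refs) == 0L) return(NA_real_)
    mean(m$dss[label, refs])
  }
  data.frame(label = m$labels,
             mean_A = vapply(m$labels, avg, 1, refs = refs_A),
             mean_B = vapply(m$labels, avg, 1, refs = refs_B),
             row.names = NULL)
}

#' Paired DSS / TM-score table
#'
#' One row per unordered pair of dataset entries, for scatter plots of
#' dynamics similarity against structural similarity.
#'
#' @param m a `dss_matrix` with companion TM-scores.
#' @return data frame (`label_i`, `label_j`, `tm_score`, `dss`).
#' @export
dss_vs_tmscore <- function(m) {
  stopifnot(inherits(m, "dss_matrix"))
  idx <- which(upper.tri(m$dss), arr.ind = TRUE)
  data.frame(label_i = m$labels[idx[, 1]], label_j = m$labels[idx[, 2]],
             tm_score = m$tm[idx], dss = m$dss[idx], row.names = NULL)
}

#' Write a labelled matrix as TSV
#' @param m a `dss_matrix` or labelled matrix.
#' @param path output file.
#' @param what `"dss"` or `"tm"` when `m` is a `dss_matrix`.
#' @export
write_matrix_tsv <- function(m, path, what = c("dss", "tm")) {
  what <- match.arg(what)
  M <- if (inherits(m, "dss_matrix")) m[[what]] else m
  write.table(M, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
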