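# Structure input and coarse-grained node extraction.
#
# A StructureModel is a light container around an atom table (one row per
# atom, coordinates in Angstrom); a NodeModel is the ordered coarse-grained
# node list the ANM operates on: one node per residue at its C-alpha, plus
# four pseudo-nodes (CHA, CHB, CHC, CHD methine carbons) per heme group.

#' Residue names recognised as heme groups
#'
#' Chemical component identifiers treated as heme when extracting pseudo-nodes.
#' @export
HEME_RESIDUES <- c("HEM", "HEC", "HEA", "HEB")

.new_structure <- function(atoms, source = NA_character_, model = 1L) {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source, model = model),
            class = "StructureModel")
}

.atom_cols <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
                "insert", "x", "y", "z", "o", "b", "elesy")

#' Read a protein structure from a PDB or mmCIF file
#'
#' Parses all chains and heteroatoms of one model. Alternate locations are
#' resolved to the highest-occupancy record (ties: first occurrence).
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (from the file extension).
#' @param model model number to extract from multi-model files (default 1).
#' @return a `StructureModel`: list with an `atoms` data frame (type, eleno,
#'   elety, alt, resid, chain, resno, insert, x, y, z, o, b, elesy), the
#'   source path and the model number.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), model = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  atoms <- raw$atom
  if (is.null(atoms) || nrow(atoms) == 0L)
    stop("empty structure: no atoms in ", path)
  n_models <- if (is.matrix(raw$xyz)) nrow(raw$xyz) else 1L
  if (model > n_models)
    stop("model ", model, " requested but file holds ", n_models)
  xyz <- if (is.matrix(raw$xyz)) raw$xyz[model, ] else as.numeric(raw$xyz)
  if (length(xyz) >= 3L * nrow(atoms)) {
    m <- matrix(xyz[seq_len(3L * nrow(atoms))], ncol = 3, byrow = TRUE)
    atoms$x <- m[, 1]; atoms$y <- m[, 2]; atoms$z <- m[, 3]
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms$o[is.na(atoms$o)] <- 1
  atoms <- .resolve_altloc(atoms)
  .new_structure(atoms[, intersect(.atom_cols, names(atoms)), drop = FALSE],
                 source = path, model = as.integer(model))
}

# keep, per (chain, resno, insert, atom name), the highest-occupancy altloc
# (ties: first occurrence in file order)
.resolve_altloc <- function(atoms) {
  alt <- atoms$alt
  if (is.null(alt) || all(is.na(alt) | alt %in% c("", " "))) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  ord <- order(key, -atoms$o, seq_len(nrow(atoms)), method = "radix")
  keep <- ord[!duplicated(key[ord])]
  atoms[sort(keep), , drop = FALSE]
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)")
  if (!is.na(x$source)) cat(" [", x$source, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Apply biological-assembly transforms to a structure
#'
#' Expands deposited coordinates into an assembly by applying each rigid
#' transform to a fresh copy of the structure. Chain identifiers of copies
#' beyond the first are suffixed with the copy index so that every chain of
#' the assembly is unique; the first copy of an exact identity transform
#' preserves coordinates bit-exactly.
#'
#' If suffixing collides with a pre-existing chain id (e.g. expanding an
#' already-expanded assembly), every copy including the first is suffixed
#' instead, keeping the labelling deterministic and unique.
#'
#' @param structure a `StructureModel`.
#' @param transforms list of transforms, each a list with `R` (3x3 rotation,
#'   orthonormal within 1e-6) and `t` (length-3 translation, Angstrom).
#' @return a `StructureModel` with one copy per transform.
#' @export
apply_assembly <- function(structure, transforms) {
  stopifnot(inherits(structure, "StructureModel"), length(transforms) >= 1L)
  chains0 <- unique(structure$atoms$chain)
  suffix_all <- length(transforms) > 1L &&
    any(paste0(rep(chains0, length(transforms) - 1L),
               "_", rep(seq_along(transforms)[-1L], each = length(chains0)))
        %in% chains0)
  copies <- vector("list", length(transforms))
  for (k in seq_along(transforms)) {
    tr <- transforms[[k]]
    R <- as.matrix(tr$R); tvec <- as.numeric(tr$t)
    if (!all(dim(R) == c(3L, 3L)) || length(tvec) != 3L)
      stop("transform ", k, ": expected 3x3 rotation and length-3 translation")
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      stop("transform ", k, ": rotation is not orthonormal within 1e-6")
    atoms <- structure$atoms
    is_identity <- identical(unname(R), diag(3)) && all(tvec == 0)
    if (!is_identity) {
      xyz <- cbind(atoms$x, atoms$y, atoms$z) %*% t(R)
      atoms$x <- xyz[, 1] + tvec[1]
      atoms$y <- xyz[, 2] + tvec[2]
      atoms$z <- xyz[, 3] + tvec[3]
    }
    if (k > 1L || suffix_all) atoms$chain <- paste0(atoms$chain, "_", k)
    copies[[k]] <- atoms
  }
  .new_structure(do.call(rbind, copies), source = structure$source,
                 model = structure$model)
}

#' Parse BIOMT assembly transforms from a PDB file
#'
#' Reads `REMARK 350   BIOMT` records into the transform list accepted by
#' [apply_assembly()].
#'
#' @param path PDB file path.
#' @return list of transforms (`R`, `t`), or an empty list if none present.
#' @export
read_biomt <- function(path) {
  lines <- grep("^REMARK 350   BIOMT", readLines(path), value = TRUE)
  if (length(lines) == 0L) return(list())
  row_no <- as.integer(substr(lines, 19, 19))
  ids <- as.integer(substr(lines, 20, 23))
  vals <- lapply(lines, function(l)
    as.numeric(strsplit(trimws(substr(l, 24, nchar(l))), "\\s+")[[1]]))
  out <- list()
  for (id in unique(ids)) {
    rows <- which(ids == id)
    rows <- rows[order(row_no[rows])]
    if (length(rows) != 3L) stop("malformed BIOMT block ", id, " in ", path)
    m <- do.call(rbind, vals[rows])
    out[[length(out) + 1L]] <- list(R = m[, 1:3, drop = FALSE], t = m[, 4])
  }
  out
}

.new_nodes <- function(df, scope = "all") {
  rownames(df) <- NULL
  structure(df, scope = scope, class = c("NodeModel", "data.frame"))
}

#' Extract the coarse-grained node model
#'
#' One node per residue possessing a C-alpha atom, in file order per chain;
#' after each chain's C-alpha nodes, four pseudo-nodes (CHA, CHB, CHC, CHD)
#' per complete heme group of that chain. Residues of polymer chains lacking
#' a C-alpha and hemes missing any of the four methine carbons are skipped
#' with a warning.
#'
#' @param structure a `StructureModel`.
#' @param scope `"all"` or a character vector of chain ids.
#' @param include_heme include heme pseudo-nodes? (default `TRUE`)
#' @param heme_residues residue names treated as heme.
#' @return a `NodeModel`: data frame (chain, resno, insert, resid, kind,
#'   x, y, z) with a `scope` attribute; `kind` is `"CA"` or one of
#'   `"CHA"`, `"CHB"`, `"CHC"`, `"CHD"`.
#' @export
extract_nodes <- function(structure, scope = "all", include_heme = TRUE,
                          heme_residues = HEME_RESIDUES) {
  stopifnot(inherits(structure, "StructureModel"))
  atoms <- structure$atoms
  chains <- unique(atoms$chain)
  if (!identical(scope, "all")) {
    missing <- setdiff(scope, chains)
    if (length(missing))
      stop("scope chain(s) not present: ", paste(missing, collapse = ", "))
    chains <- chains[chains %in% scope]
  }
  ch_atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  out <- vector("list", length(chains))
  for (ci in seq_along(chains)) {
    a <- ch_atoms[ch_atoms$chain == chains[ci], , drop = FALSE]
    is_heme <- a$resid %in% heme_residues
    poly <- a[!is_heme, , drop = FALSE]
    rkey <- paste(poly$resno, poly$insert, sep = "\r")
    res_order <- unique(rkey)
    ca <- poly[poly$elety == "CA", , drop = FALSE]
    ca <- ca[match(intersect(res_order, paste(ca$resno, ca$insert, sep = "\r")),
                   paste(ca$resno, ca$insert, sep = "\r")), , drop = FALSE]
    n_skip <- length(res_order) - nrow(ca)
    if (n_skip > 0L)
      warning(n_skip, " residue(s) without a C-alpha skipped in chain ",
              chains[ci], call. = FALSE)
    parts <- list()
    if (nrow(ca) > 0L)
      parts$ca <- data.frame(chain = ca$chain, resno = ca$resno,
                             insert = ca$insert, resid = ca$resid,
                             kind = "CA", x = ca$x, y = ca$y, z = ca$z,
                             stringsAsFactors = FALSE)
    if (include_heme && any(is_heme)) {
      hm <- a[is_heme, , drop = FALSE]
      for (hkey in unique(paste(hm$resno, hm$insert, sep = "\r"))) {
        h <- hm[paste(hm$resno, hm$insert, sep = "\r") == hkey, , drop = FALSE]
        idx <- match(c("CHA", "CHB", "CHC", "CHD"), h$elety)
        if (anyNA(idx)) {
          warning("heme ", h$resid[1], " ", h$resno[1], " in chain ",
                  chains[ci], " lacks a CH atom; skipped", call. = FALSE)
          next
        }
        h <- h[idx, , drop = FALSE]
        parts[[length(parts) + 1L]] <-
          data.frame(chain = h$chain, resno = h$resno, insert = h$insert,
                     resid = h$resid, kind = c("CHA", "CHB", "CHC", "CHD"),
                     x = h$x, y = h$y, z = h$z, stringsAsFactors = FALSE)
      }
    }
    out[[ci]] <- if (length(parts)) do.call(rbind, parts) else NULL
  }
  nodes <- do.call(rbind, out)
  if (is.null(nodes) || nrow(nodes) == 0L)
    stop("empty selection: no nodes in scope")
  dup <- duplicated(paste(nodes$chain, nodes$resno, nodes$insert, nodes$kind))
  if (any(dup)) stop("duplicate (chain, residue, kind) node")
  .new_nodes(nodes, scope = if (identical(scope, "all")) "all" else scope)
}

#' @export
print.NodeModel <- function(x, ...) {
  cat("NodeModel:", nrow(x), "nodes (",
      sum(x$kind == "CA"), "CA,", sum(x$kind != "CA"), "heme ),",
      length(unique(x$chain)), "chain(s); scope:",
      paste(attr(x, "scope"), collapse = ","), "\n")
  invisible(x)
}

#' Node coordinates as an N x 3 matrix
#' @param nodes a `NodeModel`.
#' @return numeric matrix with one row per node (Angstrom).
#' @export
node_xyz <- function(nodes) {
  cbind(x = nodes$x, y = nodes$y, z = nodes$z)
}

#' Write a node table as TSV
#' @param nodes a `NodeModel`.
#' @param path output file.
#' @export
write_node_table <- function(nodes, path) {
  write.table(as.data.frame(nodes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a structure as a PDB file
#'
#' Intended for the CA-only (plus heme) synthetic fixtures; chain identifiers
#' longer than one character (e.g. assembly copies) are remapped to single
#' letters with a warning.
#'
#' @param structure a `StructureModel`.
#' @param path output file.
#' @export
write_structure <- function(structure, path) {
  atoms <- structure$atoms
  chains <- unique(atoms$chain)
  if (any(nchar(chains) > 1L)) {
    pool <- c(LETTERS, letters, 0:9)
    if (length(chains) > length(pool)) stop("too many chains for PDB output")
    warning("multi-character chain ids remapped to single letters for PDB",
            call. = FALSE)
    atoms$chain <- pool[match(atoms$chain, chains)]
  }
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(cbind(atoms$x, atoms$y, atoms$z))),
                   type = atoms$type, resno = atoms$resno, resid = atoms$resid,
                   eleno = seq_len(nrow(atoms)), elety = atoms$elety,
                   chain = atoms$chain, insert = atoms$insert,
                   o = atoms$o, b = atoms$b, elesy = atoms$elesy)
  invisible(path)
}
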