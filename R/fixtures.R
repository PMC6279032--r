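# Deterministic synthetic structure generator.
#
# Stands in for downloaded datasets: ideal helical C-alpha traces, compact
# anti-parallel helix bundles (a globular-fold surrogate), multimeric
# assemblies built from rigid copies, Gaussian coordinate perturbation and
# heme decoration. Every stochastic operation takes an explicit seed and
# restores the caller's RNG state.

.with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Ideal helical C-alpha trace
#'
#' Places `n_res` nodes on a regular helix with canonical alpha-helix
#' geometry: 1.5 Angstrom rise and 100 degrees twist per residue on a
#' 2.3 Angstrom radius, giving the familiar ~3.8 Angstrom consecutive
#' C-alpha distance.
#'
#' @param n_res number of residues (>= 1).
#' @param rise rise per residue, Angstrom.
#' @param twist twist per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @param chain chain id.
#' @param resno_start first residue number.
#' @return a `NodeModel` of CA nodes (residue type ALA).
#' @export
make_helix <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                       chain = "A", resno_start = 1L) {
  stopifnot(n_res >= 1L)
  i <- seq_len(n_res) - 1L
  th <- i * twist * pi / 180
  .new_nodes(data.frame(
    chain = chain, resno = resno_start + i, insert = "", resid = "ALA",
    kind = "CA",
    x = radius * cos(th), y = radius * sin(th), z = i * rise,
    stringsAsFactors = FALSE))
}

.nodes_to_structure <- function(nodes, source = "synthetic") {
  atoms <- data.frame(
    type = ifelse(nodes$kind == "CA", "ATOM", "HETATM"),
    eleno = seq_len(nrow(nodes)),
    elety = ifelse(nodes$kind == "CA", "CA", nodes$kind),
    alt = "", resid = nodes$resid, chain = nodes$chain, resno = nodes$resno,
    insert = nodes$insert, x = nodes$x, y = nodes$y, z = nodes$z,
    o = 1, b = 0, elesy = "C", stringsAsFactors = FALSE)
  .new_structure(atoms, source = source)
}

#' Anti-parallel helix bundle
#'
#' Arranges `n_helices` ideal helices anti-parallel on a circle of radius
#' `packing_radius`, numbered consecutively as one chain. The default
#' packing keeps the 15 Angstrom ANM contact network connected, which is
#' asserted before returning.
#'
#' @param n_helices number of helices (>= 1).
#' @param helix_length residues per helix.
#' @param packing_radius distance of each helix axis from the bundle axis,
#'   Angstrom.
#' @param chain chain id.
#' @param cutoff connectivity-check cutoff, Angstrom.
#' @return a `StructureModel` (CA-only atoms, one chain).
#' @export
make_bundle <- function(n_helices, helix_length = 12L, packing_radius = 6,
                        chain = "A", cutoff = 15) {
  stopifnot(n_helices >= 1L, helix_length >= 1L)
  parts <- vector("list", n_helices)
  for (h in seq_len(n_helices)) {
    hel <- make_helix(helix_length, chain = chain,
                      resno_start = (h - 1L) * helix_length + 1L)
    xyz <- node_xyz(hel)
    if (h %% 2L == 0L) xyz[, 3] <- max(xyz[, 3]) - xyz[, 3]  # anti-parallel
    if (n_helices > 1L) {
      phi <- 2 * pi * (h - 1L) / n_helices
      xyz[, 1] <- xyz[, 1] + packing_radius * cos(phi)
      xyz[, 2] <- xyz[, 2] + packing_radius * sin(phi)
    }
    hel$x <- xyz[, 1]; hel$y <- xyz[, 2]; hel$z <- xyz[, 3]
    parts[[h]] <- as.data.frame(hel)
  }
  nodes <- .new_nodes(do.call(rbind, parts))
  if (max(check_connectivity(nodes, cutoff = cutoff)) > 1L)
    stop("bundle packing too sparse: contact network disconnected at ",
         cutoff, " Angstrom")
  .nodes_to_structure(nodes)
}

#' Multimeric assembly from rigid copies
#'
#' Places `copies` rigid copies of a unit side by side along x at the given
#' centre-to-centre spacing, disambiguating chain ids per copy (via
#' [apply_assembly()]).
#'
#' @param unit a `StructureModel`.
#' @param copies number of copies (>= 2).
#' @param spacing centre-to-centre translation between consecutive copies,
#'   Angstrom.
#' @return a `StructureModel`.
#' @export
make_multimer <- function(unit, copies = 2L, spacing = 11) {
  stopifnot(inherits(unit, "StructureModel"), copies >= 2L)
  transforms <- lapply(seq_len(copies) - 1L, function(k)
    list(R = diag(3), t = c(k * spacing, 0, 0)))
  apply_assembly(unit, transforms)
}

#' Gaussian coordinate perturbation
#'
#' Adds independent N(0, sigma^2) displacement to every coordinate of every
#' atom (or node), seeded and RNG-state preserving.
#'
#' @param x a `StructureModel` or `NodeModel`.
#' @param sigma per-axis standard deviation, Angstrom (>= 0).
#' @param seed integer seed; fully determines the output.
#' @return object of the same class with perturbed coordinates.
#' @export
perturb <- function(x, sigma, seed) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(x)
  if (inherits(x, "StructureModel")) {
    n <- nrow(x$atoms)
    d <- .with_seed(seed, matrix(rnorm(3L * n, sd = sigma), n, 3L))
    x$atoms$x <- x$atoms$x + d[, 1]
    x$atoms$y <- x$atoms$y + d[, 2]
    x$atoms$z <- x$atoms$z + d[, 3]
  } else if (inherits(x, "NodeModel")) {
    n <- nrow(x)
    d <- .with_seed(seed, matrix(rnorm(3L * n, sd = sigma), n, 3L))
    x$x <- x$x + d[, 1]; x$y <- x$y + d[, 2]; x$z <- x$z + d[, 3]
  } else stop("perturb expects a StructureModel or NodeModel")
  x
}

#' Add a heme group to a chain
#'
#' Appends one HEM heteroresidue whose four methine carbons (CHA, CHB, CHC,
#' CHD) form a planar square of the approximate porphyrin methine span,
#' centred near the chain's centroid so the ANM network stays connected.
#'
#' @param structure a `StructureModel`.
#' @param chain chain id to decorate.
#' @param half_span half the CHA-CHC diagonal, Angstrom (default 3.4).
#' @return a `StructureModel` with four extra HETATM records.
#' @export
add_heme <- function(structure, chain = "A", half_span = 3.4) {
  stopifnot(inherits(structure, "StructureModel"))
  a <- structure$atoms
  sel <- a$chain == chain
  if (!any(sel)) stop("chain not present: ", chain)
  ctr <- c(mean(a$x[sel]), mean(a$y[sel]), mean(a$z[sel]))
  offs <- rbind(c(half_span, 0, 0), c(0, half_span, 0),
                c(-half_span, 0, 0), c(0, -half_span, 0))
  heme <- data.frame(
    type = "HETATM", eleno = max(a$eleno) + 1:4,
    elety = c("CHA", "CHB", "CHC", "CHD"), alt = "", resid = "HEM",
    chain = chain, resno = max(a$resno[sel]) + 1L, insert = "",
    x = ctr[1] + offs[, 1], y = ctr[2] + offs[, 2], z = ctr[3] + offs[, 3],
    o = 1, b = 0, elesy = "C", stringsAsFactors = FALSE)
  .new_structure(rbind(a, heme), source = structure$source,
                 model = structure$model)
}
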