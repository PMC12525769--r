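# standard atomic masses from bio3d's periodic-table dataset
element_masses <- local({
  cache <- NULL
  function(symbols) {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("elements", package = "bio3d", envir = e)
      cache <<- e$elements
    }
    m <- cache$mass[match(toupper(trimws(symbols)), toupper(cache$symb))]
    if (anyNA(m))
      stop_pbsq("unknown element symbol(s): ",
                paste(unique(symbols[is.na(m)]), collapse = ", "))
    m
  }
})

#' Default ligand-code to bilin-type map
#'
#' Covers the common wwPDB chemical-component codes for bilins;
#' depositions vary, so the map is user-extensible in
#' [harvest_chromophores()].
#' @return Named character vector (residue code -> bilin type).
#' @export
default_ligand_map <- function()
  c(CYC = "PCB", PUB = "PUB", PEB = "PEB")

#' Extract bilin chromophore sites from a coordinate file
#'
#' Reads a PDB or mmCIF file (via \pkg{bio3d}), selects the residues whose
#' names appear in `ligand_map`, drops hydrogens, and returns one
#' chromophore site per matching residue with its mass-weighted centre.
#'
#' @param structure_file Path to a `.pdb` or `.cif` file.
#' @param ligand_map Named character vector mapping residue names to bilin
#'   types (`PCB`, `PEB`, `PUB`, ...). Default [default_ligand_map()].
#' @param group_map Optional named character vector mapping chain ids to
#'   group labels (e.g. core cylinder or rod ids); unmapped chains get
#'   group `"unassigned"`.
#' @return List of `chromophore_site` objects; empty (with a warning) when
#'   nothing matches.
#' @export
harvest_chromophores <- function(structure_file,
                                 ligand_map = default_ligand_map(),
                                 group_map = NULL) {
  if (!length(ligand_map) || is.null(names(ligand_map)))
    stop_pbsq("ligand_map must be a non-empty named vector")
  if (!file.exists(structure_file)) stop_pbsq("no such file: ", structure_file)
  ext <- tolower(tools::file_ext(structure_file))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(structure_file, verbose = FALSE)
    else bio3d::read.pdb(structure_file, verbose = FALSE),
    error = function(e) stop_pbsq("cannot parse coordinate file '",
                                  structure_file, "': ", conditionMessage(e)))
  at <- pdb$atom
  sel <- at$resid %in% names(ligand_map)
  if (!any(sel)) {
    warning("no residues matching ligand_map found in ", structure_file)
    return(list())
  }
  at <- at[sel, , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(at$elety), 1, 1)
  keep <- toupper(trimws(elem)) != "H"
  at <- at[keep, , drop = FALSE]
  elem <- trimws(elem[keep])
  key <- paste(at$chain, at$resid, at$resno, sep = "/")
  sites <- lapply(split(seq_len(nrow(at)), key), function(idx) {
    a <- at[idx, , drop = FALSE]
    el <- elem[idx]
    mass <- element_masses(el)
    chain <- a$chain[1]
    grp <- if (!is.null(group_map) && chain %in% names(group_map))
      unname(group_map[[chain]]) else "unassigned"
    chromophore_site(
      site_id = paste0(chain, "/", a$resid[1], a$resno[1]),
      chain_id = chain, residue_name = a$resid[1],
      residue_number = a$resno[1],
      atoms = data.frame(element = el, x = a$x, y = a$y, z = a$z,
                         mass = mass, stringsAsFactors = FALSE),
      bilin_type = unname(ligand_map[[a$resid[1]]]),
      group = grp)
  })
  unname(sites[order(vapply(sites, `[[`, "", "site_id"))])
}

#' Construct a chromophore site
#'
#' @param site_id Unique site label.
#' @param chain_id,residue_name,residue_number Residue identity.
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` (in
#'   angstrom) and `mass` (Da).
#' @param bilin_type One of `PCB`, `PEB`, `PUB`, `unknown`.
#' @param group Group label (core cylinder, rod, ...).
#' @return Object of class `chromophore_site` with a populated
#'   `mass_center`.
#' @export
chromophore_site <- function(site_id, chain_id = "A", residue_name = "BLN",
                             residue_number = 1L, atoms, bilin_type = "unknown",
                             group = "unassigned") {
  atoms <- as.data.frame(atoms)
  stopifnot(nrow(atoms) >= 1, all(c("x", "y", "z", "mass") %in% names(atoms)))
  structure(list(site_id = site_id, chain_id = chain_id,
                 residue_name = residue_name,
                 residue_number = as.integer(residue_number),
                 atoms = atoms, bilin_type = bilin_type, group = group,
                 mass_center = mass_center_xyz(atoms)),
            class = "chromophore_site")
}

mass_center_xyz <- function(atoms) {
  m <- atoms$mass
  tot <- sum(m)
  if (!is.finite(tot) || tot <= 0) stop_pbsq("total atomic mass is zero")
  c(x = sum(m * atoms$x), y = sum(m * atoms$y), z = sum(m * atoms$z)) / tot
}

#' Mass-weighted centre of a chromophore site
#'
#' @param site A `chromophore_site`.
#' @return Length-3 numeric vector (x, y, z) in angstrom.
#' @export
mass_center <- function(site) {
  stopifnot(inherits(site, "chromophore_site"))
  mass_center_xyz(site$atoms)
}

site_centers <- function(sites) {
  stopifnot(length(sites) >= 1)
  t(vapply(sites, function(s) s$mass_center, numeric(3)))
}

#' Pairwise mass-center distance matrix
#'
#' @param sites List of `chromophore_site`s.
#' @return Symmetric matrix of Euclidean distances in angstrom with site
#'   ids as dimnames and a zero diagonal.
#' @export
pairwise_distances <- function(sites) {
  ctr <- site_centers(sites)
  D <- as.matrix(stats::dist(ctr))
  ids <- vapply(sites, `[[`, "", "site_id")
  dimnames(D) <- list(ids, ids)
  D
}

#' Build an energy-transfer adjacency graph at a distance cutoff
#'
#' Edges connect chromophore pairs whose mass-center distance is at most
#' `cutoff_A` (boundary inclusive), the geometric criterion used to chart
#' plausible excitation-energy-transfer pathways (default 35 angstrom).
#'
#' @param sites List of `chromophore_site`s.
#' @param cutoff_A Distance cutoff in angstrom (> 0 allowed; default 35).
#' @return Object of class `eet_graph`: `nodes`, `groups`, `distances`,
#'   `cutoff_A` and an `edges` data frame (`site_a`, `site_b`, `group_a`,
#'   `group_b`, `distance_A`).
#' @export
build_eet_graph <- function(sites, cutoff_A = 35) {
  stopifnot(cutoff_A >= 0)
  D <- pairwise_distances(sites)
  ids <- rownames(D)
  grp <- vapply(sites, `[[`, "", "group")
  idx <- which(upper.tri(D) & D <= cutoff_A, arr.ind = TRUE)
  edges <- data.frame(site_a = ids[idx[, 1]], site_b = ids[idx[, 2]],
                      group_a = grp[idx[, 1]], group_b = grp[idx[, 2]],
                      distance_A = D[idx], stringsAsFactors = FALSE)
    edges <- edges[order(edges$distance_A, edges$site_a, edges$site_b), ,
                   drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = ids, groups = stats::setNames(grp, ids),
                 distances = D, cutoff_A = cutoff_A, edges = edges),
            class = "eet_graph")
}

#' @export
print.eet_graph <- function(x, ...) {
  cat("EET graph:", length(x$nodes), "chromophores,", nrow(x$edges),
      "edges at cutoff", x$cutoff_A, "angstrom\n")
  if (nrow(x$edges))
    cat("  shortest edge:", signif(min(x$edges$distance_A), 4), "angstrom (",
        x$edges$site_a[1], "-", x$edges$site_b[1], ")\n")
  invisible(x)
}

#' Minimal mass-center distance between two chromophore groups
#'
#' @param x An `eet_graph` or a list of `chromophore_site`s.
#' @param group_a,group_b Distinct group labels.
#' @return List with `distance_A`, `site_a`, `site_b`; ties broken by
#'   lexicographic site id.
#' @export
min_intergroup_distance <- function(x, group_a, group_b) {
  if (identical(group_a, group_b))
    stop_pbsq("group_a and group_b must differ (cross-group distances only)")
  if (inherits(x, "eet_graph")) {
    D <- x$distances; grp <- x$groups
  } else {
    D <- pairwise_distances(x)
    grp <- stats::setNames(vapply(x, `[[`, "", "group"), rownames(D))
  }
  ia <- which(grp == group_a); ib <- which(grp == group_b)
  if (!length(ia)) stop_pbsq("no sites in group '", group_a, "'")
  if (!length(ib)) stop_pbsq("no sites in group '", group_b, "'")
  sub <- D[ia, ib, drop = FALSE]
  best <- which(sub == min(sub), arr.ind = TRUE)
  pairs <- data.frame(a = rownames(sub)[best[, 1]], b = colnames(sub)[best[, 2]])
  pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
  list(distance_A = min(sub), site_a = pairs$a[1], site_b = pairs$b[1])
}

#' Bilin ring coplanarity geometry
#'
#' Open-chain tetrapyrroles have four rings (A-D). The B-C plane is fit by
#' total least squares (smallest eigenvector of the centred covariance of
#' the B and C ring atoms) and the A and D ring centroids are reported as
#' signed perpendicular displacements from that plane. The normal is
#' oriented so the A-ring displacement is nonnegative (ties: toward +z).
#'
#' @param site A `chromophore_site`.
#' @param ring_defs Named list with atom-name (element-name column
#'   `name` of `site$atoms`, or row indices) subsets `A`, `B`, `C`, `D`;
#'   each of `B`, `C` needs >= 3 non-collinear atoms.
#' @return Object of class `ring_geometry` with `normal` (unit), `offset`
#'   (plane constant, `dot(normal, p) = offset`), and `out_of_plane`
#'   (named displacements of A and D centroids, angstrom).
#' @export
coplanarity <- function(site, ring_defs) {
  stopifnot(inherits(site, "chromophore_site"),
            all(c("A", "B", "C", "D") %in% names(ring_defs)))
  xyz <- as.matrix(site$atoms[, c("x", "y", "z")])
  pick <- function(ring) {
    idx <- ring_defs[[ring]]
    if (is.character(idx)) {
      if (!"name" %in% names(site$atoms))
        stop_pbsq("atom names requested but site$atoms has no 'name' column")
      idx <- which(site$atoms$name %in% idx)
    }
    if (!length(idx)) stop_pbsq("ring ", ring, " selects no atoms")
    xyz[idx, , drop = FALSE]
  }
  for (r in c("B", "C"))
    if (nrow(pick(r)) < 3)
      stop_pbsq("ring ", r, " needs at least 3 atoms for the plane fit")
  bc <- rbind(pick("B"), pick("C"))
  ctr <- colMeans(bc)
  cen <- sweep(bc, 2, ctr)
  eg <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  if (eg$values[2] < 1e-10 * max(eg$values[1], 1e-300))
    stop_pbsq("B-C ring atoms are collinear or degenerate; cannot fit a plane")
  nrm <- eg$vectors[, 3]
  disp <- function(p) sum((colMeans(p) - ctr) * nrm)
  dA <- disp(pick("A")); dD <- disp(pick("D"))
  flip <- if (abs(dA) > 1e-12) dA < 0 else nrm[3] < 0
  if (flip) { nrm <- -nrm; dA <- -dA; dD <- -dD }
  structure(list(normal = nrm, offset = sum(nrm * ctr),
                 out_of_plane = c(A = dA, D = dD),
                 plane_rms = sqrt(eg$values[3])),
            class = "ring_geometry")
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf("B-C plane fit (rms %.3g angstrom); out-of-plane: A %+.3f, D %+.3f angstrom\n",
              x$plane_rms, x$out_of_plane["A"], x$out_of_plane["D"]))
  invisible(x)
}

#' Write the edge list of an EET graph as CSV
#'
#' @param graph An `eet_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eet_edges <- function(graph, path) {
  stopifnot(inherits(graph, "eet_graph"))
  utils::write.csv(graph$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
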