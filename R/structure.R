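# Minimal PDB handling, solvent-accessible surface detection, and
# epitope-sized 3D surface patch enumeration.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M", SEC = "U", PYL = "O", ASX = "B", GLX = "Z",
            UNK = "X")
AA1TO3 <- setNames(names(AA3TO1)[1:20], AA3TO1[1:20])

# element-keyed van der Waals radii (Angstrom); unknown elements get carbon's
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Construct a Structure object
#'
#' @param id Structure id.
#' @param atoms Data frame with columns `residue_index` (integer, chain
#'   order), `resname` (3-letter), `atom_name`, `element`, `x`, `y`, `z`
#'   (Angstrom). A `radius` column is added from element-keyed van der Waals
#'   radii if absent.
#' @return Object of class `Structure` with fields `id`, `atoms`,
#'   `residue_index` (ordered unique indices), `resname` (per residue) and
#'   `sequence` (one-letter, length = residue count).
#' @export
structure_object <- function(id, atoms) {
  assert_string(id)
  need <- c("residue_index", "resname", "atom_name", "element", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (!nrow(atoms)) stop("structure has no atoms", call. = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("every atom must have finite coordinates", call. = FALSE)
  }
  if (is.null(atoms$radius)) atoms$radius <- vdw_radius(atoms$element)
  ridx <- unique(atoms$residue_index)
  resname <- atoms$resname[match(ridx, atoms$residue_index)]
  seq1 <- AA3TO1[resname]
  seq1[is.na(seq1)] <- "X"
  structure(list(id = id, atoms = atoms, residue_index = ridx,
                 resname = resname,
                 sequence = paste(seq1, collapse = "")),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure '%s': %d residue(s), %d atom(s)\n",
              x$id, length(x$residue_index), nrow(x$atoms)))
  invisible(x)
}

#' Read a protein chain from a PDB file
#'
#' Parses ATOM records of the first model of a single chain (default: the
#' first chain encountered). Heteroatoms, waters, hydrogens and alternate
#' locations other than blank/"A" are excluded; residues without any usable
#' coordinates are skipped with a warning. Van der Waals radii are assigned
#' by element (C 1.70, N 1.55, O 1.52, S 1.80 Angstrom; others 1.70).
#'
#' @param path PDB file path.
#' @param chain Chain identifier, or `NULL` for the first chain.
#' @param id Structure id; defaults to the file name without extension.
#' @return A [structure_object()].
#' @export
read_structure <- function(path, chain = NULL, id = NULL) {
  assert_string(path)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]  # first model
  at <- lines[startsWith(lines, "ATOM  ")]
  if (!length(at)) stop(sprintf("no protein ATOM records in %s", path), call. = FALSE)
  fld <- function(a, b) trimws(substr(at, a, b))
  altloc <- fld(17, 17)
  keep <- altloc %in% c("", "A")
  at <- at[keep]
  fld <- function(a, b) trimws(substr(at, a, b))
  chains <- fld(22, 22)
  if (is.null(chain)) chain <- chains[1L]
  sel <- chains == chain
  if (!any(sel)) stop(sprintf("chain '%s' not found in %s", chain, path),
                      call. = FALSE)
  at <- at[sel]
  fld <- function(a, b) trimws(substr(at, a, b))
  resname <- fld(18, 20)
  ok <- resname %in% names(AA3TO1)
  at <- at[ok]; resname <- resname[ok]
  if (!length(at)) stop(sprintf("no protein residues in %s", path), call. = FALSE)
  fld <- function(a, b) trimws(substr(at, a, b))
  element <- toupper(fld(77, 78))
  atom_name <- fld(13, 16)
  no_el <- element == ""
  element[no_el] <- substr(gsub("[0-9]", "", atom_name[no_el]), 1L, 1L)
  xyz <- cbind(as.numeric(fld(31, 38)), as.numeric(fld(39, 46)),
               as.numeric(fld(47, 54)))
  resseq <- as.integer(fld(23, 26))
  hyd <- element == "H"
  bad <- !stats::complete.cases(xyz) | is.na(resseq)
  if (any(bad)) {
    miss <- unique(resseq[bad])
    warning(sprintf("skipping %d residue(s) with missing coordinates", length(miss)))
    drop_res <- resseq %in% miss
  } else drop_res <- FALSE
  keep <- !hyd & !bad & !drop_res
  atoms <- data.frame(residue_index = resseq[keep], resname = resname[keep],
                      atom_name = atom_name[keep], element = element[keep],
                      x = xyz[keep, 1L], y = xyz[keep, 2L], z = xyz[keep, 3L],
                      stringsAsFactors = FALSE)
  if (!nrow(atoms)) stop(sprintf("no usable protein residues in %s", path),
                         call. = FALSE)
  structure_object(id, atoms)
}

#' Write a Structure as a PDB file
#'
#' @param struct A [structure_object()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(struct, path) {
  stopifnot(inherits(struct, "Structure"))
  a <- struct$atoms
  rec <- sprintf(
    "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$atom_name) < 4L, paste0(" ", a$atom_name), a$atom_name),
    a$resname, a$residue_index, a$x, a$y, a$z, a$element)
  writeLines(c(rec, "END"), path)
  invisible(path)
}

# deterministic spiral (Fibonacci) point set on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Identify solvent-accessible surface residues
#'
#' Shrake-Rupley style: `n_points` are sampled deterministically on each
#' atom's probe-expanded sphere (radius `r_vdw + probe`) and points falling
#' inside any other atom's expanded sphere are discarded; the surviving
#' points form the solvent-accessible surface (SAS) point cloud. A residue's
#' surface distance is the minimum over its atoms of (distance from the atom
#' center to the nearest SAS point minus the atom's van der Waals radius),
#' so a fully exposed atom sits exactly `probe` Angstrom from the surface.
#' Residues closer than `cutoff` are flagged as surface.
#'
#' @param struct A [structure_object()].
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param cutoff Surface distance cutoff in Angstrom (default 2.55).
#' @param n_points Sphere sampling density per atom (>= 92; default 256).
#' @return Object of class `SurfaceModel`: data frame with one row per
#'   residue (`residue_index`, `distance`, `surface`) and attributes
#'   `probe`, `cutoff`, `n_points`.
#' @export
surface_residues <- function(struct, probe = 1.4, cutoff = 2.55,
                             n_points = 256L) {
  stopifnot(inherits(struct, "Structure"))
  assert_number(probe, lower = 0)
  assert_number(cutoff, lower = 0)
  n_points <- as.integer(assert_number(n_points, lower = 92))
  a <- struct$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- a$radius + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  # neighbor lists: only atoms with overlapping expanded spheres can occlude
  d2 <- as.matrix(stats::dist(xyz))^2
  lim <- outer(R, R, "+")^2
  exposed_pts <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sweep(pts * R[i], 2L, xyz[i, ], "+")
    nb <- which(d2[i, ] < lim[i, ] & seq_len(n) != i)
    keep <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1L] - xyz[j, 1L])^2 + (p[, 2L] - xyz[j, 2L])^2 +
        (p[, 3L] - xyz[j, 3L])^2
      keep <- keep & dj2 >= R[j]^2 - 1e-9
      if (!any(keep)) break
    }
    exposed_pts[[i]] <- p[keep, , drop = FALSE]
  }
  has_own <- vapply(exposed_pts, nrow, integer(1L)) > 0L
  cloud <- do.call(rbind, exposed_pts)
  # atom surface distance: probe if the atom has exposed points of its own,
  # else distance to the nearest SAS point anywhere minus its vdW radius
  atom_dist <- rep(NA_real_, n)
  atom_dist[has_own] <- probe
  buried <- which(!has_own)
  if (length(buried)) {
    if (is.null(cloud) || !nrow(cloud)) {
      atom_dist[buried] <- Inf
    } else {
      for (i in buried) {
        dmin <- sqrt(min((cloud[, 1L] - xyz[i, 1L])^2 +
                           (cloud[, 2L] - xyz[i, 2L])^2 +
                           (cloud[, 3L] - xyz[i, 3L])^2))
        atom_dist[i] <- dmin - a$radius[i]
      }
    }
  }
  res_dist <- vapply(split(atom_dist, a$residue_index), min, numeric(1L))
  ord <- match(struct$residue_index, as.integer(names(res_dist)))
  out <- data.frame(residue_index = struct$residue_index,
                    distance = unname(res_dist)[ord],
                    stringsAsFactors = FALSE)
  out$surface <- out$distance < cutoff
  attr(out, "probe") <- probe
  attr(out, "cutoff") <- cutoff
  attr(out, "n_points") <- n_points
  class(out) <- c("SurfaceModel", "data.frame")
  out
}

# minimum heavy-atom distance matrix between residues (surface subset)
residue_min_dist <- function(struct, residues) {
  a <- struct$atoms[struct$atoms$residue_index %in% residues, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  grp <- factor(a$residue_index, levels = residues)
  # aggregate atom-pair distances to residue-pair minima
  nr <- length(residues)
  out <- matrix(Inf, nr, nr, dimnames = list(residues, residues))
  gi <- as.integer(grp)
  for (i in seq_len(nr)) {
    rows <- which(gi == i)
    sub <- d[rows, , drop = FALSE]
    mins <- vapply(seq_len(nr), function(j) {
      min(sub[, gi == j, drop = FALSE])
    }, numeric(1L))
    out[i, ] <- mins
  }
  out
}

#' Enumerate epitope-sized 3D surface patches
#'
#' Every surface residue is taken as the hypothetical center of a
#' conformational epitope; its patch contains all surface residues whose
#' minimum heavy-atom distance to the center residue is at most `radius`
#' (the center belongs to its own patch). Patches smaller than `min_size`
#' residues are dropped.
#'
#' @param struct A [structure_object()].
#' @param surface A [surface_residues()] model for `struct`.
#' @param radius Patch radius in Angstrom (default 12, antibody
#'   binding-interface scale).
#' @param min_size Minimum patch size in residues (default 13).
#' @return Object of class `EpitopeTable`: list with `structure_id`,
#'   `epitopes` (named list: center residue index -> sorted member residue
#'   indices), `radius`, `min_size`.
#' @export
build_epitope_table <- function(struct, surface, radius = 12, min_size = 13L) {
  stopifnot(inherits(struct, "Structure"), inherits(surface, "SurfaceModel"))
  assert_number(radius, lower = 1e-9)
  min_size <- as.integer(assert_number(min_size, lower = 1))
  surf_res <- surface$residue_index[surface$surface]
  epitopes <- list()
  if (length(surf_res)) {
    dmat <- residue_min_dist(struct, surf_res)
    for (i in seq_along(surf_res)) {
      members <- sort(surf_res[dmat[i, ] <= radius])
      if (length(members) >= min_size) {
        epitopes[[as.character(surf_res[i])]] <- members
      }
    }
  }
  structure(list(structure_id = struct$id, epitopes = epitopes,
                 radius = radius, min_size = min_size),
            class = "EpitopeTable")
}

#' @export
print.EpitopeTable <- function(x, ...) {
  cat(sprintf("EpitopeTable '%s': %d epitope(s), radius %.1f A, min size %d\n",
              x$structure_id, length(x$epitopes), x$radius, x$min_size))
  invisible(x)
}

#' Serialize / restore EpitopeTables as JSON
#'
#' `tables` is a list of [build_epitope_table()] results; the JSON maps
#' structure id to its epitope definitions.
#'
#' @param tables List of `EpitopeTable` objects.
#' @param path JSON path.
#' @return `path` invisibly (write); named list of `EpitopeTable` (read).
#' @export
write_epitope_tables <- function(tables, path) {
  if (inherits(tables, "EpitopeTable")) tables <- list(tables)
  out <- lapply(tables, function(t) {
    list(structure_id = t$structure_id, radius = t$radius,
         min_size = t$min_size, epitopes = t$epitopes)
  })
  names(out) <- vapply(tables, `[[`, character(1L), "structure_id")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epitope_tables
#' @export
read_epitope_tables <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(t) {
    eps <- lapply(t$epitopes, function(m) sort(as.integer(m)))
    structure(list(structure_id = t$structure_id, epitopes = eps,
                   radius = t$radius, min_size = as.integer(t$min_size)),
              class = "EpitopeTable")
  })
}
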