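#' Structure model
#'
#' Container for an atomic model: unit cell, symmetry operators, an ordered
#' atom table and a mobile-atom mask.  Coordinates are Cartesian Angstrom
#' throughout; fractional coordinates appear only at the scattering
#' boundary.  Atoms sharing `(chain, resno, alt)` form one validation group.
#'
#' @param cell a [unit_cell()]
#' @param atoms data frame with columns `element`, `atomname`, `resname`,
#'   `chain`, `resno`, `alt` (conformer tag, "" if none), `x`, `y`, `z`
#'   (Angstrom), `occ` in \[0,1\], `b` (isotropic ADP, A^2, >= 0),
#'   `charge` (e) and `radius` (COSMO cavity radius, Angstrom)
#' @param ops a [symmetry_ops()] (default P1)
#' @param mobile logical vector, one entry per atom; frozen atoms never move
#'   during refinement
#' @return object of class `structure_model`
#' @export
structure_model <- function(cell, atoms, ops = symmetry_ops(),
                            mobile = rep(TRUE, nrow(atoms))) {
  req <- c("element", "atomname", "resname", "chain", "resno", "alt",
           "x", "y", "z", "occ", "b")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancies must lie in [0,1]")
  if (any(atoms$b < 0)) stop("B factors must be non-negative")
  if (length(mobile) != nrow(atoms))
    stop("mobile mask length must equal atom count")
  structure(list(cell = cell, ops = ops, atoms = atoms,
                 mobile = as.logical(mobile)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure model: %d atoms (%d mobile), %d symmetry op(s)\n",
              nrow(x$atoms), sum(x$mobile), n_ops(x$ops)))
  print(x$cell)
  invisible(x)
}

#' Number of atoms in a model
#' @param model a [structure_model()]
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Cartesian coordinates of a model as an n x 3 matrix
#' @param model a [structure_model()]
#' @export
coords <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

#' Replace coordinates of (a subset of) atoms
#' @param model a [structure_model()]
#' @param xyz n x 3 matrix of Cartesian coordinates
#' @param which indices of the atoms to update (default all)
#' @export
set_coords <- function(model, xyz, which = seq_len(n_atoms(model))) {
  xyz <- matrix(xyz, ncol = 3)
  model$atoms$x[which] <- xyz[, 1]
  model$atoms$y[which] <- xyz[, 2]
  model$atoms$z[which] <- xyz[, 3]
  model
}

.supported_elements <- function() {
  tab <- form_factor_table()
  rownames(tab)
}

#' Read a PDB-format model
#'
#' Parses ATOM/HETATM records (via bio3d), keeping alternate-location
#' conformers.  Partial charges and COSMO radii are not representable in
#' PDB; they default to 0 / NA unless a sidecar table is given (see
#' [read_charge_table()] and [apply_charge_table()]).
#'
#' @param path PDB file
#' @param cell optional [unit_cell()]; if absent, taken from the CRYST1
#'   record when present, else a 100 A cube
#' @param check_elements error on elements without scattering factors
#' @return a [structure_model()] with all atoms mobile
#' @export
read_model <- function(path, cell = NULL, check_elements = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("malformed PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(cell)) {
    cr <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
    if (length(cr) >= 1) {
      f <- suppressWarnings(as.numeric(c(
        substr(cr[1], 7, 15), substr(cr[1], 16, 24), substr(cr[1], 25, 33),
        substr(cr[1], 34, 40), substr(cr[1], 41, 47), substr(cr[1], 48, 54))))
      if (!any(is.na(f))) cell <- unit_cell(f[1], f[2], f[3], f[4], f[5], f[6])
    }
    if (is.null(cell)) cell <- unit_cell(100, 100, 100)
  }
  elem <- at$elesy
  guess <- toupper(substr(trimws(at$elety), 1, 1))
  elem <- ifelse(is.na(elem) | trimws(elem) == "", guess, trimws(elem))
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 10)))
  if (check_elements) {
    bad <- setdiff(unique(elem), .supported_elements())
    if (length(bad))
      stop("unknown element(s): ", paste(bad, collapse = ", "),
           "; supported: ", paste(.supported_elements(), collapse = " "))
  }
  atoms <- data.frame(
    element = elem,
    atomname = trimws(at$elety),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    alt = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    charge = 0, radius = NA_real_,
    stringsAsFactors = FALSE)
  structure_model(cell, atoms)
}

#' Write a model as PDB
#'
#' @param model a [structure_model()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_model <- function(model, path) {
  a <- model$atoms
  cr <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                model$cell$a, model$cell$b, model$cell$c,
                model$cell$alpha, model$cell$beta, model$cell$gamma)
  writeLines(cr, path)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(coords(model))),
                   type = rep("ATOM", nrow(a)),
                   eleno = seq_len(nrow(a)), elety = a$atomname,
                   resid = a$resname, chain = a$chain, resno = a$resno,
                   alt = ifelse(a$alt == "", NA, a$alt),
                   o = a$occ, b = a$b, elesy = a$element,
                   append = TRUE)
  invisible(path)
}

#' Sidecar charge/radius table
#'
#' PDB cannot carry partial charges or cavity radii, so they live in a
#' whitespace-separated sidecar file with columns
#' `resname atomname charge radius` (radius in Angstrom, `NA` allowed).
#'
#' @param path sidecar file
#' @return data frame with those four columns
#' @export
read_charge_table <- function(path) {
  tb <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("resname", "atomname", "charge", "radius"),
                          colClasses = c("character", "character", "numeric", "numeric"))
  tb
}

#' @rdname read_charge_table
#' @param model a [structure_model()]
#' @param table data frame from [read_charge_table()]
#' @return the model with `charge` and `radius` columns filled for matching
#'   `(resname, atomname)` pairs
#' @export
apply_charge_table <- function(model, table) {
  key <- paste(model$atoms$resname, model$atoms$atomname)
  tkey <- paste(table$resname, table$atomname)
  i <- match(key, tkey)
  hit <- !is.na(i)
  model$atoms$charge[hit] <- table$charge[i[hit]]
  model$atoms$radius[hit] <- table$radius[i[hit]]
  model
}

#' Region ("system 1") selection
#'
#' The subset of atoms whose energy is supplied by the region backend, plus
#' the bonds cut by the region boundary.  Each boundary bond is capped by a
#' hydrogen link atom placed on the inside-to-outside bond vector at
#' `scale * |bond|` from the inside atom (default 0.709, the standard
#' C-H / C-C length ratio, giving ~1.09 A for a 1.54 A C-C bond).
#'
#' @param indices atom indices of system 1 (unique, in range)
#' @param boundary_bonds two-column matrix `(inside, outside)` of atom
#'   indices, one row per cut bond; may have zero rows
#' @param link_scale scalar or per-bond vector of link-atom scale factors
#' @return object of class `region_selection`
#' @export
region_selection <- function(indices, boundary_bonds = matrix(0L, 0, 2),
                             link_scale = 0.709) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("region indices must be unique")
  boundary_bonds <- matrix(as.integer(boundary_bonds), ncol = 2)
  if (nrow(boundary_bonds)) {
    ins <- boundary_bonds[, 1] %in% indices
    out <- boundary_bonds[, 2] %in% indices
    if (!all(ins & !out))
      stop("each boundary bond must have exactly one endpoint inside the region")
  }
  ls <- rep_len(link_scale, max(1, nrow(boundary_bonds)))
  structure(list(indices = indices, boundary_bonds = boundary_bonds,
                 link_scale = ls),
            class = "region_selection")
}

#' Build the capped region coordinate set
#'
#' Returns the region atoms plus hydrogen link atoms capping each boundary
#' bond.  Link atoms carry zero charge, occupancy 1 and the hydrogen COSMO
#' radius; their positions are a linear function of the two parent atoms,
#' `x_link = x_in + scale * (x_out - x_in)`, which makes the placement
#' rotation- and translation-equivariant.
#'
#' @param model a [structure_model()]
#' @param region a [region_selection()]
#' @return list with `atoms` (atom table: region atoms then link atoms),
#'   `is_link` (logical), `parent` (for link atoms, the row index pair
#'   `(inside, outside)` in the model), `scale` (per link atom)
#' @export
place_link_atoms <- function(model, region) {
  a <- model$atoms[region$indices, , drop = FALSE]
  nb <- nrow(region$boundary_bonds)
  if (nb == 0) {
    return(list(atoms = a, is_link = rep(FALSE, nrow(a)),
                parent = matrix(0L, 0, 2), scale = numeric(0)))
  }
  xin <- coords(model)[region$boundary_bonds[, 1], , drop = FALSE]
  xout <- coords(model)[region$boundary_bonds[, 2], , drop = FALSE]
  dv <- xout - xin
  blen <- sqrt(rowSums(dv^2))
  if (any(blen < 0.5))
    stop("boundary bond shorter than 0.5 A (atoms ",
         paste(region$boundary_bonds[blen < 0.5, 1], collapse = ","), ")")
  s <- rep_len(region$link_scale, nb)
  xl <- xin + dv * s
  link <- data.frame(
    element = "H", atomname = "HL", resname = "LNK",
    chain = a$chain[1], resno = max(model$atoms$resno) + seq_len(nb),
    alt = "", x = xl[, 1], y = xl[, 2], z = xl[, 3],
    occ = 1, b = 0, charge = 0, radius = 1.3,
    stringsAsFactors = FALSE)
  list(atoms = rbind(a, link),
       is_link = c(rep(FALSE, nrow(a)), rep(TRUE, nb)),
       parent = region$boundary_bonds, scale = s)
}
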