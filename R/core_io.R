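# Domain containers and I/O for annotated structures and trajectories.
#
# A `ligdyn_topology` holds the per-atom table (names, residues, chemistry
# flags, vdW radii), the bond list and the ring definitions; a
# `ligdyn_trajectory` binds a topology to a frames x atoms x 3 coordinate
# array in Angstrom. Atom indices are 1-based throughout, and residue
# numbers are preserved exactly as authored in the input file (matching is
# always by resid + chain, never by ordinal position).

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

KNOWN_FLAGS <- c("donor", "acceptor", "hydrogen", "polar", "nonpolar_carbon",
                 "cation_group", "anion_group")

# Bondi van der Waals radii (Angstrom); fallback for unannotated atoms.
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
                 F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

#' Bondi van der Waals radius for an element
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom; elements absent from the
#'   Bondi table fall back to the carbon radius (1.70 Angstrom).
#' @export
bondi_radius <- function(element) {
  r <- BONDI_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Construct a topology
#'
#' @param atoms data.frame with columns `name`, `element`, `resid`,
#'   `resname`, `chain`; optional `vdw_radius`, `flags` (semicolon-separated
#'   flag list per atom), `ring_id`.
#' @param bonds two-column integer matrix of 1-based atom-index pairs.
#' @param rings named list mapping ring id to an ordered atom-index cycle
#'   (closed implicitly; each cycle must have >= 4 atoms).
#' @return object of class `ligdyn_topology`.
#' @export
topology <- function(atoms, bonds = NULL, rings = list()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  req <- c("name", "element", "resid", "resname", "chain")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- bondi_radius(atoms$element)
  if (any(!is.finite(atoms$vdw_radius)) || any(atoms$vdw_radius <= 0))
    stop("vdw_radius must be positive and finite")
  if (is.null(atoms$flags)) atoms$flags <- ""
  if (is.null(atoms$ring_id)) atoms$ring_id <- NA_integer_
  atoms$serial <- seq_len(n)
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1 | bonds > n)) stop("bond atom index out of range")
  }
  if (length(rings)) {
    for (rid in names(rings)) {
      cyc <- rings[[rid]]
      if (any(cyc < 1 | cyc > n)) stop("ring ", rid, ": atom index out of range")
      if (length(cyc) < 4) stop("ring ", rid, ": a ring cycle needs >= 4 atoms")
      if (anyDuplicated(cyc)) stop("ring ", rid, ": cycle atoms must be unique")
    }
  }
  # consistency: an atom may carry at most one of cation_group/anion_group,
  # and a hydrogen-flagged atom must be element H
  fl <- strsplit(atoms$flags, ";", fixed = TRUE)
  both <- vapply(fl, function(f) all(c("cation_group", "anion_group") %in% f), logical(1))
  if (any(both)) stop("atom flagged both cation_group and anion_group")
  hyd <- vapply(fl, function(f) "hydrogen" %in% f, logical(1))
  if (any(hyd & toupper(atoms$element) != "H"))
    stop("hydrogen flag on a non-H element")
  structure(list(atoms = atoms, bonds = bonds, rings = rings),
            class = "ligdyn_topology")
}

#' @export
print.ligdyn_topology <- function(x, ...) {
  cat("ligdyn topology:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), "residues,",
      if (is.null(x$bonds)) 0 else nrow(x$bonds), "bonds,",
      length(x$rings), "rings\n")
  invisible(x)
}

#' Construct a trajectory
#'
#' @param topology a `ligdyn_topology`.
#' @param coords numeric array of dimension frames x atoms x 3 (Angstrom).
#'   A single n x 3 matrix is promoted to a 1-frame trajectory.
#' @param frame_spacing time between frames in ps (metadata only).
#' @return object of class `ligdyn_trajectory`.
#' @export
trajectory <- function(topology, coords, frame_spacing = 10) {
  stopifnot(inherits(topology, "ligdyn_topology"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(1, dim(coords)))
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be a frames x atoms x 3 array")
  if (dim(coords)[1] < 1) stop("a trajectory needs at least one frame")
  if (dim(coords)[2] != nrow(topology$atoms))
    stop("coords atom dimension (", dim(coords)[2],
         ") does not match topology (", nrow(topology$atoms), " atoms)")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  structure(list(topology = topology, coords = coords,
                 frame_spacing = frame_spacing),
            class = "ligdyn_trajectory")
}

#' @export
print.ligdyn_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("ligdyn trajectory:", d[1], "frames x", d[2], "atoms",
      sprintf("(%.6g ps/frame)\n", x$frame_spacing))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `ligdyn_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame as an atoms x 3 matrix
#' @param traj a `ligdyn_trajectory`.
#' @param i frame index (1-based).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$coords[i, , ], ncol = 3)
}

## ---------------------------------------------------------------- PDB I/O

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL/ENDMDL block becomes one frame; a file without MODEL records
#' is read as a 1-frame trajectory. Atom order must be identical across
#' frames; the element is taken from PDB columns 77-78 with a fallback to
#' the first letter of the atom name. Occupancy and B-factor are ignored.
#'
#' @param path path to a PDB file.
#' @param frame_spacing time between frames in ps (metadata).
#' @return a `ligdyn_trajectory`.
#' @export
read_multimodel_pdb <- function(path, frame_spacing = 10) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # validate coordinate fields up front so a bad line is reported by number
  atom_lines <- which(is_atom)
  for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
    v <- suppressWarnings(as.numeric(substr(lines[atom_lines], fld[1], fld[2])))
    if (anyNA(v)) {
      bad <- atom_lines[which(is.na(v))[1]]
      stop("unparseable ATOM record at line ", bad, " of ", path)
    }
  }

  # per-MODEL atom counts must agree; report the offending MODEL by number
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1) {
    model_ids <- trimws(substr(lines[model_starts], 7, 14))
    bounds <- c(model_starts, length(lines) + 1L)
    counts <- vapply(seq_along(model_starts), function(k) {
      sum(is_atom[bounds[k]:(bounds[k + 1] - 1L)])
    }, integer(1))
    if (length(unique(counts)) != 1) {
      off <- which(counts != counts[1])[1]
      stop("atom count mismatch in MODEL ", model_ids[off],
           " (", counts[off], " atoms vs ", counts[1], " in MODEL ",
           model_ids[1], ")")
    }
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- trimws(at$elesy)
  noel <- is.na(elem) | elem == ""
  if (any(noel)) elem[noel] <- substr(gsub("[^A-Za-z].*", "", trimws(at$elety[noel])), 1, 1)
  atoms <- data.frame(
    name = trimws(at$elety), element = elem, resid = at$resno,
    resname = trimws(at$resid), chain = ifelse(is.na(at$chain), "", at$chain),
    stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nfr <- nrow(xyz)
  nat <- ncol(xyz) / 3
  coords <- array(NA_real_, dim = c(nfr, nat, 3))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, ncol(xyz), by = 3), drop = FALSE]
  trajectory(topology(atoms), coords, frame_spacing = frame_spacing)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Emits standards-conformant fixed-width ATOM records with one
#' MODEL/ENDMDL block per frame; CONECT records are omitted.
#'
#' @param traj a `ligdyn_trajectory`.
#' @param path output path.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "ligdyn_trajectory"))
  if (n_frames(traj) < 1) stop("refusing to write an empty trajectory")
  if (max(abs(traj$coords)) > 9999.999)
    stop("coordinate magnitude exceeds the PDB fixed-width field")
  at <- traj$topology$atoms
  nfr <- n_frames(traj)
  nat <- nrow(at)
  xyz <- matrix(NA_real_, nfr, 3 * nat)
  for (k in 1:3) xyz[, seq(k, 3 * nat, by = 3)] <- traj$coords[, , k]
  het <- !(at$resname %in% STANDARD_AA)
  type <- ifelse(het, "HETATM", "ATOM")
  bio3d::write.pdb(file = path, xyz = xyz, type = type,
                   resno = at$resid, resid = at$resname,
                   eleno = seq_len(nat), elety = at$name,
                   chain = ifelse(at$chain == "", " ", at$chain),
                   elesy = at$element)
  invisible(path)
}

## --------------------------------------------------------- annotation I/O

#' Load a chemistry annotation sidecar onto a topology
#'
#' The sidecar is a TSV with header columns `chain`, `resid`, `name`,
#' `element`, `vdw_radius`, `flags` (semicolon-separated subset of
#' donor/acceptor/hydrogen/polar/nonpolar_carbon/cation_group/anion_group)
#' and `ring_id`. Rows are matched to atoms by (chain, resid, name).
#' Unannotated atoms keep defaults: the Bondi vdW radius for their element
#' and no flags. Ring cycles are assembled in sidecar row order.
#'
#' @param path path to the annotation TSV.
#' @param topo a `ligdyn_topology`.
#' @return the topology with flags, radii and rings filled in; the number
#'   of annotation rows that matched no atom is attached as attribute
#'   `n_unmatched` (and raised as a warning when non-zero).
#' @export
load_annotation <- function(path, topo) {
  stopifnot(inherits(topo, "ligdyn_topology"))
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  req <- c("chain", "resid", "name")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  at <- topo$atoms
  key_atom <- paste(at$chain, at$resid, at$name, sep = "|")
  key_ann <- paste(ann$chain, ann$resid, ann$name, sep = "|")
  idx <- match(key_ann, key_atom)
  n_unmatched <- sum(is.na(idx))
  if (n_unmatched > 0)
    warning(n_unmatched, " annotation row(s) matched no atom")
  ok <- !is.na(idx)
  if (!is.null(ann$vdw_radius)) {
    v <- suppressWarnings(as.numeric(ann$vdw_radius))
    use <- ok & !is.na(v)
    at$vdw_radius[idx[use]] <- v[use]
  }
  if (!is.null(ann$flags)) {
    f <- ifelse(is.na(ann$flags), "", ann$flags)
    unknown <- setdiff(unlist(strsplit(f[ok], ";")), c(KNOWN_FLAGS, ""))
    if (length(unknown))
      warning("unknown flag(s) ignored: ", paste(unique(unknown), collapse = ", "))
    at$flags[idx[ok]] <- f[ok]
  }
  rings <- topo$rings
  if (!is.null(ann$ring_id)) {
    rid <- suppressWarnings(as.integer(ann$ring_id))
    has_ring <- ok & !is.na(rid)
    at$ring_id[idx[has_ring]] <- rid[has_ring]
    partial <- character(0)
    for (r in unique(rid[has_ring])) {
      cyc <- idx[has_ring & rid == r]
      # a closed ring cycle needs >= 4 atoms; fewer annotated atoms mark
      # ring membership on the atoms without defining a usable cycle
      if (length(cyc) >= 4) rings[[as.character(r)]] <- cyc
      else partial <- c(partial, as.character(r))
    }
    if (length(partial))
      warning("ring id(s) with fewer than 4 annotated atoms kept as atom ",
              "flags only: ", paste(partial, collapse = ", "))
  }
  out <- topology(at, bonds = topo$bonds, rings = rings)
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Write the annotation sidecar for a topology
#'
#' Inverse of [load_annotation()]; used by the synthetic-data generators so
#' tests exercise the real I/O path.
#'
#' @param topo a `ligdyn_topology`.
#' @param path output TSV path.
#' @export
write_annotation <- function(topo, path) {
  at <- topo$atoms
  ann <- data.frame(chain = at$chain, resid = at$resid, name = at$name,
                    element = at$element, vdw_radius = at$vdw_radius,
                    flags = at$flags, ring_id = at$ring_id)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Logical vector: which atoms carry a given flag
#' @param topo a `ligdyn_topology`.
#' @param flag flag name, e.g. "donor".
#' @export
has_flag <- function(topo, flag) {
  vapply(strsplit(topo$atoms$flags, ";", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

## ------------------------------------------------------------- selections

#' Construct a selection from explicit indices
#' @param indices integer atom indices (1-based); deduplicated and sorted.
#' @param label free-text label.
#' @export
selection <- function(indices, label = "") {
  indices <- sort(unique(as.integer(indices)))
  structure(list(indices = indices, label = label), class = "ligdyn_selection")
}

#' @export
print.ligdyn_selection <- function(x, ...) {
  cat("ligdyn selection [", x$label, "]: ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}

#' @export
length.ligdyn_selection <- function(x) length(x$indices)

#' Select atoms of a topology with a small expression grammar
#'
#' The grammar supports keyword selectors `name`, `resname`, `resid`
#' (values or inclusive ranges like `125-129`), `chain`, `element`, `flag`,
#' combined with `and`, `or`, `not` and parentheses, plus the shortcuts
#' `all`, `protein` (standard amino-acid resnames), `backbone`
#' (protein N, CA, C, O), `calpha` (protein CA) and `heavy`
#' (element != H).
#'
#' @param topo a `ligdyn_topology`.
#' @param expr selection expression, e.g. `"heavy and not protein"`.
#' @return a `ligdyn_selection` with a deterministic sorted index set.
#' @export
select_atoms <- function(topo, expr) {
  stopifnot(inherits(topo, "ligdyn_topology"))
  toks <- sel_tokenize(expr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  st$expr <- expr
  mask <- sel_parse_or(st, topo)
  if (st$pos <= length(st$toks$text))
    sel_err(st, "unexpected token '", st$toks$text[st$pos], "'")
  selection(which(mask), label = expr)
}

sel_tokenize <- function(expr) {
  if (!nzchar(trimws(expr))) stop("empty selection expression")
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, expr)[[1]]
  text <- regmatches(expr, gregexpr(pat, expr))[[1]]
  list(text = text, start = as.integer(m))
}

sel_err <- function(st, ...) {
  pos <- if (st$pos <= length(st$toks$start)) st$toks$start[st$pos]
         else nchar(st$expr) + 1L
  stop("selection syntax error at position ", pos, ": ", ..., call. = FALSE)
}

sel_peek <- function(st) {
  if (st$pos > length(st$toks$text)) NA_character_ else st$toks$text[st$pos]
}

sel_parse_or <- function(st, topo) {
  m <- sel_parse_and(st, topo)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    m <- m | sel_parse_and(st, topo)
  }
  m
}

sel_parse_and <- function(st, topo) {
  m <- sel_parse_not(st, topo)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    m <- m & sel_parse_not(st, topo)
  }
  m
}

sel_parse_not <- function(st, topo) {
  if (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "not") {
    st$pos <- st$pos + 1L
    return(!sel_parse_not(st, topo))
  }
  sel_parse_primary(st, topo)
}

SEL_RESERVED <- c("and", "or", "not", "(", ")")

sel_values <- function(st) {
  vals <- character(0)
  while (!is.na(sel_peek(st)) && !(tolower(sel_peek(st)) %in% SEL_RESERVED)) {
    vals <- c(vals, st$toks$text[st$pos])
    st$pos <- st$pos + 1L
  }
  if (!length(vals)) sel_err(st, "selector needs at least one value")
  vals
}

sel_parse_primary <- function(st, topo) {
  tok <- sel_peek(st)
  if (is.na(tok)) sel_err(st, "unexpected end of expression")
  at <- topo$atoms
  n <- nrow(at)
  is_protein <- at$resname %in% STANDARD_AA
  lower <- tolower(tok)
  st$pos <- st$pos + 1L
  switch(lower,
    "(" = {
      m <- sel_parse_or(st, topo)
      if (is.na(sel_peek(st)) || sel_peek(st) != ")")
        sel_err(st, "missing closing parenthesis")
      st$pos <- st$pos + 1L
      m
    },
    "all" = rep(TRUE, n),
    "protein" = is_protein,
    "backbone" = is_protein & at$name %in% c("N", "CA", "C", "O"),
    "calpha" = is_protein & at$name == "CA",
    "heavy" = toupper(at$element) != "H",
    "name" = at$name %in% sel_values(st),
    "resname" = at$resname %in% sel_values(st),
    "chain" = at$chain %in% sel_values(st),
    "element" = toupper(at$element) %in% toupper(sel_values(st)),
    "flag" = {
      vals <- sel_values(st)
      bad <- setdiff(vals, KNOWN_FLAGS)
      if (length(bad)) sel_err(st, "unknown flag '", bad[1], "'")
      Reduce(`|`, lapply(vals, function(f) has_flag(topo, f)))
    },
    "resid" = {
      vals <- sel_values(st)
      m <- rep(FALSE, n)
      for (v in vals) {
        if (grepl("^-?[0-9]+--?[0-9]+$", v)) {
          parts <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
          lo <- as.integer(parts[2]); hi <- as.integer(parts[3])
          m <- m | (at$resid >= lo & at$resid <= hi)
        } else if (grepl("^-?[0-9]+$", v)) {
          m <- m | at$resid == as.integer(v)
        } else sel_err(st, "bad resid value '", v, "'")
      }
      m
    },
    {
      st$pos <- st$pos - 1L
      sel_err(st, "unknown selector '", tok, "'")
    })
}
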