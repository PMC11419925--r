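#' Construct a structure object
#'
#' A structure is an ordered atom table plus a note recording the residue
#' numbering convention in force (mature-protein numbering allows negative
#' residue numbers for the propeptide, e.g. -7..-1).
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `chain`, `resseq`, `x`, `y`, `z`.
#' @param numbering_note free-text note on the numbering convention.
#' @return An object of class `pdb_structure`.
#' @export
new_structure <- function(atoms, numbering_note = "mature-protein numbering") {
  required <- c("serial", "name", "element", "resname", "chain", "resseq",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[required]
  atoms$name <- as.character(atoms$name)
  atoms$element <- toupper(as.character(atoms$element))
  atoms$resname <- toupper(as.character(atoms$resname))
  atoms$chain <- as.character(atoms$chain)
  atoms$resseq <- as.integer(atoms$resseq)
  if (nrow(atoms) < 1L) stop("structure must contain at least one atom")
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")])))) {
    stop("non-finite coordinates in atoms table")
  }
  if (any(atoms$element == "" | is.na(atoms$element))) {
    stop("empty element symbol in atoms table")
  }
  key <- paste(atoms$chain, atoms$resseq, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom name) triple: ",
         key[anyDuplicated(key)][1L])
  }
  structure(list(atoms = atoms, numbering_note = numbering_note),
            class = "pdb_structure")
}

#' Construct a trajectory from a list of structures
#'
#' All frames must share one topology: identical atom count and identical
#' (chain, residue, atom name) ordering.
#'
#' @param frames list of `pdb_structure` objects.
#' @param frame_times optional numeric vector of frame times (ns), strictly
#'   increasing.
#' @return An object of class `pdb_trajectory` holding one shared topology
#'   and an `n_atoms x 3 x n_frames` coordinate array.
#' @export
as_trajectory <- function(frames, frame_times = NULL) {
  if (inherits(frames, "pdb_structure")) frames <- list(frames)
  stopifnot(length(frames) >= 1L)
  topo_key <- function(s) paste(s$atoms$chain, s$atoms$resseq, s$atoms$name)
  ref <- topo_key(frames[[1L]])
  for (i in seq_along(frames)) {
    k <- topo_key(frames[[i]])
    if (length(k) != length(ref) || any(k != ref)) {
      stop("topology mismatch: frame ", i,
           " does not share the atom ordering of frame 1")
    }
  }
  if (!is.null(frame_times)) {
    stopifnot(length(frame_times) == length(frames))
    if (any(diff(frame_times) <= 0)) {
      stop("frame_times must be strictly increasing")
    }
  }
  coords <- array(NA_real_, dim = c(length(ref), 3L, length(frames)))
  for (i in seq_along(frames)) {
    coords[, , i] <- as.matrix(frames[[i]]$atoms[c("x", "y", "z")])
  }
  topology <- frames[[1L]]$atoms
  topology$x <- topology$y <- topology$z <- NULL
  structure(list(topology = topology, coords = coords,
                 frame_times = frame_times,
                 numbering_note = frames[[1L]]$numbering_note),
            class = "pdb_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `pdb_trajectory`.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "pdb_trajectory"))
  dim(traj$coords)[3L]
}

#' Extract one frame of a trajectory as a structure
#' @param traj a `pdb_trajectory`.
#' @param i frame index (1-based).
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "pdb_trajectory"),
            i >= 1L, i <= n_frames(traj))
  atoms <- traj$topology
  atoms$x <- traj$coords[, 1L, i]
  atoms$y <- traj$coords[, 2L, i]
  atoms$z <- traj$coords[, 3L, i]
  new_structure(atoms, traj$numbering_note)
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat("<pdb_structure> ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resseq))), " residues (",
      x$numbering_note, ")\n", sep = "")
  invisible(x)
}

#' @export
print.pdb_trajectory <- function(x, ...) {
  cat("<pdb_trajectory> ", n_frames(x), " frames x ",
      nrow(x$topology), " atoms\n", sep = "")
  invisible(x)
}

# -- reading ------------------------------------------------------------

# Pre-scan a PDB file: MODEL/ENDMDL balance, per-model atom counts,
# coordinate-field sanity with the offending line number.
pdb_prescan <- function(lines, path) {
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  n_model <- sum(rec == "MODEL ")
  n_endmdl <- sum(rec == "ENDMDL")
  if (n_model != n_endmdl) {
    stop("unbalanced MODEL/ENDMDL records in ", path,
         " (", n_model, " MODEL vs ", n_endmdl, " ENDMDL)")
  }
  for (ln in which(is_atom)) {
    fields <- c(substr(lines[ln], 31L, 38L), substr(lines[ln], 39L, 46L),
                substr(lines[ln], 47L, 54L))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop("malformed coordinate field at line ", ln, " of ", path)
    }
  }
  if (n_model > 0L) {
    model_id <- cumsum(rec == "MODEL ")
    counts <- tapply(is_atom & model_id > 0L, model_id, sum)
    counts <- counts[names(counts) != "0"]
    if (length(unique(counts)) > 1L) {
      stop("topology mismatch in ", path, ": models contain ",
           paste(unique(counts), collapse = ", "), " atoms")
    }
  }
  n_model
}

#' Read a PDB file as a structure or trajectory
#'
#' Files without MODEL records yield a single [new_structure()]; files with
#' MODEL/ENDMDL blocks yield a [as_trajectory()] with one frame per model.
#' HETATM records (including the heme group) are retained. Alternate
#' locations other than blank or 'A' are dropped, with a message giving the
#' count. Parsing is delegated to \pkg{bio3d}; this wrapper adds record
#' validation (line-numbered coordinate errors, MODEL balance, per-model
#' topology consistency) and the package's structure/trajectory containers.
#'
#' @param path path to a PDB file.
#' @param numbering_note note recorded on the returned object.
#' @return A `pdb_structure` or `pdb_trajectory`.
#' @export
read_pdb <- function(path, numbering_note = "mature-protein numbering") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  n_model <- pdb_prescan(lines, path)

  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom
  alt <- at$alt
  keep <- is.na(alt) | alt %in% c("", " ", "A")
  if (any(!keep)) {
    message("read_pdb: dropped ", sum(!keep),
            " alternate-location atom(s) (altloc not blank/'A')")
  }
  elesy <- at$elesy
  need_ele <- is.na(elesy) | trimws(elesy) == ""
  if (any(need_ele)) {
    elesy[need_ele] <- suppressWarnings(bio3d::atom2ele(at$elety[need_ele]))
  }
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = trimws(elesy),
    resname = trimws(at$resid), chain = ifelse(is.na(at$chain), "A", at$chain),
    resseq = at$resno, x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]

  if (n_model <= 1L && (is.null(dim(pdb$xyz)) || nrow(pdb$xyz) == 1L)) {
    return(new_structure(atoms, numbering_note))
  }
  xyz <- pdb$xyz
  idx <- which(keep)
  frames <- vector("list", nrow(xyz))
  for (m in seq_len(nrow(xyz))) {
    a <- atoms
    a$x <- xyz[m, 3L * idx - 2L]
    a$y <- xyz[m, 3L * idx - 1L]
    a$z <- xyz[m, 3L * idx]
    frames[[m]] <- new_structure(a, numbering_note)
  }
  as_trajectory(frames)
}

#' Write a structure or trajectory to a PDB file
#'
#' Trajectories are written as multi-model PDB (one MODEL block per frame).
#' Atoms whose residue name matches `het_resnames` are written as HETATM
#' records. Coordinates are printed at the format's 3-decimal precision.
#'
#' @param x a `pdb_structure` or `pdb_trajectory`.
#' @param path output path.
#' @param het_resnames residue names written as HETATM (default heme).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, het_resnames = "HEM") {
  if (inherits(x, "pdb_structure")) {
    topo <- x$atoms
    xyz <- matrix(t(as.matrix(x$atoms[c("x", "y", "z")])), nrow = 1L)
  } else if (inherits(x, "pdb_trajectory")) {
    topo <- x$topology
    nf <- n_frames(x)
    xyz <- matrix(NA_real_, nrow = nf, ncol = 3L * nrow(topo))
    for (m in seq_len(nf)) {
      xyz[m, ] <- as.vector(t(x$coords[, , m]))
    }
  } else {
    stop("x must be a pdb_structure or pdb_trajectory")
  }
  type <- ifelse(topo$resname %in% het_resnames, "HETATM", "ATOM")
  bio3d::write.pdb(file = path, xyz = xyz, type = type,
                   resno = topo$resseq, resid = topo$resname,
                   eleno = topo$serial, elety = topo$name,
                   chain = topo$chain, elesy = topo$element)
  if (any(type == "HETATM")) {
    # bio3d's multi-model writer emits everything as ATOM; restore the
    # HETATM record type for het residues
    lines <- readLines(path, warn = FALSE)
    is_atom <- startsWith(lines, "ATOM  ")
    resnames <- trimws(substr(lines, 18L, 20L))
    fix <- is_atom & resnames %in% het_resnames
    lines[fix] <- sub("^ATOM  ", "HETATM", lines[fix])
    writeLines(lines, path)
  }
  invisible(path)
}

# -- selections ---------------------------------------------------------

#' Select atoms by chain, residue and atom name
#'
#' Returns the resolved, duplicate-free atom indices with a description
#' attribute. `resseq` may be a vector of residue numbers or a list of
#' `c(lo, hi)` ranges; `exclude_resseq` removes residues the same way
#' (used for the terminal-exclusion convention, propeptide -7..-1 and
#' C-terminal 329..344).
#'
#' @param x a `pdb_structure` or `pdb_trajectory`.
#' @param chain chain id(s), or NULL for all.
#' @param resseq residue numbers or list of ranges, or NULL for all.
#' @param names atom name(s), or NULL for all.
#' @param exclude_resseq residue numbers or list of ranges to drop.
#' @return Integer index vector of class `atom_selection`.
#' @export
select_atoms <- function(x, chain = NULL, resseq = NULL, names = NULL,
                         exclude_resseq = NULL) {
  topo <- if (inherits(x, "pdb_trajectory")) x$topology else x$atoms
  expand_ranges <- function(r) {
    if (is.null(r)) return(NULL)
    if (is.list(r)) unlist(lapply(r, function(ab) seq(ab[1L], ab[2L]))) else r
  }
  keep <- rep(TRUE, nrow(topo))
  if (!is.null(chain)) keep <- keep & topo$chain %in% chain
  rs <- expand_ranges(resseq)
  if (!is.null(rs)) keep <- keep & topo$resseq %in% rs
  if (!is.null(names)) keep <- keep & topo$name %in% names
  ex <- expand_ranges(exclude_resseq)
  if (!is.null(ex)) keep <- keep & !(topo$resseq %in% ex)
  idx <- which(keep)
  attr(idx, "description") <- paste0(
    "chain=", if (is.null(chain)) "*" else paste(chain, collapse = ","),
    " resseq=", if (is.null(rs)) "*" else paste(range(rs), collapse = ".."),
    " names=", if (is.null(names)) "*" else paste(names, collapse = ","),
    if (!is.null(ex)) paste0(" excluding=", paste(range(ex), collapse = ".."))
  )
  class(idx) <- "atom_selection"
  idx
}

#' Default protein-core Cα selection
#'
#' Cα atoms excluding the flexible termini: the propeptide (-7..-1) and the
#' C-terminal tail (329..344) under mature-protein numbering. This is the
#' default selection for trajectory RMSD.
#'
#' @param x a `pdb_structure` or `pdb_trajectory`.
#' @param exclude list of `c(lo, hi)` residue ranges to drop.
#' @export
protein_core_selection <- function(x, exclude = list(c(-7L, -1L),
                                                     c(329L, 344L))) {
  select_atoms(x, names = "CA", exclude_resseq = exclude)
}
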