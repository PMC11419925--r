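coords_matrix <- function(x, idx = NULL) {
  m <- as.matrix(x$atoms[c("x", "y", "z")])
  if (!is.null(idx)) m <- m[as.integer(idx), , drop = FALSE]
  m
}

# Kabsch algorithm: least-squares proper rotation via SVD, with the
# determinant correction that excludes reflections.
kabsch_rotation <- function(mobile_xyz, ref_xyz) {
  mc <- colMeans(mobile_xyz)
  rc <- colMeans(ref_xyz)
  h <- crossprod(sweep(mobile_xyz, 2L, mc), sweep(ref_xyz, 2L, rc))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = rot, mobile_center = mc, ref_center = rc)
}

#' Rigid-body superposition of one structure onto another
#'
#' Least-squares proper-rotation (Kabsch) alignment of the selected atoms of
#' `mobile` onto those of `reference`; the fitted transform is then applied
#' to every atom of `mobile`.
#'
#' @param mobile,reference `pdb_structure` objects.
#' @param selection atom indices (see [select_atoms()]) resolved in both
#'   structures; at least 3 non-collinear atoms.
#' @param selection_ref selection in `reference` when its indexing differs.
#' @return List with the transformed `structure`, the 3x3 `rotation`, and
#'   the `translation` applied after rotation about the mobile centroid.
#' @export
kabsch_superpose <- function(mobile, reference, selection,
                             selection_ref = selection) {
  mx <- coords_matrix(mobile, selection)
  rx <- coords_matrix(reference, selection_ref)
  if (nrow(mx) < 3L || nrow(rx) < 3L) {
    stop("superposition needs at least 3 selected atoms")
  }
  if (nrow(mx) != nrow(rx)) stop("selections resolve to different atom counts")
  for (m in list(mx, rx)) {
    cm <- sweep(m, 2L, colMeans(m))
    if (sum(svd(cm)$d > 1e-8) < 2L) {
      stop("degenerate geometry: selected atoms are collinear")
    }
  }
  fit <- kabsch_rotation(mx, rx)
  all_xyz <- coords_matrix(mobile)
  moved <- sweep(all_xyz, 2L, fit$mobile_center) %*% t(fit$rotation)
  moved <- sweep(moved, 2L, fit$ref_center, FUN = "+")
  out <- mobile
  out$atoms$x <- moved[, 1L]
  out$atoms$y <- moved[, 2L]
  out$atoms$z <- moved[, 3L]
  list(structure = out, rotation = fit$rotation,
       translation = unname(fit$ref_center -
                            as.vector(fit$rotation %*% fit$mobile_center)))
}

#' Root-mean-square deviation between two structures
#'
#' RMSD over the selected atoms, optionally after Kabsch superposition of
#' the selection. The conventional trajectory observable uses the
#' protein-core Cα selection ([protein_core_selection()]), which excludes
#' the flexible N- and C-terminal residues.
#'
#' @param frame,reference `pdb_structure` objects.
#' @param selection atom indices resolved in both.
#' @param superpose superpose the selection before measuring?
#' @return RMSD in Å (non-negative scalar).
#' @export
rmsd <- function(frame, reference, selection, superpose = FALSE) {
  if (length(selection) == 0L) stop("empty selection")
  if (superpose) {
    frame <- kabsch_superpose(frame, reference, selection)$structure
  }
  a <- coords_matrix(frame, selection)
  b <- coords_matrix(reference, selection)
  if (nrow(a) != nrow(b)) stop("selections resolve to different atom counts")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame RMSD trace over a trajectory
#'
#' @param traj a `pdb_trajectory`.
#' @param reference reference `pdb_structure` (default: first frame).
#' @param selection atom indices (default: protein-core Cα).
#' @param superpose superpose each frame onto the reference first?
#' @return data.frame with `frame`, `time_ns` (NA when unknown), `rmsd`.
#' @export
rmsd_trace <- function(traj, reference = NULL, selection = NULL,
                       superpose = TRUE) {
  stopifnot(inherits(traj, "pdb_trajectory"))
  if (is.null(reference)) reference <- get_frame(traj, 1L)
  if (is.null(selection)) selection <- protein_core_selection(traj)
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(i) {
    rmsd(get_frame(traj, i), reference, selection, superpose = superpose)
  }, numeric(1L))
  data.frame(
    frame = seq_len(nf),
    time_ns = if (is.null(traj$frame_times)) NA_real_ else traj$frame_times,
    rmsd = vals
  )
}

#' Inter-atom distance trace over a trajectory
#'
#' Euclidean distance between two single atoms in every frame, with mean
#' and sample (n-1) standard deviation. This is the observable behind
#' residue-to-propionate distance monitoring (by default the propionate-A
#' carboxylate oxygen to a residue Cα).
#'
#' @param traj a `pdb_trajectory`.
#' @param atom_a,atom_b selector lists with any of `chain`, `resseq`,
#'   `name`; each must resolve to exactly one atom.
#' @param frames optional `c(first, last)` frame-index window.
#' @return Object of class `distance_trace`: list with `trace` (data.frame
#'   `frame`, `time_ns`, `distance`), `mean`, `sd`, `degenerate` (TRUE when
#'   a single frame makes the sd undefined; reported as 0).
#' @export
distance_trace <- function(traj, atom_a, atom_b, frames = NULL) {
  stopifnot(inherits(traj, "pdb_trajectory"))
  resolve_one <- function(sel) {
    idx <- select_atoms(traj, chain = sel$chain, resseq = sel$resseq,
                        names = sel$name)
    if (length(idx) != 1L) {
      stop("selector resolves to ", length(idx), " atoms (need exactly 1): ",
           attr(idx, "description"))
    }
    as.integer(idx)
  }
  ia <- resolve_one(atom_a)
  ib <- resolve_one(atom_b)
  nf <- n_frames(traj)
  window <- if (is.null(frames)) seq_len(nf) else {
    stopifnot(frames[1L] >= 1L, frames[2L] <= nf, frames[1L] <= frames[2L])
    seq(frames[1L], frames[2L])
  }
  delta <- traj$coords[ia, , window, drop = FALSE] -
    traj$coords[ib, , window, drop = FALSE]
  dvec <- sqrt(apply(delta, 3L, function(m) sum(m^2)))
  degenerate <- length(dvec) < 2L
  out <- list(
    trace = data.frame(
      frame = window,
      time_ns = if (is.null(traj$frame_times)) NA_real_
                else traj$frame_times[window],
      distance = dvec
    ),
    mean = mean(dvec),
    sd = if (degenerate) 0 else stats::sd(dvec),
    degenerate = degenerate,
    atoms = c(attr(select_atoms(traj, chain = atom_a$chain,
                                resseq = atom_a$resseq, names = atom_a$name),
                   "description"),
              attr(select_atoms(traj, chain = atom_b$chain,
                                resseq = atom_b$resseq, names = atom_b$name),
                   "description"))
  )
  class(out) <- "distance_trace"
  out
}

#' @export
print.distance_trace <- function(x, ...) {
  cat(sprintf("<distance_trace> %d frames: %.2f +/- %.2f A%s\n",
              nrow(x$trace), x$mean, x$sd,
              if (x$degenerate) " (single frame; sd degenerate)" else ""))
  invisible(x)
}

#' Write a trace as tidy TSV
#'
#' One row per frame, columns `frame_index`, `time_ns`, `value`, preceded
#' by `#`-commented header lines naming the selections.
#'
#' @param trace a `distance_trace`, or a data.frame from [rmsd_trace()].
#' @param path output path.
#' @param comment extra comment lines (without the leading `#`).
#' @export
write_trace_tsv <- function(trace, path, comment = character()) {
  if (inherits(trace, "distance_trace")) {
    df <- trace$trace
    names(df) <- c("frame_index", "time_ns", "value")
    comment <- c(paste("atoms:", paste(trace$atoms, collapse = " | ")),
                 sprintf("mean=%.6g sd=%.6g", trace$mean, trace$sd), comment)
  } else {
    df <- trace
    names(df)[names(df) == "frame"] <- "frame_index"
    names(df)[3L] <- "value"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
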