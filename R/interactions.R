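# Angle at vertex `at` between the directions to `a` and `b`, in degrees.
angle_deg <- function(a, at, b) {
  u <- a - at
  v <- b - at
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

interaction_categories <- c("BB_CH", "SC_H", "SC_CH", "SC_SB")

donor_class_category <- c(backbone_carbon = "BB_CH",
                          sidechain_polar = "SC_H",
                          sidechain_carbon = "SC_CH")

#' Test one donor/acceptor pair against the hydrogen-bond criteria
#'
#' A (carbon) hydrogen bond is recorded when the heavy-atom donor-acceptor
#' distance d is within the element cutoff (3.4 Å for N/O, 3.8 Å for S/C by
#' default) and at least one antecedent combination places both the X-D-A
#' angle at the donor and the D-A-Y angle at the acceptor inside the
#' 90-180 degree window. Hydrogens are not used.
#'
#' @param donor list with `xyz` (length-3), `element` (`"N"`, `"O"`, `"S"`
#'   or `"C"`), `class` (one of `backbone_carbon`, `sidechain_polar`,
#'   `sidechain_carbon`), and `antecedents`: a matrix of candidate X
#'   coordinates (one row per antecedent, rownames = atom names).
#' @param acceptor list with `xyz` (the carboxylate oxygen) and `y_xyz`
#'   (the carboxylate carbon, the Y of D-A-Y).
#' @param criteria a [geometric_criteria()].
#' @return NULL when the pair fails; otherwise a list with `category`,
#'   `d`, `angle_xda`, `angle_day` and the accepted `antecedent` name.
#' @export
detect_hbond <- function(donor, acceptor, criteria = geometric_criteria()) {
  x <- donor$antecedents
  if (is.null(x) || nrow(x) == 0L) {
    stop("unresolved geometry: donor has no antecedent atom coordinates")
  }
  if (any(!is.finite(x))) {
    bad <- rownames(x)[!stats::complete.cases(x)]
    stop("unresolved geometry: missing coordinates for antecedent atom ",
         paste(bad, collapse = ", "))
  }
  d <- sqrt(sum((donor$xyz - acceptor$xyz)^2))
  d_max <- if (donor$element %in% c("N", "O")) criteria$d_max_no
           else criteria$d_max_sc
  if (d > d_max) return(NULL)
  day <- angle_deg(donor$xyz, acceptor$xyz, acceptor$y_xyz)
  if (day < criteria$angle_min || day > criteria$angle_max) return(NULL)
  for (i in seq_len(nrow(x))) {
    xda <- angle_deg(x[i, ], donor$xyz, acceptor$xyz)
    if (xda >= criteria$angle_min && xda <= criteria$angle_max) {
      return(list(category = unname(donor_class_category[donor$class]),
                  d = d, angle_xda = xda, angle_day = day,
                  antecedent = rownames(x)[i]))
    }
  }
  NULL
}

#' Test an Arg/Lys residue against the salt-bridge criterion
#'
#' A salt bridge is recorded when the minimum distance from the residue's
#' charged-group nitrogens (NH1/NH2/NE for Arg, NZ for Lys) to the
#' carboxylate oxygen is within the cutoff (5.6 Å by default). No angle
#' condition applies.
#'
#' @param residue data.frame of the residue's atoms (columns `name`, `x`,
#'   `y`, `z`, `resname`); must be arginine or lysine.
#' @param acceptor list with `xyz`, the carboxylate oxygen coordinates.
#' @param criteria a [geometric_criteria()].
#' @return NULL, or a list with `category = "SC_SB"`, `d` (the minimum
#'   distance) and `donor_atom` (the nitrogen attaining it).
#' @export
detect_salt_bridge <- function(residue, acceptor,
                               criteria = geometric_criteria()) {
  resname <- toupper(residue$resname[1L])
  charged <- salt_bridge_atoms()[[resname]]
  if (is.null(charged)) {
    stop("salt-bridge donors must be ARG or LYS, got ", resname)
  }
  rows <- residue[residue$name %in% charged, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  dd <- sqrt((rows$x - acceptor$xyz[1L])^2 + (rows$y - acceptor$xyz[2L])^2 +
             (rows$z - acceptor$xyz[3L])^2)
  i <- which.min(dd)
  if (dd[i] > criteria$d_max_salt) return(NULL)
  list(category = "SC_SB", d = dd[i], donor_atom = rows$name[i])
}

empty_events <- function() {
  data.frame(chain = character(), resseq = integer(), resname = character(),
             donor_atom = character(), acceptor_group = character(),
             acceptor_atom = character(), category = character(),
             d = numeric(), angle_xda = numeric(), angle_day = numeric())
}

#' Census all heme-propionate interactions in one frame
#'
#' Walks every residue and every applicable donor rule, tests each donor
#' against every propionate carboxylate oxygen under the geometric
#' criteria, and tests Arg/Lys residues for salt bridges. Events are
#' unique at the (donor atom, acceptor atom, category) level.
#'
#' @param frame a `pdb_structure` containing the heme group.
#' @param donors donor dictionary (see [default_donor_rules()]).
#' @param acceptors acceptor table (see [default_acceptors()]).
#' @param criteria a [geometric_criteria()].
#' @param salt_bridge_mode `"both"` records a short Arg/Lys contact as both
#'   salt bridge and hydrogen bond when each criterion holds (the criteria
#'   are stated independently); `"priority"` suppresses the hydrogen-bond
#'   event for charged-group atoms that already form a salt bridge with the
#'   same oxygen.
#' @return data.frame of events: `chain`, `resseq`, `resname`,
#'   `donor_atom`, `acceptor_group`, `acceptor_atom`, `category`, `d`,
#'   `angle_xda`, `angle_day`.
#' @export
scan_frame <- function(frame, donors = default_donor_rules(),
                       acceptors = default_acceptors(),
                       criteria = geometric_criteria(),
                       salt_bridge_mode = c("both", "priority")) {
  salt_bridge_mode <- match.arg(salt_bridge_mode)
  at <- frame$atoms
  heme_resname <- acceptors$resname[1L]
  heme <- at[at$resname == heme_resname, , drop = FALSE]
  if (nrow(heme) == 0L) stop("no heme residue ('", heme_resname,
                             "') in frame")
  prot <- at[at$resname != heme_resname, , drop = FALSE]
  if (nrow(prot) == 0L) stop("no donor residues in frame")

  acc_list <- list()
  for (k in seq_len(nrow(acceptors))) {
    arow <- heme[heme$name == acceptors$atom[k], , drop = FALSE]
    yrow <- heme[heme$name == acceptors$antecedent[k], , drop = FALSE]
    if (nrow(arow) != 1L || nrow(yrow) != 1L) next
    acc_list[[length(acc_list) + 1L]] <- list(
      group = acceptors$group[k], atom = acceptors$atom[k],
      xyz = c(arow$x, arow$y, arow$z), y_xyz = c(yrow$x, yrow$y, yrow$z))
  }

  events <- list()
  add <- function(res, donor_atom, acc, hit) {
    events[[length(events) + 1L]] <<- data.frame(
      chain = res$chain[1L], resseq = res$resseq[1L],
      resname = res$resname[1L], donor_atom = donor_atom,
      acceptor_group = acc$group, acceptor_atom = acc$atom,
      category = hit$category, d = hit$d,
      angle_xda = hit$angle_xda %||% NA_real_,
      angle_day = hit$angle_day %||% NA_real_)
  }

  for (res in split(prot, paste(prot$chain, prot$resseq))) {
    resname <- res$resname[1L]
    rules <- donors[donors$resname %in% c("*", resname), , drop = FALSE]
    for (r in seq_len(nrow(rules))) {
      drow <- res[res$name == rules$atom[r], , drop = FALSE]
      if (nrow(drow) != 1L) next
      ante_names <- strsplit(rules$antecedents[r], ",")[[1L]]
      arow <- res[res$name %in% ante_names, , drop = FALSE]
      if (nrow(arow) == 0L) {
        stop("unresolved geometry: no antecedent atom (",
             rules$antecedents[r], ") for donor ", rules$atom[r],
             " of residue ", resname, " ", res$resseq[1L])
      }
      dxyz <- c(drow$x, drow$y, drow$z)
      ax <- as.matrix(arow[c("x", "y", "z")])
      rownames(ax) <- arow$name
      donor <- list(xyz = dxyz, element = rules$element[r],
                    class = rules$class[r], antecedents = ax)
      for (acc in acc_list) {
        if (sum((dxyz - acc$xyz)^2) > (criteria$d_max_salt + 0.5)^2) next
        hit <- detect_hbond(donor, acc, criteria)
        if (!is.null(hit)) add(res, rules$atom[r], acc, hit)
      }
    }
    if (resname %in% names(salt_bridge_atoms())) {
      for (acc in acc_list) {
        hit <- detect_salt_bridge(res, acc, criteria)
        if (!is.null(hit)) {
          donor_atom <- hit$donor_atom
          hit$donor_atom <- NULL
          add(res, donor_atom, acc, hit)
        }
      }
    }
  }
  if (length(events) == 0L) return(empty_events())
  ev <- do.call(rbind, events)
  ev <- ev[!duplicated(ev[c("chain", "resseq", "donor_atom",
                            "acceptor_atom", "category")]), , drop = FALSE]
  if (salt_bridge_mode == "priority") {
    sb <- ev[ev$category == "SC_SB", , drop = FALSE]
    if (nrow(sb)) {
      sb_key <- paste(sb$chain, sb$resseq, sb$donor_atom, sb$acceptor_atom)
      drop <- ev$category == "SC_H" &
        paste(ev$chain, ev$resseq, ev$donor_atom, ev$acceptor_atom) %in% sb_key
      ev <- ev[!drop, , drop = FALSE]
    }
  }
  rownames(ev) <- NULL
  ev
}

#' Census interactions across a whole trajectory
#'
#' Runs [scan_frame()] on every frame and binds the events with a leading
#' `frame` column.
#'
#' @inheritParams scan_frame
#' @param traj a `pdb_trajectory`.
#' @return data.frame of events with a `frame` column; attribute
#'   `n_frames` records the trajectory length.
#' @export
scan_trajectory <- function(traj, donors = default_donor_rules(),
                            acceptors = default_acceptors(),
                            criteria = geometric_criteria(),
                            salt_bridge_mode = c("both", "priority")) {
  salt_bridge_mode <- match.arg(salt_bridge_mode)
  nf <- n_frames(traj)
  out <- vector("list", nf)
  for (i in seq_len(nf)) {
    ev <- scan_frame(get_frame(traj, i), donors, acceptors, criteria,
                     salt_bridge_mode)
    if (nrow(ev)) out[[i]] <- cbind(frame = i, ev)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  ev <- if (length(out)) do.call(rbind, out) else cbind(frame = integer(),
                                                        empty_events())
  rownames(ev) <- NULL
  attr(ev, "n_frames") <- nf
  ev
}

#' Aggregate events into per-residue interaction frequencies and distances
#'
#' For each (residue, category): the frequency I and the mean event
#' distance D, the inputs of the interaction score. In the default
#' `frame_fraction` mode I is the fraction of frames with at least one
#' event of the category for the residue (so I is in \[0, 1\]); in
#' `events_per_frame` mode I is the mean number of events per frame
#' (which can exceed 1 when a residue contacts several oxygens).
#' Zero-event categories are absent from the table; downstream scoring
#' treats them as I = 0 with D undefined.
#'
#' @param events event table from [scan_trajectory()] (or [scan_frame()]).
#' @param n_frames number of frames scanned; taken from the events
#'   attribute when present.
#' @param mode frequency definition, see above.
#' @param residues optional residue numbers to keep.
#' @return data.frame `chain`, `resseq`, `resname`, `category`, `I`, `D`,
#'   `n_events`, `n_frames`.
#' @export
aggregate_events <- function(events,
                             n_frames = attr(events, "n_frames"),
                             mode = c("frame_fraction", "events_per_frame"),
                             residues = NULL) {
  mode <- match.arg(mode)
  if (is.null(n_frames)) stop("n_frames is required (or scan a trajectory)")
  if (!("frame" %in% names(events))) {
    events <- if (nrow(events)) cbind(frame = 1L, events)
              else cbind(frame = integer(), events)
  }
  if (!is.null(residues)) {
    events <- events[events$resseq %in% residues, , drop = FALSE]
  }
  if (nrow(events) == 0L) {
    return(data.frame(chain = character(), resseq = integer(),
                      resname = character(), category = character(),
                      I = numeric(), D = numeric(), n_events = integer(),
                      n_frames = integer()))
  }
  key <- interaction(events$chain, events$resseq, events$resname,
                     events$category, drop = TRUE)
  rows <- lapply(split(events, key), function(g) {
    data.frame(
      chain = g$chain[1L], resseq = g$resseq[1L], resname = g$resname[1L],
      category = g$category[1L],
      I = if (mode == "frame_fraction") length(unique(g$frame)) / n_frames
          else nrow(g) / n_frames,
      D = mean(g$d), n_events = nrow(g), n_frames = n_frames)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chain, out$resseq, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interaction summary for one residue (the Eq-style score inputs)
#'
#' The eight numbers consumed by [interaction_score()]: frequency and mean
#' distance for backbone carbon hydrogen bonds (BBCH), sidechain hydrogen
#' bonds (SCH), sidechain carbon hydrogen bonds (SCCH) and sidechain salt
#' bridges (SCSB). A zero frequency carries an undefined (NA) distance.
#'
#' @param BBCHI,SCHI,SCCHI,SCSBI frequencies (>= 0).
#' @param BBCHD,SCHD,SCCHD,SCSBD mean distances, Å (NA when the matching
#'   frequency is 0).
#' @param n_frames frames behind the summary (metadata).
#' @return Object of class `interaction_summary`.
#' @export
interaction_summary <- function(BBCHI = 0, BBCHD = NA_real_,
                                SCHI = 0, SCHD = NA_real_,
                                SCCHI = 0, SCCHD = NA_real_,
                                SCSBI = 0, SCSBD = NA_real_,
                                n_frames = NA_integer_) {
  s <- list(BBCHI = BBCHI, BBCHD = BBCHD, SCHI = SCHI, SCHD = SCHD,
            SCCHI = SCCHI, SCCHD = SCCHD, SCSBI = SCSBI, SCSBD = SCSBD,
            n_frames = n_frames)
  for (cat in c("BBCH", "SCH", "SCCH", "SCSB")) {
    i <- s[[paste0(cat, "I")]]
    d <- s[[paste0(cat, "D")]]
    if (!is.finite(i) || i < 0) stop("negative or missing frequency for ", cat)
    if (i > 0 && (!is.finite(d) || d <= 0)) {
      stop("positive frequency for ", cat, " requires a positive distance")
    }
  }
  structure(s, class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat("<interaction_summary>\n")
  for (cat in c("BBCH", "SCH", "SCCH", "SCSB")) {
    cat(sprintf("  %-5s I = %.4g  D = %s\n", cat, x[[paste0(cat, "I")]],
                if (is.na(x[[paste0(cat, "D")]])) "-"
                else sprintf("%.3f A", x[[paste0(cat, "D")]])))
  }
  invisible(x)
}

#' Collapse an aggregate table into one residue's interaction summary
#'
#' @param agg output of [aggregate_events()].
#' @param resseq residue number to extract.
#' @param chain optional chain restriction.
#' @return An [interaction_summary()].
#' @export
summary_for_residue <- function(agg, resseq, chain = NULL) {
  g <- agg[agg$resseq == resseq, , drop = FALSE]
  if (!is.null(chain)) g <- g[g$chain == chain, , drop = FALSE]
  pick <- function(category) {
    r <- g[g$category == category, , drop = FALSE]
    if (nrow(r) == 0L) c(I = 0, D = NA_real_) else c(I = r$I[1L], D = r$D[1L])
  }
  bb <- pick("BB_CH"); sh <- pick("SC_H")
  sc <- pick("SC_CH"); sb <- pick("SC_SB")
  interaction_summary(
    BBCHI = bb[["I"]], BBCHD = bb[["D"]], SCHI = sh[["I"]], SCHD = sh[["D"]],
    SCCHI = sc[["I"]], SCCHD = sc[["D"]], SCSBI = sb[["I"]], SCSBD = sb[["D"]],
    n_frames = if (nrow(g)) g$n_frames[1L] else NA_integer_)
}

#' Write event / summary tables as TSV
#'
#' @param x event table ([scan_trajectory()]) or aggregate table
#'   ([aggregate_events()]).
#' @param path output path.
#' @param comment comment lines written with a leading `#`.
#' @export
write_interactions_tsv <- function(x, path, comment = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste("#", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
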