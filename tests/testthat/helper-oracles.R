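# Independent brute-force oracle for the interaction census, written as a
# literal nested-loop translation of the geometric criteria, plus random
# small-frame generators used by the property tests.

oracle_angle <- function(a, at, b) {
  u <- a - at
  v <- b - at
  acos(max(-1, min(1, sum(u * v) / (sqrt(sum(u * u)) * sqrt(sum(v * v)))))) *
    180 / pi
}

# Exhaustive all-pairs evaluation: every donor rule of every residue
# against every carboxylate oxygen, then Arg/Lys salt bridges with the
# min-nitrogen convention. Returns a sorted key set for comparison.
oracle_scan_keys <- function(frame, criteria = geometric_criteria()) {
  at <- frame$atoms
  heme <- at[at$resname == "HEM", , drop = FALSE]
  prot <- at[at$resname != "HEM", , drop = FALSE]
  acc_def <- list(
    list(atom = "O1A", y = "CGA"), list(atom = "O2A", y = "CGA"),
    list(atom = "O1D", y = "CGD"), list(atom = "O2D", y = "CGD"))
  xyz_of <- function(df, nm) {
    r <- df[df$name == nm, , drop = FALSE]
    if (nrow(r) != 1L) NULL else c(r$x, r$y, r$z)
  }
  rules <- default_donor_rules()
  keys <- character()
  for (resid in unique(prot$resseq)) {
    res <- prot[prot$resseq == resid, , drop = FALSE]
    resname <- res$resname[1L]
    for (ri in seq_len(nrow(rules))) {
      if (!(rules$resname[ri] %in% c("*", resname))) next
      dpos <- xyz_of(res, rules$atom[ri])
      if (is.null(dpos)) next
      ante <- strsplit(rules$antecedents[ri], ",")[[1L]]
      for (acc in acc_def) {
        apos <- xyz_of(heme, acc$atom)
        ypos <- xyz_of(heme, acc$y)
        if (is.null(apos) || is.null(ypos)) next
        d <- sqrt(sum((dpos - apos)^2))
        dmax <- if (rules$element[ri] %in% c("N", "O")) criteria$d_max_no
                else criteria$d_max_sc
        if (d > dmax) next
        day <- oracle_angle(dpos, apos, ypos)
        if (day < criteria$angle_min || day > criteria$angle_max) next
        ok <- FALSE
        for (an in ante) {
          xpos <- xyz_of(res, an)
          if (is.null(xpos)) next
          xda <- oracle_angle(xpos, dpos, apos)
          if (xda >= criteria$angle_min && xda <= criteria$angle_max) {
            ok <- TRUE
            break
          }
        }
        if (ok) {
          cat_lab <- switch(rules$class[ri],
                            backbone_carbon = "BB_CH",
                            sidechain_polar = "SC_H",
                            sidechain_carbon = "SC_CH")
          keys <- c(keys, paste(resid, rules$atom[ri], acc$atom, cat_lab,
                                round(d, 6)))
        }
      }
    }
    charged <- if (resname == "ARG") c("NH1", "NH2", "NE")
               else if (resname == "LYS") "NZ" else NULL
    if (!is.null(charged)) {
      for (acc in acc_def) {
        apos <- xyz_of(heme, acc$atom)
        if (is.null(apos)) next
        best_d <- Inf
        best_n <- NA_character_
        for (nm in charged) {
          npos <- xyz_of(res, nm)
          if (is.null(npos)) next
          d <- sqrt(sum((npos - apos)^2))
          if (d < best_d) {
            best_d <- d
            best_n <- nm
          }
        }
        if (is.finite(best_d) && best_d <= criteria$d_max_salt) {
          keys <- c(keys, paste(resid, best_n, acc$atom, "SC_SB",
                                round(best_d, 6)))
        }
      }
    }
  }
  sort(keys)
}

scan_frame_keys <- function(frame, ...) {
  ev <- scan_frame(frame, ...)
  if (nrow(ev) == 0L) return(character())
  sort(paste(ev$resseq, ev$donor_atom, ev$acceptor_atom, ev$category,
             round(ev$d, 6)))
}

# A frame with a full two-propionate heme and randomly placed small
# residues of assorted donor types, positioned so that events straddle
# every cutoff.
random_unit <- function() {
  v <- stats::rnorm(3L)
  v / sqrt(sum(v^2))
}

random_small_frame <- function() {
  heme <- data.frame(
    serial = 9001:9006,
    name = c("CGA", "O1A", "O2A", "CGD", "O1D", "O2D"),
    element = c("C", "O", "O", "C", "O", "O"),
    resname = "HEM", chain = "A", resseq = 500L,
    x = c(-1.30, 0, -1.98, 8.70, 10.0, 8.02),
    y = c(0, 0, 1.05, 0, 0, -1.05),
    z = 0
  )
  templates <- list(
    GLY = c("N", "CA", "C"),
    SER = c("CA", "CB", "OG"),
    ALA = c("N", "CA", "CB"),
    THR = c("CA", "CB", "OG1"),
    LYS = c("CE", "NZ"),
    ARG = c("CD", "CZ", "NE", "NH1", "NH2")
  )
  elements <- function(nms) {
    ifelse(startsWith(nms, "N"), "N",
           ifelse(startsWith(nms, "O"), "O",
                  ifelse(startsWith(nms, "S"), "S", "C")))
  }
  n_res <- sample(1:4, 1L)
  rows <- list(heme)
  for (i in seq_len(n_res)) {
    resname <- sample(names(templates), 1L)
    nms <- templates[[resname]]
    anchor_acc <- if (stats::runif(1L) < 0.5) c(0, 0, 0) else c(10, 0, 0)
    center <- anchor_acc + stats::runif(1L, 2.2, 7.0) * random_unit()
    xyz <- t(vapply(seq_along(nms), function(k) {
      center + stats::runif(1L, 0, 1.6) * random_unit()
    }, numeric(3L)))
    rows[[i + 1L]] <- data.frame(
      serial = 100L * i + seq_along(nms),
      name = nms, element = elements(nms),
      resname = resname, chain = "A", resseq = 100L + i,
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
  }
  new_structure(do.call(rbind, rows), "random test frame")
}

# Minimal single-donor frame builder for the detection unit tests: one
# donor atom at a prescribed distance/angle geometry from O1A.
frame_with_donor <- function(resname, atom_names, donor_atom, d,
                             angle_xda = 120, angle_day = 120,
                             bond = 1.5) {
  day <- angle_day * pi / 180
  xda <- angle_xda * pi / 180
  u <- c(-cos(day), sin(day), 0)
  dpos <- d * u
  v <- -u
  p <- c(-v[2L], v[1L], 0)
  xpos <- dpos + bond * (cos(xda) * v + sin(xda) * p)
  extra <- xpos + bond * u
  pos <- rbind(dpos, xpos, extra)[seq_along(atom_names), , drop = FALSE]
  elements <- ifelse(startsWith(atom_names, "N"), "N",
                     ifelse(startsWith(atom_names, "O"), "O",
                            ifelse(startsWith(atom_names, "S"), "S", "C")))
  heme <- data.frame(
    serial = 9001:9002, name = c("CGA", "O1A"), element = c("C", "O"),
    resname = "HEM", chain = "A", resseq = 500L,
    x = c(-1.3, 0), y = c(0, 0), z = c(0, 0))
  res <- data.frame(
    serial = seq_along(atom_names), name = atom_names, element = elements,
    resname = resname, chain = "A", resseq = 181L,
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L])
  new_structure(rbind(heme, res), "unit-test frame")
}
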