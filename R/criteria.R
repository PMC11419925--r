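#' Geometric criteria for non-bond interaction detection
#'
#' Distance and angle windows for (carbon) hydrogen bonds and salt bridges
#' between heme propionate carboxylates and residue donors. Defaults are
#' the published cutoffs: d <= 3.4 Å for nitrogen/oxygen donors, d <= 3.8 Å
#' for sulfur or carbon donors, both X-D-A and D-A-Y angles in 90-180
#' degrees, and d <= 5.6 Å for Arg/Lys salt bridges (no angle condition).
#' Hydrogen positions are never required: all criteria act on heavy atoms.
#'
#' @param d_max_no distance cutoff (Å) for N/O donors.
#' @param d_max_sc distance cutoff (Å) for S/C donors.
#' @param d_max_salt salt-bridge cutoff (Å), Arg/Lys charged N to
#'   carboxylate O.
#' @param angle_min,angle_max angle window (degrees) applied to both the
#'   X-D-A angle at the donor and the D-A-Y angle at the acceptor.
#' @return Object of class `geometric_criteria`.
#' @export
geometric_criteria <- function(d_max_no = 3.4, d_max_sc = 3.8,
                               d_max_salt = 5.6,
                               angle_min = 90, angle_max = 180) {
  stopifnot(
    d_max_no > 0, d_max_no <= d_max_sc, d_max_sc <= d_max_salt,
    angle_min >= 0, angle_min < angle_max, angle_max <= 180
  )
  structure(list(d_max_no = d_max_no, d_max_sc = d_max_sc,
                 d_max_salt = d_max_salt,
                 angle_min = angle_min, angle_max = angle_max),
            class = "geometric_criteria")
}

#' @export
print.geometric_criteria <- function(x, ...) {
  cat(sprintf(paste0("<geometric_criteria> d<=%.1f A (N/O), d<=%.1f A (S/C),",
                     " salt bridge d<=%.1f A, angles %g-%g deg\n"),
              x$d_max_no, x$d_max_sc, x$d_max_salt, x$angle_min, x$angle_max))
  invisible(x)
}

#' Default donor dictionary
#'
#' Which heavy atoms of each residue act as interaction donors, their
#' element, class, and the bonded antecedent atoms usable as X in the
#' X-D-A angle. The backbone donor is the Cα of every residue (a carbon
#' donor, hence the relaxed 3.8 Å cutoff); sidechain polar donors are the
#' standard N/O hydrogen-bond donors; Cys SG is a sulfur donor; and the Cβ
#' of every residue bearing one is a sidechain carbon donor. Shipped as an
#' editable table so a curated donor list can be substituted.
#'
#' @return data.frame with columns `resname` (or `"*"` for every residue),
#'   `atom`, `element`, `class` (`backbone_carbon`, `sidechain_polar`,
#'   `sidechain_carbon`), `antecedents` (comma-separated atom names).
#' @export
default_donor_rules <- function() {
  rules <- rbind(
    data.frame(resname = "*", atom = "CA", element = "C",
               class = "backbone_carbon", antecedents = "N,C,CB"),
    data.frame(
      resname = c("SER", "THR", "TYR", "ASN", "GLN", "HIS", "HIS", "TRP",
                  "ARG", "ARG", "ARG", "LYS"),
      atom    = c("OG", "OG1", "OH", "ND2", "NE2", "ND1", "NE2", "NE1",
                  "NE", "NH1", "NH2", "NZ"),
      element = c("O", "O", "O", "N", "N", "N", "N", "N", "N", "N", "N", "N"),
      class = "sidechain_polar",
      antecedents = c("CB", "CB", "CZ", "CG", "CD", "CG,CE1", "CD2,CE1",
                      "CD1,CE2", "CD,CZ", "CZ", "CZ", "CE")
    ),
    data.frame(resname = "CYS", atom = "SG", element = "S",
               class = "sidechain_carbon", antecedents = "CB"),
    data.frame(resname = "*", atom = "CB", element = "C",
               class = "sidechain_carbon", antecedents = "CA")
  )
  rownames(rules) <- NULL
  rules
}

#' Default heme propionate acceptor set
#'
#' The four carboxylate oxygens of heme propionates A and D, each with its
#' carboxylate carbon as the Y antecedent of the D-A-Y angle. Restrict to
#' one propionate with `groups`.
#'
#' @param groups propionate group ids to include, subset of `c("A", "D")`.
#' @param heme_resname residue name of the heme group.
#' @return data.frame with columns `group`, `atom`, `antecedent`, `resname`.
#' @export
default_acceptors <- function(groups = c("A", "D"), heme_resname = "HEM") {
  acc <- data.frame(
    group = c("A", "A", "D", "D"),
    atom = c("O1A", "O2A", "O1D", "O2D"),
    antecedent = c("CGA", "CGA", "CGD", "CGD"),
    resname = heme_resname
  )
  acc[acc$group %in% groups, , drop = FALSE]
}

# Charged-group nitrogens defining Arg/Lys salt-bridge donors.
salt_bridge_atoms <- function() {
  list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ")
}

#' Read / write an interaction configuration file
#'
#' A YAML file with optional keys `criteria` (fields of
#' [geometric_criteria()]), `donors` (rows of the donor dictionary),
#' `acceptors` (`groups`, `heme_resname`), and `frequency_mode`. Any key
#' omitted falls back to the package defaults, so an empty file reproduces
#' the published cutoffs exactly.
#'
#' @param path path to a YAML config file.
#' @return list with `criteria`, `donors`, `acceptors`, `frequency_mode`.
#' @export
read_interaction_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  crit <- do.call(geometric_criteria, cfg$criteria %||% list())
  donors <- if (is.null(cfg$donors)) default_donor_rules() else {
    do.call(rbind, lapply(cfg$donors, as.data.frame))
  }
  acc_args <- cfg$acceptors %||% list()
  acceptors <- do.call(default_acceptors, acc_args)
  list(criteria = crit, donors = donors, acceptors = acceptors,
       frequency_mode = cfg$frequency_mode %||% "frame_fraction")
}

#' @rdname read_interaction_config
#' @param config a list as returned by [read_interaction_config()].
#' @export
write_interaction_config <- function(config, path) {
  out <- list(
    criteria = unclass(config$criteria),
    donors = config$donors,
    acceptors = list(groups = unique(config$acceptors$group),
                     heme_resname = config$acceptors$resname[1L]),
    frequency_mode = config$frequency_mode
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
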