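# Donor archetypes used by the pocket generator. Each is a minimal residue
# carrying one donor of a single category plus the antecedent chain needed
# for the X-D-A angle. The in-window distance/angle sub-windows are chosen
# so that, given the retreat-type construction below, antecedent atoms can
# never themselves fall inside a detection cutoff (e.g. a polar donor at
# d >= 2.85 with X-D-A >= 130 deg keeps its C-beta > 3.9 A from the
# acceptor, clear of the 3.8 A carbon cutoff).
pocket_archetypes <- function() {
  list(
    backbone = list(resname = "GLY", donor = "CA", element = "C",
                    ante = "N", extra = "C", bond = 1.45,
                    category = "BB_CH", d_default = 3.5,
                    d_window = c(3.0, 3.79), d_out = 6.5),
    polar = list(resname = "SER", donor = "OG", element = "O",
                 ante = "CB", extra = "CA", bond = 1.43,
                 category = "SC_H", d_default = 3.0,
                 d_window = c(2.85, 3.39), d_out = 6.5),
    carbon = list(resname = "ALA", donor = "CB", element = "C",
                  ante = "CA", extra = "N", bond = 1.52,
                  category = "SC_CH", d_default = 3.5,
                  d_window = c(3.0, 3.79), d_out = 6.5),
    saltbridge = list(resname = "LYS", donor = "NZ", element = "N",
                      ante = "CE", extra = "CD", bond = 1.49,
                      category = "SC_SB", d_default = 4.5,
                      d_window = c(3.45, 5.59), d_out = 7.0)
  )
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# Place a donor triad (donor, antecedent X, one further chain atom) at
# distance d from the acceptor at the origin, with prescribed D-A-Y and
# X-D-A angles and azimuth phi about the acceptor-Y axis. Y sits along
# -x, so donors retreat into the +x half-space.
place_donor <- function(d, angle_day, angle_xda, phi, bond) {
  day <- angle_day * pi / 180
  xda <- angle_xda * pi / 180
  u <- c(-cos(day), sin(day) * cos(phi), sin(day) * sin(phi))
  donor <- d * u
  v <- -u  # donor -> acceptor
  p <- c(0, -v[3L], v[2L])
  if (sum(p^2) < 1e-12) p <- c(0, 1, 0)
  p <- p / sqrt(sum(p^2))
  x_atom <- donor + bond * (cos(xda) * v + sin(xda) * p)
  extra <- x_atom + bond * u
  rbind(donor = donor, x = x_atom, extra = extra)
}

minimal_heme_atoms <- function() {
  # one carboxylate oxygen per propionate: keeps every generated event
  # attributable to exactly one (donor, acceptor) pair
  data.frame(
    serial = 9001:9004,
    name = c("CGA", "O1A", "CGD", "O1D"),
    element = c("C", "O", "C", "O"),
    resname = "HEM", chain = "A", resseq = 500L,
    x = c(-1.3, 0, 20.0, 21.3), y = c(0, 0, 20.0, 20.0), z = c(0, 0, 0, 0)
  )
}

#' Generate a synthetic heme-pocket trajectory with known ground truth
#'
#' Builds a multi-model trajectory containing a minimal heme (one
#' carboxylate oxygen and its carbon per propionate) and one minimal donor
#' residue per requested donor. In each frame each donor is, with
#' probability equal to its occupancy, placed inside its detection window
#' (distance and both angles solved exactly, then jittered within the
#' window) and otherwise well outside every cutoff. The returned ground
#' truth records the realised per-frame placements, so scanner recovery
#' can be asserted exactly in the noiseless limit and binomially under
#' occupancy sampling.
#'
#' @param donors data.frame with columns `kind` (one of `"backbone"`,
#'   `"polar"`, `"carbon"`, `"saltbridge"`) and `occupancy` (in \[0, 1\]),
#'   optionally `distance` (nominal donor-acceptor distance, Å).
#' @param n_frames number of frames (>= 1).
#' @param jitter_d Gaussian jitter sd on the in-window distance, Å.
#' @param jitter_angle Gaussian jitter sd on the in-window angles, degrees.
#' @param angle_day,angle_xda nominal D-A-Y and X-D-A angles, degrees.
#' @param seed integer seed; same seed gives byte-identical output.
#' @return list with `trajectory` (a `pdb_trajectory`) and `truth`: a
#'   data.frame per donor (`resseq`, `resname`, `kind`, `category`,
#'   `occupancy`, `distance_nominal`, `occupancy_realized`,
#'   `mean_distance_realized`) plus attributes `n_frames` and `seed`.
#' @examples
#' pocket <- make_pocket_trajectory(n_frames = 10, seed = 1)
#' ev <- scan_trajectory(pocket$trajectory)
#' aggregate_events(ev)
#' @export
make_pocket_trajectory <- function(donors = data.frame(
                                     kind = c("backbone", "polar",
                                              "saltbridge"),
                                     occupancy = c(0.7, 0.5, 0.3)),
                                   n_frames = 100L,
                                   jitter_d = 0.05, jitter_angle = 3,
                                   angle_day = 135, angle_xda = 150,
                                   seed = 1L) {
  arch <- pocket_archetypes()
  stopifnot(all(donors$kind %in% names(arch)),
            all(donors$occupancy >= 0), all(donors$occupancy <= 1),
            n_frames >= 1L, jitter_d >= 0, jitter_angle >= 0)
  nd <- nrow(donors)
  set.seed(seed)

  ang_window <- c(130, 170)
  day_window <- c(95, 175)
  if (angle_xda < ang_window[1L] || angle_xda > ang_window[2L] ||
      angle_day < day_window[1L] || angle_day > day_window[2L]) {
    stop("nominal angles outside the generator's safe windows (",
         "X-D-A in [130, 170], D-A-Y in [95, 175])")
  }

  heme <- minimal_heme_atoms()
  phis <- seq(0, by = 0.35, length.out = nd)
  frames <- vector("list", n_frames)
  placed <- matrix(FALSE, n_frames, nd)
  dists <- matrix(NA_real_, n_frames, nd)

  specs <- vector("list", nd)
  for (j in seq_len(nd)) {
    a <- arch[[donors$kind[j]]]
    d_nom <- if (!is.null(donors$distance) && is.finite(donors$distance[j])) {
      donors$distance[j]
    } else {
      a$d_default
    }
    if (d_nom < a$d_window[1L] || d_nom > a$d_window[2L]) {
      stop("infeasible nominal distance ", d_nom, " for kind '",
           donors$kind[j], "' (window ", a$d_window[1L], "-",
           a$d_window[2L], " A)")
    }
    specs[[j]] <- c(a, list(d_nom = d_nom, resseq = 180L + j))
  }

  for (f in seq_len(n_frames)) {
    rows <- list(heme)
    for (j in seq_len(nd)) {
      a <- specs[[j]]
      inside <- stats::runif(1L) < donors$occupancy[j]
      placed[f, j] <- inside
      if (inside) {
        d <- clamp(a$d_nom + stats::rnorm(1L, 0, jitter_d),
                   a$d_window[1L], a$d_window[2L])
        xda <- clamp(angle_xda + stats::rnorm(1L, 0, jitter_angle),
                     ang_window[1L], ang_window[2L])
        day <- clamp(angle_day + stats::rnorm(1L, 0, jitter_angle),
                     day_window[1L], day_window[2L])
        dists[f, j] <- d
      } else {
        d <- a$d_out
        xda <- angle_xda
        day <- angle_day
      }
      xyz <- place_donor(d, day, xda, phis[j], a$bond)
      rows[[j + 1L]] <- data.frame(
        serial = 100L * j + 1:3,
        name = c(a$donor, a$ante, a$extra),
        element = c(a$element, substr(a$ante, 1L, 1L),
                    substr(a$extra, 1L, 1L)),
        resname = a$resname, chain = "A", resseq = a$resseq,
        x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
    }
    frames[[f]] <- new_structure(do.call(rbind, rows),
                                 "synthetic pocket numbering")
  }

  truth <- data.frame(
    resseq = vapply(specs, `[[`, integer(1L), "resseq"),
    resname = vapply(specs, `[[`, character(1L), "resname"),
    kind = donors$kind,
    category = vapply(specs, `[[`, character(1L), "category"),
    occupancy = donors$occupancy,
    distance_nominal = vapply(specs, `[[`, numeric(1L), "d_nom"),
    occupancy_realized = colMeans(placed),
    mean_distance_realized = colMeans(dists, na.rm = TRUE)
  )
  attr(truth, "n_frames") <- n_frames
  attr(truth, "seed") <- seed
  list(trajectory = as_trajectory(frames), truth = truth)
}

#' Generate a synthetic variant panel obeying a known linear Tm law
#'
#' Draws per-variant interaction summaries from plausible ranges (the
#' weighted backbone term stays within 0-0.75 and the sidechain
#' hydrogen-bond term within 0-0.35, the spans seen in practice), computes
#' the true index with the supplied weights, and sets
#' `Tm = a * index + b + N(0, sigma^2)`.
#'
#' @param aa181 residue identities at the contact position (>= 3 distinct).
#' @param weights true [hemelock_weights()].
#' @param a,b true linear coefficients (°C per index unit; °C).
#' @param sigma Tm noise sd, °C.
#' @param seed integer seed.
#' @return list with `panel` (a variant panel data.frame including
#'   `Tm_obs`) and `truth` (`weights`, `a`, `b`, `sigma`, `index`).
#' @export
make_variant_panel <- function(aa181 = c("G", "A", "S", "C", "T", "V",
                                         "L", "M", "F", "Y", "W", "I"),
                               weights = hemelock_weights(),
                               a = 4.995, b = 42.86, sigma = 0,
                               seed = 1L) {
  stopifnot(length(unique(aa181)) >= 3L, sigma >= 0)
  aa3 <- canonical_aa(aa181)
  n <- length(aa3)
  set.seed(seed)
  panel <- data.frame(
    variant = paste0("V181", substr(aa181, 1L, 1L)),
    aa181 = aa3,
    BBCHI = stats::runif(n, 0, 0.75), BBCHD = stats::runif(n, 3.3, 3.8),
    SCHI = stats::runif(n, 0, 1), SCHD = stats::runif(n, 2.8, 3.4),
    SCCHI = stats::runif(n, 0, 0.5), SCCHD = stats::runif(n, 3.0, 3.8),
    SCSBI = stats::runif(n, 0, 0.5), SCSBD = stats::runif(n, 4.0, 5.5)
  )
  idx <- panel_index(panel, weights)
  panel$Tm_obs <- a * idx + b + stats::rnorm(n, 0, sigma)
  list(panel = panel,
       truth = list(weights = weights, a = a, b = b, sigma = sigma,
                    index = idx, seed = seed))
}

#' Generate a synthetic thermal-inactivation time series
#'
#' Exponential activity decay sampled at the stated times, with optional
#' Gaussian noise on the log scale. The default decay constant corresponds
#' to a 19.07-minute half-life, a typical wild-type value under heat
#' stress.
#'
#' @param kd true deactivation constant, min^-1.
#' @param times sampling times, minutes.
#' @param sigma_ln noise sd on ln(activity).
#' @param seed integer seed.
#' @return list with `series` (data.frame `time_min`, `activity`) and
#'   `truth` (`kd`, `t_half`, `sigma_ln`).
#' @export
make_decay_series <- function(kd = log(2) / 19.07,
                              times = seq(0, 300, by = 30),
                              sigma_ln = 0, seed = 1L) {
  stopifnot(kd > 0, all(times >= 0), sigma_ln >= 0)
  set.seed(seed)
  lact <- -kd * times + stats::rnorm(length(times), 0, sigma_ln)
  list(series = data.frame(time_min = times, activity = exp(lact)),
       truth = list(kd = kd, t_half = log(2) / kd, sigma_ln = sigma_ln))
}

#' Generate a synthetic Michaelis-Menten saturation series
#'
#' Rates on an 8-point substrate grid spanning 50-2000 µM (the assayed
#' span), with optional multiplicative Gaussian noise and replicates.
#'
#' @param vmax,km true parameters (rate unit; µM).
#' @param conc_uM substrate concentration grid, µM.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param replicates replicate rates per concentration.
#' @param seed integer seed.
#' @return list with `series` (data.frame `conc_uM`, `rate`) and `truth`.
#' @export
make_saturation_series <- function(vmax = 10, km = 200,
                                   conc_uM = c(50, 100, 200, 400, 800,
                                               1200, 1600, 2000),
                                   cv = 0, replicates = 1L, seed = 1L) {
  stopifnot(vmax > 0, km > 0, all(conc_uM > 0), cv >= 0, replicates >= 1L)
  set.seed(seed)
  s <- rep(conc_uM, each = replicates)
  v <- vmax * s / (km + s) * (1 + stats::rnorm(length(s), 0, cv))
  list(series = data.frame(conc_uM = s, rate = pmax(v, 0)),
       truth = list(vmax = vmax, km = km, cv = cv))
}
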