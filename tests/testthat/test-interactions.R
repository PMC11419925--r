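test_that("hydrogen-bond detection honours distance and angle windows", {
  crit <- geometric_criteria()
  # polar N donor inside every threshold
  f <- frame_with_donor("ASN", c("ND2", "CG"), "ND2", d = 3.0,
                        angle_xda = 120, angle_day = 120)
  ev <- scan_frame(f)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$category, "SC_H")
  expect_equal(ev$d, 3.0, tolerance = 1e-9)
  # same donor just past the 3.4 A nitrogen/oxygen cutoff
  f <- frame_with_donor("ASN", c("ND2", "CG"), "ND2", d = 3.5)
  expect_equal(nrow(scan_frame(f)), 0L)
  # backbone C-alpha at 3.6 A passes under the relaxed 3.8 A carbon cutoff
  f <- frame_with_donor("GLY", c("CA", "N", "C"), "CA", d = 3.6,
                        angle_xda = 150, angle_day = 100)
  ev <- scan_frame(f)
  expect_equal(ev$category, "BB_CH")
  expect_equal(ev$d, 3.6, tolerance = 1e-9)
  # oxygen donor with the only antecedent at X-D-A = 85 degrees fails
  f <- frame_with_donor("TYR", c("OH", "CZ"), "OH", d = 3.0,
                        angle_xda = 85, angle_day = 120)
  expect_equal(nrow(scan_frame(f)), 0L)
  # D-A-Y outside the window also fails
  f <- frame_with_donor("TYR", c("OH", "CZ"), "OH", d = 3.0,
                        angle_xda = 120, angle_day = 80)
  expect_equal(nrow(scan_frame(f)), 0L)
  # sulfur donor gets the 3.8 A cutoff and the carbon-hydrogen-bond class
  f <- frame_with_donor("CYS", c("SG", "CB", "CA"), "SG", d = 3.6,
                        angle_xda = 150, angle_day = 120, bond = 1.8)
  ev <- scan_frame(f)
  expect_equal(ev$category, "SC_CH")
})

test_that("detect_hbond demands antecedent coordinates", {
  donor <- list(xyz = c(3, 0, 0), element = "N", class = "sidechain_polar",
                antecedents = matrix(numeric(), 0L, 3L))
  acceptor <- list(xyz = c(0, 0, 0), y_xyz = c(-1.3, 0, 0))
  expect_error(detect_hbond(donor, acceptor), "no antecedent")
  donor$antecedents <- matrix(c(NA_real_, 0, 0), 1L,
                              dimnames = list("CG", NULL))
  expect_error(detect_hbond(donor, acceptor), "CG")
})

test_that("salt bridges use the minimum charged-nitrogen distance", {
  crit <- geometric_criteria()
  acceptor <- list(xyz = c(0, 0, 0))
  lys <- data.frame(name = c("CE", "NZ"), resname = "LYS",
                    x = c(6.0, 5.0), y = 0, z = 0)
  hit <- detect_salt_bridge(lys, acceptor, crit)
  expect_equal(hit$category, "SC_SB")
  expect_equal(hit$d, 5.0)
  expect_equal(hit$donor_atom, "NZ")
  arg <- data.frame(name = c("NH1", "NH2", "NE"), resname = "ARG",
                    x = c(5.7, 6.0, 6.2), y = 0, z = 0)
  expect_null(detect_salt_bridge(arg, acceptor, crit))
  arg$x[2L] <- 4.9
  expect_equal(detect_salt_bridge(arg, acceptor, crit)$donor_atom, "NH2")
  gly <- data.frame(name = "CA", resname = "GLY", x = 3, y = 0, z = 0)
  expect_error(detect_salt_bridge(gly, acceptor, crit), "ARG or LYS")
})

test_that("a short Lys contact is both salt bridge and hydrogen bond", {
  f <- frame_with_donor("LYS", c("NZ", "CE"), "NZ", d = 3.2,
                        angle_xda = 120, angle_day = 120)
  ev <- scan_frame(f)
  expect_setequal(ev$category, c("SC_H", "SC_SB"))
  expect_equal(ev$d, c(3.2, 3.2), tolerance = 1e-9)
  # the salt-bridge-priority mode keeps only the salt bridge
  ev2 <- scan_frame(f, salt_bridge_mode = "priority")
  expect_equal(ev2$category, "SC_SB")
})

test_that("scan_frame covers the whole frame and requires a heme", {
  f <- frame_with_donor("ALA", c("CB", "CA", "N"), "CB", d = 3.7,
                        angle_xda = 150, angle_day = 120)
  ev <- scan_frame(f)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$category, "SC_CH")
  far <- frame_with_donor("ASN", c("ND2", "CG"), "ND2", d = 6.5)
  expect_equal(nrow(scan_frame(far)), 0L)
  no_heme <- far
  no_heme$atoms <- no_heme$atoms[no_heme$atoms$resname != "HEM", ]
  expect_error(scan_frame(no_heme), "no heme")
})

test_that("scan_frame equals the exhaustive all-pairs oracle", {
  set.seed(501)
  for (k in 1:60) {
    f <- random_small_frame()
    expect_identical(scan_frame_keys(f), oracle_scan_keys(f))
  }
})

test_that("loosening cutoffs never removes events, tightening never adds", {
  set.seed(502)
  base <- geometric_criteria()
  loose <- geometric_criteria(d_max_no = 3.8, d_max_sc = 4.2,
                              d_max_salt = 6.0, angle_min = 80)
  tight <- geometric_criteria(d_max_no = 3.0, d_max_sc = 3.4,
                              d_max_salt = 5.0, angle_min = 100)
  for (k in 1:25) {
    f <- random_small_frame()
    kb <- scan_frame_keys(f, criteria = base)
    kl <- scan_frame_keys(f, criteria = loose)
    kt <- scan_frame_keys(f, criteria = tight)
    expect_true(all(kb %in% kl))
    expect_true(all(kt %in% kb))
  }
})

test_that("criteria validate their ordering and default to the printed cutoffs", {
  crit <- geometric_criteria()
  expect_equal(crit$d_max_no, 3.4)
  expect_equal(crit$d_max_sc, 3.8)
  expect_equal(crit$d_max_salt, 5.6)
  expect_equal(c(crit$angle_min, crit$angle_max), c(90, 180))
  expect_error(geometric_criteria(d_max_no = 4.0, d_max_sc = 3.8))
  expect_error(geometric_criteria(angle_min = 120, angle_max = 100))
  # an empty config file falls back to the same defaults
  tf <- tempfile(fileext = ".yaml")
  writeLines("", tf)
  cfg <- read_interaction_config(tf)
  expect_equal(unclass(cfg$criteria), unclass(crit))
  expect_equal(cfg$frequency_mode, "frame_fraction")
  # and a config round-trips
  out <- tempfile(fileext = ".yaml")
  write_interaction_config(cfg, out)
  cfg2 <- read_interaction_config(out)
  expect_equal(unclass(cfg2$criteria), unclass(cfg$criteria))
})

test_that("aggregation computes frame fractions and mean distances", {
  # synthetic event table: BB_CH in 7 of 10 frames, two known distances
  ev <- data.frame(
    frame = c(1:7, 3L, 8L),
    chain = "A", resseq = c(rep(181L, 7L), 181L, 182L),
    resname = c(rep("GLY", 7L), "GLY", "SER"),
    donor_atom = c(rep("CA", 7L), "CA", "OG"),
    acceptor_group = "A",
    acceptor_atom = c(rep("O1A", 7L), "O2A", "O1A"),
    category = c(rep("BB_CH", 7L), "BB_CH", "SC_H"),
    d = c(3.0, 3.4, rep(3.2, 5L), 3.2, 3.1),
    angle_xda = 120, angle_day = 120
  )
  agg <- aggregate_events(ev, n_frames = 10L)
  bb <- agg[agg$category == "BB_CH", ]
  expect_equal(bb$I, 0.7)
  expect_equal(bb$D, mean(c(3.0, 3.4, rep(3.2, 5L), 3.2)))
  expect_equal(bb$n_events, 8L)
  # events-per-frame mode counts multiplicity, so I can exceed the fraction
  epf <- aggregate_events(ev, n_frames = 10L, mode = "events_per_frame")
  expect_equal(epf[epf$category == "BB_CH", "I"], 0.8)
  expect_true(all(epf$I >= agg$I))
  # frame-fraction frequencies are proportions
  expect_true(all(agg$I >= 0 & agg$I <= 1))
  # aggregation is order-independent
  shuffled <- ev[sample(nrow(ev)), ]
  expect_equal(aggregate_events(shuffled, n_frames = 10L), agg)
  # distance pair example
  expect_equal(agg[agg$category == "SC_H", "D"], 3.1)
})

test_that("per-residue summaries carry the zero-frequency convention", {
  ev <- data.frame(
    frame = 1L, chain = "A", resseq = 181L, resname = "GLY",
    donor_atom = "CA", acceptor_group = "A", acceptor_atom = "O1A",
    category = "BB_CH", d = 3.0, angle_xda = 120, angle_day = 120
  )
  s <- summary_for_residue(aggregate_events(ev, n_frames = 2L), 181L)
  expect_equal(s$BBCHI, 0.5)
  expect_equal(s$BBCHD, 3.0)
  expect_equal(s$SCHI, 0)
  expect_true(is.na(s$SCHD))
  expect_error(interaction_summary(BBCHI = -0.1), "negative")
  expect_error(interaction_summary(BBCHI = 0.5, BBCHD = NA), "positive")
})
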