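two_atom_frame <- function(d) {
  atoms <- data.frame(
    serial = 1:2, name = c("CA", "O1A"), element = c("C", "O"),
    resname = c("GLY", "HEM"), chain = "A", resseq = c(181L, 500L),
    x = c(0, d), y = 0, z = 0
  )
  new_structure(atoms)
}

square_frame <- function() {
  atoms <- data.frame(
    serial = 1:4, name = "CA", element = "C", resname = "GLY", chain = "A",
    resseq = 1:4, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0
  )
  new_structure(atoms)
}

apply_rigid <- function(s, rot, shift) {
  xyz <- as.matrix(s$atoms[c("x", "y", "z")]) %*% t(rot)
  s$atoms$x <- xyz[, 1L] + shift[1L]
  s$atoms$y <- xyz[, 2L] + shift[2L]
  s$atoms$z <- xyz[, 3L] + shift[3L]
  s
}

random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

test_that("rmsd is zero for identical frames and exact for a known shift", {
  s <- square_frame()
  sel <- select_atoms(s)
  expect_equal(rmsd(s, s, sel), 0)
  moved <- s
  moved$atoms$x[1L] <- moved$atoms$x[1L] + 2  # one of 4 atoms off by 2 A
  expect_equal(rmsd(moved, s, sel, superpose = FALSE), 1.0)
  expect_error(rmsd(s, s, integer()), "empty selection")
})

test_that("superposition removes translations and recovers rotations", {
  s <- square_frame()
  sel <- select_atoms(s)
  shifted <- apply_rigid(s, diag(3L), c(1, 2, 3))
  expect_equal(rmsd(shifted, s, sel, superpose = TRUE), 0, tolerance = 1e-10)
  fit <- kabsch_superpose(s, s, sel)
  expect_equal(fit$rotation, diag(3L), tolerance = 1e-10)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-10)
  rot90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3L, 3L, byrow = TRUE)
  rotated <- apply_rigid(s, rot90, c(0, 0, 0))
  fit <- kabsch_superpose(rotated, s, sel)
  expect_equal(rmsd(rotated, s, sel, superpose = TRUE), 0, tolerance = 1e-10)
  expect_equal(fit$rotation, t(rot90), tolerance = 1e-10)
})

test_that("rmsd under superposition is invariant to random rigid motions", {
  set.seed(401)
  pocket <- make_pocket_trajectory(n_frames = 1L, seed = 5L)
  s <- get_frame(pocket$trajectory, 1L)
  sel <- select_atoms(s)
  for (k in 1:10) {
    moved <- apply_rigid(s, random_rotation(), stats::rnorm(3L, sd = 5))
    expect_lt(rmsd(moved, s, sel, superpose = TRUE), 1e-8)
    # both structures under one common rigid motion, superpose on
    rot <- random_rotation()
    shift <- stats::rnorm(3L)
    perturbed <- s
    perturbed$atoms$x <- perturbed$atoms$x + stats::rnorm(nrow(s$atoms), sd = 0.3)
    r0 <- rmsd(perturbed, s, sel, superpose = TRUE)
    r1 <- rmsd(apply_rigid(perturbed, rot, shift), apply_rigid(s, rot, shift),
               sel, superpose = TRUE)
    expect_equal(r0, r1, tolerance = 1e-8)
    expect_equal(rmsd(perturbed, s, sel), rmsd(s, perturbed, sel))
  }
})

test_that("agreement with the reference superposition implementation", {
  set.seed(77)
  pocket <- make_pocket_trajectory(n_frames = 1L, seed = 6L)
  s <- get_frame(pocket$trajectory, 1L)
  moved <- apply_rigid(s, random_rotation(), c(2, -1, 4))
  moved$atoms$x <- moved$atoms$x + stats::rnorm(nrow(s$atoms), sd = 0.2)
  sel <- select_atoms(s)
  ours <- rmsd(moved, s, sel, superpose = TRUE)
  ref <- bio3d::rmsd(
    as.vector(t(as.matrix(s$atoms[c("x", "y", "z")]))),
    as.vector(t(as.matrix(moved$atoms[c("x", "y", "z")]))),
    fit = TRUE
  )
  expect_equal(ours, ref, tolerance = 1e-3)  # the reference rounds to 3 dp
})

test_that("degenerate selections are rejected", {
  line <- new_structure(data.frame(
    serial = 1:3, name = "CA", element = "C", resname = "GLY", chain = "A",
    resseq = 1:3, x = c(0, 1, 2), y = 0, z = 0
  ))
  sel <- select_atoms(line)
  expect_error(kabsch_superpose(line, line, sel), "collinear")
  pair <- new_structure(line$atoms[1:2, ])
  expect_error(kabsch_superpose(pair, pair, select_atoms(pair)),
               "at least 3")
})

test_that("distance traces report per-frame values, mean and sd", {
  traj <- as_trajectory(list(two_atom_frame(3), two_atom_frame(5)))
  dt <- distance_trace(traj, list(name = "CA"), list(name = "O1A"))
  expect_equal(dt$trace$distance, c(3, 5))
  expect_equal(dt$mean, 4.0)
  expect_equal(dt$sd, stats::sd(c(3, 5)))
  expect_false(dt$degenerate)
  single <- distance_trace(as_trajectory(list(two_atom_frame(3))),
                           list(name = "CA"), list(name = "O1A"))
  expect_equal(single$sd, 0)
  expect_true(single$degenerate)
  expect_error(
    distance_trace(traj, list(name = "CB"), list(name = "O1A")),
    "resolves to 0"
  )
  expect_error(
    distance_trace(traj, list(chain = "A"), list(name = "O1A")),
    "resolves to 2"
  )
})

test_that("a generated distance ensemble recovers its programmed mean", {
  set.seed(402)
  n <- 500L
  frames <- lapply(stats::rnorm(n, 3.5, 0.2), two_atom_frame)
  dt <- distance_trace(as_trajectory(frames), list(name = "CA"),
                       list(name = "O1A"))
  expect_lt(abs(dt$mean - 3.5), 3 * 0.2 / sqrt(n))
  # frame-range restriction honoured, and mean equals a naive recount
  sub <- distance_trace(as_trajectory(frames), list(name = "CA"),
                        list(name = "O1A"), frames = c(101L, 200L))
  naive <- vapply(101:200, function(i) {
    a <- frames[[i]]$atoms
    sqrt(sum((unlist(a[1L, c("x", "y", "z")]) -
              unlist(a[2L, c("x", "y", "z")]))^2))
  }, numeric(1L))
  expect_equal(sub$trace$distance, naive)
  expect_equal(sub$mean, mean(naive))
})

test_that("traces serialise to commented tidy TSV", {
  traj <- as_trajectory(list(two_atom_frame(3), two_atom_frame(5)))
  dt <- distance_trace(traj, list(name = "CA"), list(name = "O1A"))
  tf <- tempfile(fileext = ".tsv")
  write_trace_tsv(dt, tf)
  lines <- readLines(tf)
  expect_true(all(startsWith(lines[1:2], "#")))
  tab <- utils::read.delim(tf, comment.char = "#")
  expect_equal(names(tab), c("frame_index", "time_ns", "value"))
  expect_equal(tab$value, c(3, 5))
})
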