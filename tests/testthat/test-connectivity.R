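# State windows, segmentation, instantaneous phase and PLV.

test_that("state windows land at the protocol positions", {
  rec <- eeg_recording(matrix(0, 1, 500 * 1024), 1024, "Cz")
  w <- extract_state_windows(rec, rest_start = 0, t_light = 300,
                             t_heavy = 400)
  expect_equal(unname(w$VIMS_0), c(1, 60 * 1024))
  expect_equal(unname(w$VIMS_1), c(270 * 1024 + 1, 330 * 1024))
  expect_equal(unname(w$VIMS_2), c(340 * 1024 + 1, 400 * 1024))
  # every window spans exactly 60 s
  for (s in names(w)) expect_equal(unname(diff(w[[s]])) + 1, 60 * 1024)
})

test_that("state windows outside the recording raise errors naming the state", {
  rec <- eeg_recording(matrix(0, 1, 500 * 64), 64, "Cz")
  expect_error(extract_state_windows(rec, 0, t_light = 20, t_heavy = 400),
               "VIMS_1")
  expect_error(extract_state_windows(rec, 0, t_light = 300, t_heavy = 50),
               "VIMS_2")
  expect_message(extract_state_windows(rec, 0, t_light = 300, t_heavy = 310),
                 "overlap")
})

test_that("segmentation yields floor(duration/len) full windows in order", {
  x60 <- matrix(rnorm(2 * 60 * 1024), 2)
  segs <- segment_window(x60, rate = 1024, win_len = 3)
  expect_length(segs, 20L)
  expect_true(all(vapply(segs, ncol, integer(1)) == 3072L))
  expect_equal(segs[[2]], x60[, 3073:6144])
  expect_length(segment_window(matrix(0, 1, 2 * 1024), 1024, 3), 0L)
  segs7 <- segment_window(matrix(rnorm(7 * 10), 1), rate = 10, win_len = 3)
  expect_length(segs7, 2L)
})

test_that("instantaneous phase advances at the tone frequency", {
  rate <- 1024
  t <- seq(0, 3 - 1 / rate, by = 1 / rate)
  x <- rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t))
  ph <- instantaneous_phase(x, rate)$phase
  core <- seq(round(0.1 * ncol(x)), round(0.9 * ncol(x)))
  # unwrapped phase slope = 2*pi*10 rad/s over the central 80%
  unwrapped <- cumsum(c(ph[1, core[1]],
                        (diff(ph[1, core]) + pi) %% (2 * pi) - pi))
  slope <- stats::coef(stats::lm(unwrapped ~ t[core]))[2]
  expect_equal(unname(slope), 2 * pi * 10, tolerance = 0.01)
  # cos leads sin by pi/2 at equal frequency
  dphi <- (ph[2, core] - ph[1, core] + pi) %% (2 * pi) - pi
  expect_true(all(abs(dphi - pi / 2) < 0.02))
})

test_that("an all-zero channel gets zero phase with a warning", {
  x <- rbind(0, sin(2 * pi * 5 * seq(0, 1, by = 1 / 256)))
  expect_warning(ph <- instantaneous_phase(x, 256), "identically zero")
  expect_true(all(ph$phase[1, ] == 0))
})

test_that("PLV analytic cases: identity, constant offset, cancelling phases", {
  set.seed(20)
  ph <- runif(3072, -pi, pi)
  expect_identical(plv_pair(ph, ph), 1)
  expect_equal(plv_pair(ph, ph + 1.23), 1, tolerance = 1e-12)
  alt <- rep(c(0, pi), each = 1536)
  expect_equal(plv_pair(alt, numeric(3072)), 0, tolerance = 1e-12)
  expect_error(plv_pair(ph, ph[-1]), "equal length")
})

test_that("plv_pair matches a brute-force per-sample oracle", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(50:500, 1)
    a <- runif(n, -pi, pi)
    b <- runif(n, -pi, pi)
    # independent oracle: explicit sample loop over Euler terms
    s <- 0
    for (j in seq_len(n)) s <- s + complex(real = cos(a[j] - b[j]),
                                           imaginary = sin(a[j] - b[j]))
    expect_equal(plv_pair(a, b), Mod(s / n), tolerance = 1e-12)
  }
})

test_that("mean PLV of independent uniform phases follows sqrt(pi)/(2 sqrt(N))", {
  set.seed(22)
  n <- 3072
  draws <- 1000
  plvs <- replicate(draws, plv_pair(runif(n, -pi, pi), runif(n, -pi, pi)))
  expect_equal(mean(plvs), sqrt(pi) / (2 * sqrt(n)), tolerance = 0.1)
})

test_that("expected PLV of independent phases scales as 1/sqrt(N)", {
  set.seed(23)
  m <- function(n) mean(replicate(400, plv_pair(runif(n, -pi, pi),
                                                runif(n, -pi, pi))))
  expect_equal(m(256) / m(1024), 2, tolerance = 0.15)
})

test_that("PLV is invariant to amplitude rescaling and common phase offsets", {
  set.seed(24)
  rate <- 256
  t <- seq(0, 2 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 8 * t) + 0.3 * rnorm(length(t))
  y <- sin(2 * pi * 8 * t + 0.7) + 0.3 * rnorm(length(t))
  ph1 <- instantaneous_phase(rbind(x, y), rate)$phase
  ph2 <- instantaneous_phase(rbind(5.7 * x, 0.01 * y), rate)$phase
  expect_equal(plv_pair(ph1[1, ], ph1[2, ]), plv_pair(ph2[1, ], ph2[2, ]),
               tolerance = 1e-10)
  expect_equal(plv_pair(ph1[1, ] + 0.9, ph1[2, ] + 0.9),
               plv_pair(ph1[1, ], ph1[2, ]), tolerance = 1e-12)
})

test_that("PLV matrices are symmetric with unit diagonal and [0,1] entries", {
  set.seed(25)
  for (i in 1:5) {
    ph <- matrix(runif(6 * 300, -pi, pi), 6)
    m <- plv_matrix(ph)
    expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
    expect_equal(unname(diag(m)), rep(1, 6))
    expect_true(all(m >= 0 & m <= 1))
  }
  # identical channels give an all-ones matrix
  ph2 <- matrix(rep(runif(100, -pi, pi), 2), 2, byrow = TRUE)
  expect_equal(unclass(plv_matrix(ph2)), matrix(1, 2, 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  # off-diagonals of independent phases sit near the finite-N floor
  ph3 <- matrix(runif(4 * 3072, -pi, pi), 4)
  m3 <- plv_matrix(ph3)
  expect_lt(max(m3[upper.tri(m3)]), 0.1)
})

test_that("matrix averaging is element-wise with label inheritance", {
  m1 <- plv_matrix(matrix(runif(3 * 200, -pi, pi), 3), band = "gamma",
                   state = "VIMS_0")
  expect_equal(unclass(average_matrices(list(m1, m1))), unclass(m1),
               ignore_attr = TRUE)
  ones <- matrix(1, 3, 3)
  zeros <- diag(3)
  l <- list(structure(ones, class = c("plv_matrix", "matrix"), band = "g",
                      state = "s"),
            structure(zeros, class = c("plv_matrix", "matrix"), band = "g",
                      state = "s"))
  avg <- average_matrices(l)
  expect_equal(avg[1, 2], 0.5)
  expect_equal(attr(avg, "band"), "g")
})

test_that("topology thresholding keeps edges at or above the cutoff", {
  m <- matrix(0.6, 52, 52)
  diag(m) <- 1
  topo <- threshold_topology(m, 0.55)
  expect_equal(nrow(topo), 52 * 51 / 2)
  expect_equal(nrow(threshold_topology(matrix(0.5, 52, 52), 0.55)), 0L)
  m3 <- matrix(1, 3, 3)
  m3[1, 2] <- m3[2, 1] <- 0.9
  m3[1, 3] <- m3[3, 1] <- 0.55
  m3[2, 3] <- m3[3, 2] <- 0.2
  topo3 <- threshold_topology(m3, 0.55)
  expect_equal(nrow(topo3), 2L)       # the boundary value 0.55 is kept
  expect_true(all(topo3$i < topo3$j))
  # proportional mode keeps the strongest fraction instead
  expect_equal(nrow(threshold_topology(m3, 1 / 3, proportional = TRUE)), 1L)
})

test_that("PLV matrices and topologies round-trip through their exports", {
  set.seed(26)
  m <- plv_matrix(matrix(runif(4 * 100, -pi, pi), 4,
                         dimnames = list(c("Fz", "Cz", "Pz", "Oz"), NULL)),
                  band = "alpha", state = "VIMS_1", subject = 3L,
                  segment = 7L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_plv_matrix(m, path)
  back <- read_plv_matrix(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
  expect_equal(attr(back, "band"), "alpha")
  expect_equal(attr(back, "subject"), 3L)
  topo <- threshold_topology(unclass(m), 0.1)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_topology(topo, csv)
  expect_equal(nrow(utils::read.csv(csv)), nrow(topo))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_topology(topo, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(topo))
})
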