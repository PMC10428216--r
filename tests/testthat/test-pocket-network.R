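two_pocket_log <- function(merges, splits, n_frames = 5) {
  new_pocket_event_log(c("A", "B", "C"),
                       matrix(100, n_frames, 3), merges, splits)
}

test_that("event counting preserves ordered pairs exactly", {
  log <- two_pocket_log(
    merges = tibble::tibble(frame = c(1, 2, 3), from = c("A", "A", "B"),
                            to = c("B", "B", "A")),
    splits = tibble::tibble(frame = integer(), from = character(), to = character())
  )
  ms <- events_to_matrices(log)
  expect_identical(ms$alpha["A", "B"], 2L)
  expect_identical(ms$alpha["B", "A"], 1L)
  expect_true(all(ms$beta == 0))
  expect_true(all(diag(ms$alpha) == 0))
})

test_that("unknown pockets and self-pairs are rejected with the frame index", {
  expect_error(
    two_pocket_log(tibble::tibble(frame = 4L, from = "A", to = "Z"),
                   tibble::tibble(frame = integer(), from = character(), to = character())),
    "frame 4", class = "kinoflex_validation_error")
  expect_error(
    two_pocket_log(tibble::tibble(frame = 1L, from = "A", to = "A"),
                   tibble::tibble(frame = integer(), from = character(), to = character())),
    "self-pair", class = "kinoflex_validation_error")
})

test_that("Poisson-generated logs match an independent streaming counter", {
  log <- gen_pocket_events(pocket_sim_spec(pocket_names = c("A", "B", "C"),
                                           n_frames = 400, link_rate = 0.05,
                                           seed = 3))
  ms <- events_to_matrices(log)
  # single-pass scalar counter over the raw event stream
  count <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  for (r in seq_len(nrow(log$merges))) {
    count[log$merges$from[r], log$merges$to[r]] <-
      count[log$merges$from[r], log$merges$to[r]] + 1L
  }
  expect_identical(ms$alpha, count)
  expect_identical(sum(ms$alpha), nrow(log$merges))
  expect_identical(sum(ms$beta), nrow(log$splits))
})

test_that("the connection matrix is the symmetrised average of alpha and beta", {
  # hand evaluation of the stated formula
  ms <- list(alpha = matrix(c(0, 2, 4, 0), 2, 2, byrow = TRUE),
             beta = matrix(c(0, 1, 3, 0), 2, 2, byrow = TRUE))
  gam <- connection_matrix(ms)
  expect_equal(unclass(gam), matrix(c(0, 2.5, 2.5, 0), 2, 2))

  # fixed point: alpha = beta, both symmetric -> gamma = alpha
  sym <- matrix(c(0, 3, 3, 0), 2, 2)
  expect_equal(unclass(connection_matrix(list(alpha = sym, beta = sym))), sym)

  # element-wise four-term scalar oracle on random integer matrices
  withr::with_seed(7, {
    for (rep in 1:10) {
      a <- matrix(sample(0:9, 25, replace = TRUE), 5, 5); diag(a) <- 0
      b <- matrix(sample(0:9, 25, replace = TRUE), 5, 5); diag(b) <- 0
      gam <- connection_matrix(list(alpha = a, beta = b))
      for (i in 1:5) for (j in 1:5) {
        expect_identical(gam[i, j], (a[i, j] + a[j, i] + b[i, j] + b[j, i]) / 4)
      }
      expect_equal(gam, t(gam))
      expect_true(all(diag(gam) == 0))
      # total event conservation
      expect_identical(sum(gam), (sum(a) + sum(b)) / 2)
    }
  })
  expect_error(connection_matrix(list(alpha = matrix(0, 2, 2),
                                      beta = matrix(0, 3, 3))),
               "shape", class = "kinoflex_validation_error")
})

test_that("time-averaged volumes follow the zero-when-undetected convention", {
  vols <- matrix(0, 10, 3, dimnames = list(NULL, c("A", "B", "C")))
  vols[, 1] <- 500                 # always present
  vols[1:5, 3] <- 600              # half the frames
  empty <- tibble::tibble(frame = integer(), from = character(), to = character())
  log <- new_pocket_event_log(c("A", "B", "C"), vols, empty, empty)
  out <- time_averaged_volumes(log)
  expect_equal(out$mean_volume, c(500, 0, 300))
  expect_equal(out$detection_fraction, c(1, 0, 0.5))

  # invariance to frame reordering
  log2 <- new_pocket_event_log(c("A", "B", "C"), vols[sample(10), ], empty, empty)
  expect_equal(time_averaged_volumes(log2), out)
})

test_that("connection distributions pool row entries and keep zeros", {
  g1 <- connection_matrix(list(
    alpha = matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
                   dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
    beta = matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
                  dimnames = list(c("A", "B", "C"), c("A", "B", "C")))))
  g0 <- connection_matrix(list(alpha = matrix(0, 3, 3, dimnames = dimnames(g1)),
                               beta = matrix(0, 3, 3, dimnames = dimnames(g1))))
  cd <- connection_distribution(list(s1 = g1, s2 = g0),
                                c(s1 = "active", s2 = "active"))
  a_entries <- cd$entries[cd$entries$pocket == "A", ]
  expect_setequal(a_entries$gamma[a_entries$system == "s1"], c(1, 2))
  expect_setequal(a_entries$gamma[a_entries$system == "s2"], c(0, 0))
  rs <- cd$row_sums
  expect_equal(rs$connections[rs$system == "s1" & rs$pocket == "A"], 3)
  expect_equal(rs$connections[rs$system == "s2" & rs$pocket == "A"], 0)
})

test_that("halved link rates in actives show up as lower connection row-sums", {
  wins <- vapply(1:10, function(s) {
    la <- gen_pocket_events(pocket_sim_spec(pocket_names = c("A", "B", "C", "D"),
                                            n_frames = 5000, link_rate = 0.001,
                                            seed = 2000 + s))
    li <- gen_pocket_events(pocket_sim_spec(pocket_names = c("A", "B", "C", "D"),
                                            n_frames = 5000, link_rate = 0.002,
                                            seed = 3000 + s))
    ga <- connection_matrix(events_to_matrices(la))
    gi <- connection_matrix(events_to_matrices(li))
    cd <- connection_distribution(list(act = ga, ina = gi),
                                  c(act = "active", ina = "inactive"))
    rs <- cd$row_sums
    mean(rs$connections[rs$label == "inactive"]) >
      mean(rs$connections[rs$label == "active"])
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("the JSON event-log dialect round-trips", {
  log <- gen_pocket_events(pocket_sim_spec(n_frames = 30, link_rate = 0.05, seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_pocket_events_json(log, path)
  back <- read_pocket_events_json(path)
  expect_identical(back$pocket_names, log$pocket_names)
  expect_equal(back$volumes, log$volumes, tolerance = 1e-12)
  expect_equal(dplyr::arrange(back$merges, frame, from, to),
               dplyr::arrange(log$merges, frame, from, to))
  expect_equal(dplyr::arrange(back$splits, frame, from, to),
               dplyr::arrange(log$splits, frame, from, to))
})
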