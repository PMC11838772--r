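make_long_csv <- function(path, drop_cell = NULL, dup = FALSE) {
  grid <- expand.grid(entity_id = c("a", "b"), time = 0:3,
                      variable = c("x", "y", "z"), stringsAsFactors = FALSE)
  grid$value <- seq_len(nrow(grid)) / 10
  grid$observed <- TRUE
  if (!is.null(drop_cell))
    grid <- grid[!(grid$entity_id == drop_cell[1] & grid$time == drop_cell[2] &
                     grid$variable == drop_cell[3]), ]
  if (dup) grid <- rbind(grid, grid[5, ])
  write.csv(grid, path, row.names = FALSE)
  path
}

test_that("long-format reading produces dense matrices with correct masks", {
  f <- make_long_csv(tempfile(fileext = ".csv"))
  trs <- read_trajectories(f)
  expect_length(trs, 2L)
  expect_equal(dim(trs[["a"]]$values), c(3L, 4L))
  expect_true(all(trs[["a"]]$mask))
  expect_identical(trs[["a"]]$variables, c("x", "y", "z"))

  f2 <- make_long_csv(tempfile(fileext = ".csv"), drop_cell = c("a", 2, "y"))
  trs2 <- read_trajectories(f2)
  expect_false(trs2[["a"]]$mask["y", 3L])      # 1-based column for time 2
  expect_identical(unname(trs2[["a"]]$values["y", 3L]), 0)
  expect_identical(sum(!trs2[["a"]]$mask), 1L)
})

test_that("reader validates duplicates, bad values, and short entities", {
  f <- make_long_csv(tempfile(fileext = ".csv"), dup = TRUE)
  expect_error(read_trajectories(f), "duplicate row for entity")

  bad <- data.frame(entity_id = "a", time = c(0, 1), variable = "x",
                    value = c("1.2", "oops"), observed = TRUE)
  fb <- tempfile(fileext = ".csv"); write.csv(bad, fb, row.names = FALSE)
  expect_error(read_trajectories(fb), "non-numeric value at row")

  short <- data.frame(entity_id = c("a", "a", "b"), time = c(0, 1, 0),
                      variable = "x", value = 1, observed = TRUE)
  fs <- tempfile(fileext = ".csv"); write.csv(short, fs, row.names = FALSE)
  expect_warning(trs <- read_trajectories(fs), "fewer than 2 time points")
  expect_named(trs, "a")
})

test_that("read -> write -> read is idempotent at the bit level", {
  sim <- tiny_sim(seed = 8, sigma = 0.1, n = 4, T_steps = 6)
  f1 <- tempfile(fileext = ".csv")
  write_trajectories(sim$trajectories, f1)
  r1 <- read_trajectories(f1)
  f2 <- tempfile(fileext = ".csv")
  write_trajectories(r1, f2)
  r2 <- read_trajectories(f2)
  for (id in names(r1)) {
    expect_identical(r2[[id]]$values, r1[[id]]$values)
    expect_identical(r2[[id]]$mask, r1[[id]]$mask)
    expect_identical(r2[[id]]$times, r1[[id]]$times)
  }
  ## wide export has one row per entity-time, one column per variable
  fw <- tempfile(fileext = ".csv")
  write_trajectories_wide(r1, fw)
  wide <- read.csv(fw, check.names = FALSE)
  expect_equal(nrow(wide), 4 * 6)
  expect_true(all(r1[[1]]$variables %in% names(wide)))
})

test_that("trajectory constructor enforces its invariants", {
  expect_error(trajectory("e", matrix(1:4, 2, 2), times = c(2, 1)),
               "strictly increasing")
  expect_error(trajectory("e", matrix(1:4, 2, 2), variables = c("a", "a")),
               "duplicate variable")
  expect_error(trajectory("e", matrix(1:2, 2, 1)), "at least two time points")
  m <- matrix(c(1, NA, 3, 4), 2, 2)
  expect_error(trajectory("e", m), "non-finite observed")
  expect_silent(trajectory("e", m, mask = matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)))
})

test_that("min-max scaling maps onto [eps, 1], handles constants, inverts", {
  tr <- trajectory("e", rbind(c(10, 15, 20), c(5, 5, 5)), variables = c("u", "cst"))
  sp <- fit_scaling(list(tr), eps_pos = 0.01)
  sc <- apply_scaling(sp, tr)
  expect_equal(sc$values["u", ], c(0.01, 0.505, 1))
  expect_equal(sc$values["cst", ], rep(0.5, 3))
  set.seed(1)
  x <- matrix(rnorm(2 * 50, 12, 4), 2, 50)
  expect_rel_equal(invert_scaling(sp, apply_scaling(sp, x)), x, 1e-9)

  ## unobserved-variable error lists the variable
  tr2 <- trajectory("e", rbind(c(1, 2), c(0, 0)), variables = c("ok", "gone"),
                    mask = rbind(c(TRUE, TRUE), c(FALSE, FALSE)))
  expect_error(fit_scaling(list(tr2)), "gone")

  ## JSON round trip
  f <- tempfile(fileext = ".json")
  write_scaling(sp, f)
  sp2 <- read_scaling(f)
  expect_equal(sp2$offset, sp$offset)
  expect_equal(sp2$scale, sp$scale)
})

test_that("edit-window enumeration matches the counting formula and protocols", {
  tr <- random_trajectory(T_steps = 5)
  w <- make_edit_windows(tr, min_history = 2, horizon_set = 1)
  expect_identical(w$hist_end, 2:4)
  expect_identical(w$target, w$hist_end + 1L)

  ## brute-force count property over random configurations
  set.seed(42)
  for (r in 1:20) {
    T_ <- sample(3:25, 1); mh <- sample(1:6, 1)
    H <- sample(1:8, sample(1:3, 1))
    tr2 <- random_trajectory(T_steps = T_, seed = r)
    w2 <- make_edit_windows(tr2, mh, H)
    expected <- sum(pmax(0, T_ - unique(H) - mh + 1))
    expect_identical(nrow(w2), as.integer(expected))
  }

  ## the delayed protocol: 23 steps, first nine as history, targets 10..23
  tr3 <- random_trajectory(T_steps = 23, seed = 7)
  w3 <- make_edit_windows(tr3, min_history = 9, horizon_set = 1:14)
  w9 <- w3[w3$hist_end == 9L, ]
  expect_identical(sort(w9$target), 10:23)

  ## too short: empty result, not an error
  expect_identical(nrow(make_edit_windows(random_trajectory(T_steps = 3), 5, 1)), 0L)
})
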