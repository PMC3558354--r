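# Independent oracle: count chronic-protocol administrations by direct
# day-by-day enumeration of the calendar (no shared code with the package).
chronic_count_oracle <- function(T_days, start_week, end_week,
                                 weekdays = c(0L, 3L), start_weekday = 4L) {
  cnt <- 0L
  for (d in 0:(T_days - 1)) {
    if (!(((start_weekday + d) %% 7) %in% weekdays)) next
    w <- d %/% 7
    if (w >= start_week && w < end_week && ((w - start_week) %% 4) < 2)
      cnt <- cnt + 1L
  }
  cnt
}

test_that("time grid discretization and search-space accounting", {
  g_all <- time_grid(400, 24, 0:6)
  expect_equal(g_all$N, 400L)
  expect_equal(log2_search_space(g_all), 400L)

  g_mt <- time_grid(400, 24, c(0L, 3L)) # Mon/Thu, default Friday start
  expect_equal(g_mt$N, 400L)
  expect_equal(log2_search_space(g_mt), 114L)

  g_one <- time_grid(7, 24, 0L, start_weekday = 0L)
  expect_equal(log2_search_space(g_one), 1L)

  expect_equal(log2_search_space(time_grid(400, 24, integer(0))), 0L)

  # sub-daily slots: one admissible slot per admissible day
  g8 <- time_grid(400, 8, c(0L, 3L))
  expect_equal(g8$N, 1200L)
  expect_equal(log2_search_space(g8), 114L)

  expect_error(time_grid(0, 24), "positive")
  expect_error(time_grid(400, 0), "positive")
  expect_error(time_grid(400, 7), "divide")
  expect_error(time_grid(400, 36), "multiple")
  expect_error(time_grid(400, 24, c(0L, 9L)), "0..6")
})

test_that("admissible count is exactly k*T/7 for whole weeks, any alignment", {
  for (wk in list(integer(0), 0L, c(0L, 3L), c(1L, 4L, 6L), 0:6)) {
    for (sw in 0:6) {
      for (T_days in c(7, 28, 140)) {
        g <- time_grid(T_days, 24, wk, start_weekday = sw)
        expect_equal(log2_search_space(g), length(wk) * T_days / 7)
      }
    }
  }
  # and is never above N, with equality iff the mask is all-true
  g <- time_grid(31, 24, c(0L, 3L))
  expect_lt(log2_search_space(g), g$N)
  expect_equal(log2_search_space(time_grid(31, 24, 0:6)), 31L)
})

test_that("administration counting", {
  g <- time_grid(400, 24, c(0L, 3L))
  expect_equal(count_administrations(new_schedule(g, integer(g$N))), 0L)
  x <- integer(g$N)
  x[which(g$admissible)[1]] <- 1L
  expect_equal(count_administrations(new_schedule(g, x)), 1L)

  bad <- structure(list(grid = g, x = c(0L, 1L)), class = "vax_schedule")
  expect_error(count_administrations(bad), "match")
})

test_that("chronic protocol matches the enumeration oracle", {
  g10 <- time_grid(70, 24, c(0L, 3L))
  s1 <- chronic_protocol(g10, start_week = 0, end_week = 4)
  expect_equal(count_administrations(s1), 4L) # one full cycle -> 4 shots

  expect_equal(count_administrations(chronic_protocol(g10, 3, 3)), 0L)

  g <- time_grid(400, 24, c(0L, 3L))
  s <- chronic_protocol(g, start_week = 6, end_week = 52)
  expect_equal(count_administrations(s), chronic_count_oracle(400, 6, 52))
  expect_equal(nrow(validate_schedule(s)), 0L)

  # default span, and a few other windows, against the oracle
  expect_equal(count_administrations(chronic_protocol(g)),
               chronic_count_oracle(400, 6, 400 %/% 7))
  for (ab in list(c(0, 8), c(5, 21), c(10, 11))) {
    expect_equal(
      count_administrations(chronic_protocol(g, ab[1], ab[2])),
      chronic_count_oracle(400, ab[1], ab[2]))
  }

  # administration count is non-decreasing in the window length
  counts <- sapply(seq(6, 54, by = 8),
                   function(e) count_administrations(chronic_protocol(g, 6, e)))
  expect_true(all(diff(counts) >= 0))

  expect_error(chronic_protocol(time_grid(400, 24, integer(0))), "weekly")
  expect_error(chronic_protocol(g, 6, 60), "horizon")
})

test_that("schedule validation reports slots and reasons", {
  g <- toy_grid()
  ok <- new_schedule(g, as.integer(g$admissible))
  expect_equal(nrow(validate_schedule(ok)), 0L)

  bad_slot <- which(!g$admissible)[1]
  x <- integer(g$N); x[bad_slot] <- 1L
  v <- validate_schedule(structure(list(grid = g, x = x),
                                   class = "vax_schedule"))
  expect_equal(v$slot, bad_slot)
  expect_match(v$reason, "inadmissible")
  expect_error(new_schedule(g, x), "inadmissible")

  v2 <- validate_schedule(structure(list(grid = g, x = integer(3)),
                                    class = "vax_schedule"))
  expect_equal(nrow(v2), 1L)
  expect_match(v2$reason, "length")
})

test_that("schedule file round-trip is the identity; bad files are rejected", {
  g <- time_grid(400, 24, c(0L, 3L))
  s <- chronic_protocol(g)
  path <- withr::local_tempfile(fileext = ".json")
  write_schedule(s, path)
  s2 <- read_schedule(path)
  expect_identical(s2$x, s$x)
  expect_identical(s2$grid$admissible, g$admissible)

  # random valid schedules round-trip bit-exactly
  withr::with_seed(42, {
    for (i in 1:5) {
      x <- integer(g$N)
      x[g$admissible] <- rbinom(sum(g$admissible), 1, 0.5)
      si <- new_schedule(g, x)
      write_schedule(si, path)
      expect_identical(read_schedule(path)$x, si$x)
    }
  })

  # declared N inconsistent with the bitstring
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$x <- substr(obj$x, 1, 100)
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(read_schedule(path), "length")

  # admissibility violation listed
  obj$x <- paste(rep("1", g$N), collapse = "")
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(read_schedule(path), "admissib")

  # non-binary characters
  obj$x <- paste(rep("2", g$N), collapse = "")
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(read_schedule(path), "0/1")

  writeLines("not json at all {", path)
  expect_error(read_schedule(path), "parse")
})
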