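#' Discretized vaccination time grid
#'
#' Discretizes the interval `[0, T]` into equally spaced administration
#' slots and marks which slots are admissible under a weekly constraint
#' (e.g. "administrations only on Mondays and Thursdays").  The admissible
#' slots span the schedule search space: its cardinality is `2^k` where `k`
#' is the number of admissible slots, so a 400-day daily grid with no
#' constraint has a `2^400` search space while the Monday/Thursday
#' constraint reduces it to `2^114` under the default calendar alignment.
#'
#' Weekdays are encoded 0--6 with 0 = Monday.  `start_weekday` anchors day 0
#' of the grid on the calendar; the default (4, a Friday) is the alignment
#' in which both Monday and Thursday occur exactly `floor(400/7) = 57` times
#' in 400 days, giving the canonical 114 admissible slots.  The admissible
#' count for other alignments can differ by one slot per weekday.
#'
#' When `dt_hours < 24`, only the first slot of an admissible day is
#' admissible, so the weekly constraint keeps its meaning at sub-daily
#' resolution.
#'
#' @param T_days Horizon in days (> 0).
#' @param dt_hours Slot width in hours; must divide 24 or be a multiple
#'   of 24.
#' @param admissible_weekdays Integer vector of weekday indices 0--6
#'   (0 = Monday) on which administration is permitted.  May be empty
#'   (no admissible slot).
#' @param start_weekday Weekday index of day 0.
#' @return An object of class `vax_grid` with fields `T_days`, `dt_hours`,
#'   `N` (slot count), `slot_times` (slot start times in hours),
#'   `admissible` (logical mask of length `N`), `admissible_weekdays`,
#'   `start_weekday`.
#' @examples
#' g <- time_grid(400, 24, c(0, 3)) # Mon/Thu over 400 days
#' log2_search_space(g)             # 114
#' @export
time_grid <- function(T_days, dt_hours = 24, admissible_weekdays = c(0L, 3L),
                      start_weekday = 4L) {
  if (!is.numeric(T_days) || length(T_days) != 1L || T_days <= 0)
    stop("T_days must be a single positive number")
  if (!is.numeric(dt_hours) || length(dt_hours) != 1L || dt_hours <= 0)
    stop("dt_hours must be a single positive number")
  if (dt_hours <= 24) {
    if (24 %% dt_hours != 0)
      stop("dt_hours must divide 24")
  } else if (dt_hours %% 24 != 0) {
    stop("dt_hours above 24 must be a multiple of 24")
  }
  admissible_weekdays <- as.integer(unique(admissible_weekdays))
  if (length(admissible_weekdays) &&
      (any(admissible_weekdays < 0L) || any(admissible_weekdays > 6L)))
    stop("weekday indices must lie in 0..6 (0 = Monday)")
  start_weekday <- as.integer(start_weekday)
  if (length(start_weekday) != 1L || start_weekday < 0L || start_weekday > 6L)
    stop("start_weekday must lie in 0..6 (0 = Monday)")

  N <- as.integer(floor(T_days * 24 / dt_hours))
  slot_times <- (seq_len(N) - 1) * dt_hours
  day <- floor(slot_times / 24)
  weekday <- (start_weekday + day) %% 7
  admissible <- weekday %in% admissible_weekdays
  if (dt_hours < 24) {
    admissible <- admissible & (slot_times %% 24 == 0)
  }
  structure(
    list(T_days = T_days, dt_hours = dt_hours, N = N,
         slot_times = slot_times, admissible = admissible,
         admissible_weekdays = admissible_weekdays,
         start_weekday = start_weekday),
    class = "vax_grid"
  )
}

#' @export
print.vax_grid <- function(x, ...) {
  cat(sprintf(
    "<vax_grid> %g days, dt = %g h, N = %d slots, %d admissible (|D| = 2^%d)\n",
    x$T_days, x$dt_hours, x$N, sum(x$admissible), sum(x$admissible)))
  invisible(x)
}

#' Base-2 logarithm of the schedule search-space cardinality
#'
#' The search space is the set of binary schedules supported on the
#' admissible slots, so its cardinality is 2 raised to the number of
#' admissible slots.  Returns that exponent.
#'
#' @param grid A [time_grid()] object.
#' @return Integer count of admissible slots.
#' @export
log2_search_space <- function(grid) {
  stopifnot(inherits(grid, "vax_grid"))
  sum(grid$admissible)
}

#' Construct a schedule on a time grid
#'
#' A schedule is a binary vector `x` over the grid slots: `x[i] = 1` means
#' one vaccine administration (fixed dose) at slot `i`.  Administrations are
#' only allowed on admissible slots.
#'
#' @param grid A [time_grid()] object.
#' @param x Binary (0/1) vector of length `grid$N`.
#' @return An object of class `vax_schedule` with fields `grid` and `x`.
#' @export
new_schedule <- function(grid, x) {
  stopifnot(inherits(grid, "vax_grid"))
  x <- as.integer(x)
  s <- structure(list(grid = grid, x = x), class = "vax_schedule")
  v <- validate_schedule(s, grid)
  if (nrow(v) > 0)
    stop("invalid schedule: ", paste(v$reason[seq_len(min(3, nrow(v)))],
                                     collapse = "; "))
  s
}

#' @export
print.vax_schedule <- function(x, ...) {
  cat(sprintf("<vax_schedule> %d administrations on a %g-day grid\n",
              count_administrations(x), x$grid$T_days))
  invisible(x)
}

#' Number of administrations in a schedule
#'
#' @param s A `vax_schedule`.
#' @return `sum(x)`, the administration count `n`.
#' @export
count_administrations <- function(s) {
  stopifnot(inherits(s, "vax_schedule"))
  if (length(s$x) != s$grid$N)
    stop("schedule length does not match its grid")
  sum(s$x)
}

#' Reference chronic vaccination protocol
#'
#' Builds the chronic protocol: repeated 4-week cycles in which every
#' admissible slot of the first 2 weeks of each cycle carries an
#' administration (with the twice-weekly constraint this is 4
#' administrations per complete cycle), from `start_week` up to (but not
#' including) `end_week`.  The in-vivo reference starts at 6 weeks of age.
#'
#' @param grid A [time_grid()] with a weekly admissibility pattern (i.e. a
#'   non-empty `admissible_weekdays` set).
#' @param start_week First week (0-based) of the first cycle.
#' @param end_week Week at which cycling stops; `end_week * 7` must not
#'   exceed the grid horizon.  Defaults to the last complete week.
#' @return A `vax_schedule`.
#' @export
chronic_protocol <- function(grid, start_week = 6L,
                             end_week = grid$T_days %/% 7) {
  stopifnot(inherits(grid, "vax_grid"))
  if (length(grid$admissible_weekdays) == 0L)
    stop("chronic protocol requires a grid with a weekly admissibility pattern")
  if (start_week < 0) stop("start_week must be >= 0")
  if (end_week * 7 > grid$T_days)
    stop("end_week exceeds the grid horizon")
  x <- integer(grid$N)
  day <- floor(grid$slot_times / 24)
  w <- start_week
  while (w < end_week) {
    lo <- w * 7
    hi <- min((w + 2) * 7, end_week * 7) # first 2 weeks of the cycle
    sel <- grid$admissible & day >= lo & day < hi
    x[sel] <- 1L
    w <- w + 4
  }
  new_schedule(grid, x)
}

#' Diagnose schedule constraint violations
#'
#' @param s A `vax_schedule` (or a bare list with an `x` field).
#' @param grid Grid to validate against; defaults to the schedule's own.
#' @return A data frame with columns `slot` (1-based index, `NA` for
#'   whole-vector problems) and `reason`; zero rows iff the schedule is
#'   valid.
#' @export
validate_schedule <- function(s, grid = s$grid) {
  x <- s$x
  out <- data.frame(slot = integer(), reason = character(),
                    stringsAsFactors = FALSE)
  if (length(x) != grid$N) {
    return(rbind(out, data.frame(
      slot = NA_integer_,
      reason = sprintf("schedule length %d does not match grid N = %d",
                       length(x), grid$N))))
  }
  bad_val <- which(!(x %in% c(0L, 1L)))
  for (i in bad_val)
    out <- rbind(out, data.frame(
      slot = i, reason = sprintf("slot %d: value %s is not 0/1", i, x[i])))
  bad_adm <- which(x == 1L & !grid$admissible)
  for (i in bad_adm)
    out <- rbind(out, data.frame(
      slot = i,
      reason = sprintf("slot %d: administration on inadmissible slot", i)))
  out
}

#' Read / write a schedule file
#'
#' Schedules are stored as a JSON object with fields `T_days`, `dt_hours`,
#' `start_weekday`, `admissible_weekdays` and `x` (the 0/1 bitstring of
#' length `N`).  `write_schedule()` followed by `read_schedule()` is the
#' identity on valid schedules; `read_schedule()` rejects files whose
#' bitstring is inconsistent with the declared grid or violates
#' admissibility.
#'
#' @param path File path.
#' @return `read_schedule()` returns a `vax_schedule`;
#'   `write_schedule()` returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse schedule file '", path, "': ",
                         conditionMessage(e)))
  need <- c("T_days", "dt_hours", "start_weekday", "admissible_weekdays", "x")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("schedule file '", path, "' is missing field(s): ",
         paste(miss, collapse = ", "))
  grid <- time_grid(obj$T_days, obj$dt_hours,
                    as.integer(obj$admissible_weekdays),
                    as.integer(obj$start_weekday))
  bits <- strsplit(obj$x, "")[[1]]
  if (!all(bits %in% c("0", "1")))
    stop("schedule file '", path, "': field 'x' contains non-0/1 characters")
  if (length(bits) != grid$N)
    stop("schedule file '", path, "': bitstring length ", length(bits),
         " does not match declared grid N = ", grid$N)
  x <- as.integer(bits)
  s <- structure(list(grid = grid, x = x), class = "vax_schedule")
  v <- validate_schedule(s, grid)
  if (nrow(v) > 0)
    stop("schedule file '", path, "' violates admissibility: ",
         paste(v$reason, collapse = "; "))
  s
}

#' @rdname read_schedule
#' @param s A `vax_schedule`.
#' @export
write_schedule <- function(s, path) {
  stopifnot(inherits(s, "vax_schedule"))
  g <- s$grid
  obj <- list(T_days = g$T_days, dt_hours = g$dt_hours,
              start_weekday = g$start_weekday,
              admissible_weekdays = as.integer(g$admissible_weekdays),
              x = paste(s$x, collapse = ""))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Internal: compressed genome view (values on admissible slots only).
genes_from_schedule <- function(s) {
  s$x[s$grid$admissible]
}

schedule_from_genes <- function(grid, genes) {
  x <- integer(grid$N)
  x[grid$admissible] <- as.integer(genes)
  new_schedule(grid, x)
}
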