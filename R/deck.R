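#' Robot deck layout
#'
#' Positions on the deck and the pairing between each culture plate and its
#' dedicated deep-well media reservoir (one reservoir well feeds one culture
#' well, which also gives each culture its own tip and media to prevent
#' cross-contamination). The standard high-throughput deck carries up to
#' five 96-well culture plates, five paired media plates, a tip rack, the
#' plate reader, and a wash station.
#'
#' @param n_culture_plates Number of culture plates (>= 1).
#' @param plate_type `"culture_plate_96"` or `"culture_plate_24"`.
#' @param wash_station Include a wash station site.
#' @return An object of class `deck_layout` with elements `positions` (a
#'   tibble: `site`, `kind`, `label`) and `pairing` (a tibble: `culture`,
#'   `media`).
#' @examples
#' deck_layout(5)
#' @export
deck_layout <- function(n_culture_plates = 5,
                        plate_type = c("culture_plate_96", "culture_plate_24"),
                        wash_station = TRUE) {
  plate_type <- match.arg(plate_type)
  if (n_culture_plates < 1) abort("need at least one culture plate")
  cult <- paste0("P", seq_len(n_culture_plates))
  media <- paste0("M", seq_len(n_culture_plates))
  positions <- bind_rows(
    tibble(site = paste0("S", seq_along(cult)), kind = plate_type,
           label = cult),
    tibble(site = paste0("S", length(cult) + seq_along(media)),
           kind = "media_deepwell_96", label = media),
    tibble(site = "T1", kind = "tip_rack", label = "TIPS"),
    tibble(site = "R1", kind = "reader", label = "READER"),
    if (wash_station) tibble(site = "W1", kind = "wash_station", label = "WASH")
  )
  if (anyDuplicated(positions$label)) abort("deck labels must be unique")
  structure(list(positions = positions,
                 pairing = tibble(culture = cult, media = media)),
            class = "deck_layout")
}

#' @export
print.deck_layout <- function(x, ...) {
  cat("<deck_layout>", nrow(x$pairing), "culture plate(s) with paired media;",
      nrow(x$positions), "sites\n")
  invisible(x)
}

wells_per_plate <- function(kind) {
  switch(kind, culture_plate_96 = 96L, culture_plate_24 = 24L,
         abort(paste0("unknown plate kind: ", kind)))
}

#' Scheduling parameters
#'
#' Durations of the scheduler's tasks, in minutes. Reading a plate takes
#' about 10 minutes, as does the pipetting service of a plate; tip washing
#' defaults to folded into the service time (`wash_min = 0`); these splits
#' are modeling assumptions and all are configurable. Resources are one
#' pipetting head, one reader, one transport arm.
#'
#' @param service_min Pipetting service time per plate.
#' @param read_min Plate-reader time per plate.
#' @param wash_min Tip wash cycle time (0 folds washing into the service).
#' @param move_min Transport-arm move time per plate move.
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(service_min = 10, read_min = 10, wash_min = 0,
                            move_min = 0.5) {
  if (service_min <= 0 || read_min <= 0 || move_min <= 0) {
    abort("service_min, read_min and move_min must be > 0")
  }
  if (wash_min < 0) abort("wash_min must be >= 0")
  structure(list(service_min = service_min, read_min = read_min,
                 wash_min = wash_min, move_min = move_min),
            class = "schedule_config")
}

#' Channel assignment over one or two 24-well plates
#'
#' An 8-channel pipetting head over a 4-row 24-well plate can align at most
#' one channel per row, so a single plate exposes only 4 usable channels and
#' needs 6 pipetting cycles (one per column) for its 24 wells; two plates
#' serviced sequentially need 12. When two 24-well plates sit deck-adjacent
#' along the channel axis, the head can span both (4 + 4 rows = 8 channels)
#' and service all 48 wells in 6 cycles — twice the speed.
#'
#' @param plates One or two plate labels.
#' @param head_channels Channels on the pipetting head (must be 8).
#' @param span If two plates are given, span both with the full head
#'   (`TRUE`, default) or service them sequentially (`FALSE`).
#' @return A tibble with one row per (cycle, channel): `cycle`, `channel`,
#'   `plate`, `well`. Every well of every plate appears exactly once.
#' @examples
#' a <- assign_channels("A")                       # 6 cycles x 4 channels
#' b <- assign_channels(c("A", "B"), span = FALSE) # 12 cycles
#' d <- assign_channels(c("A", "B"), span = TRUE)  # 6 cycles
#' max(b$cycle) / max(d$cycle)                     # the 2x speedup
#' @export
assign_channels <- function(plates, head_channels = 8, span = TRUE) {
  if (head_channels != 8) abort("this head model has 8 channels")
  if (length(plates) < 1 || length(plates) > 2) {
    abort("assign_channels handles one or two 24-well plates")
  }
  rows <- 4L; cols <- 6L
  one_plate <- function(plate, channel_offset, cycle_offset) {
    tidyr::expand_grid(cycle = seq_len(cols), row = seq_len(rows)) |>
      mutate(
        plate = plate,
        channel = .data$row + channel_offset,
        well = paste0(LETTERS[.data$row], .data$cycle),
        cycle = .data$cycle + cycle_offset
      ) |>
      select("cycle", "channel", "plate", "well")
  }
  if (length(plates) == 1) {
    one_plate(plates, 0L, 0L)
  } else if (span) {
    bind_rows(one_plate(plates[1], 0L, 0L), one_plate(plates[2], 4L, 0L)) |>
      arrange(.data$cycle, .data$channel)
  } else {
    bind_rows(one_plate(plates[1], 0L, 0L), one_plate(plates[2], 0L, cols))
  }
}

#' Asynchronous multi-plate turbidostat schedule
#'
#' Discrete-event schedule of `cycles` full service rounds over every
#' culture plate on the deck. Per plate and round, the task chain is: move
#' to reader (arm), read (reader), move back (arm), pipetting service
#' (head), and optionally a tip wash (head + wash station). Each physical
#' resource (head, reader, arm) is single-occupancy; plates are visited in
#' fixed round-robin order and each task starts as soon as both its plate
#' and its resource are free. Reading plate i therefore overlaps pipetting
#' of plate j != i, which is what makes hundreds of cultures maintainable:
#' the asynchronous makespan is never worse than running every task
#' back-to-back.
#'
#' @param deck A [deck_layout()].
#' @param cfg A [schedule_config()].
#' @param cycles Number of full service rounds (>= 1).
#' @return A list of class `deck_schedule`: `steps` (a tibble of timed
#'   steps: `index`, `action`, `plate`, `well`, `volume_uL`, `channel`,
#'   `t_start_min`, `t_end_min`), and `summary` (one row: cultures serviced
#'   per full cycle, async and serialized makespans in minutes).
#' @examples
#' sched <- schedule_async(deck_layout(5), schedule_config(), cycles = 1)
#' sched$summary
#' @export
schedule_async <- function(deck, cfg = schedule_config(), cycles = 1) {
  stopifnot(inherits(deck, "deck_layout"), inherits(cfg, "schedule_config"))
  if (cycles < 1) abort("cycles must be >= 1")
  culture <- filter(deck$positions,
                    .data$kind %in% c("culture_plate_96", "culture_plate_24"))
  if (nrow(culture) == 0) abort("deck has no culture plates")
  has_wash <- any(deck$positions$kind == "wash_station")
  do_wash <- cfg$wash_min > 0
  if (do_wash && !has_wash) abort("wash configured but no wash station on deck")

  task_template <- function(plate) {
    t <- tibble(
      action = c("move_plate", "read_plate", "move_plate", "aspirate",
                 "dispense", if (do_wash) "wash"),
      resource = c("arm", "reader", "arm", "head", "head",
                   if (do_wash) "head"),
      dur = c(cfg$move_min, cfg$read_min, cfg$move_min,
              cfg$service_min / 2, cfg$service_min / 2,
              if (do_wash) cfg$wash_min),
      plate = plate
    )
    t
  }

  res_free <- c(arm = 0, reader = 0, head = 0)
  plate_free <- setNames(numeric(nrow(culture)), culture$label)
  steps <- list()
  for (cyc in seq_len(cycles)) {
    for (p in culture$label) {
      for (j in seq_len(nrow(task_template(p)))) {
        tk <- task_template(p)[j, ]
        t0 <- max(plate_free[[p]], res_free[[tk$resource]])
        t1 <- t0 + tk$dur
        plate_free[[p]] <- t1
        res_free[[tk$resource]] <- t1
        steps[[length(steps) + 1]] <- tibble(
          cycle = cyc, action = tk$action, plate = p,
          well = "ALL",
          volume_uL = 0,
          channel = if (tk$action %in% c("aspirate", "dispense")) "ALL96" else "",
          resource = tk$resource,
          t_start_min = t0, t_end_min = t1
        )
      }
    }
  }
  steps <- bind_rows(steps) |>
    arrange(.data$t_start_min, .data$plate) |>
    mutate(index = row_number(), .before = 1)

  cultures_per_cycle <- sum(purrr::map_int(culture$kind, wells_per_plate))
  serial <- sum(steps$t_end_min - steps$t_start_min) / cycles
  summary <- tibble(
    n_culture_plates = nrow(culture),
    cultures_per_cycle = cultures_per_cycle,
    cycles = cycles,
    makespan_min = max(steps$t_end_min),
    serial_makespan_min = serial * cycles
  )
  structure(list(steps = steps, summary = summary, deck = deck, cfg = cfg),
            class = "deck_schedule")
}

#' @export
print.deck_schedule <- function(x, ...) {
  s <- x$summary
  cat("<deck_schedule>", s$n_culture_plates, "plate(s),",
      s$cultures_per_cycle, "cultures/cycle,", s$cycles, "cycle(s), makespan",
      round(s$makespan_min, 1), "min (serialized",
      round(s$serial_makespan_min, 1), "min)\n")
  invisible(x)
}

#' @rdname schedule_async
#' @param x A `deck_schedule`.
#' @param ... Unused.
#' @method tidy deck_schedule
#' @export
tidy.deck_schedule <- function(x, ...) x$steps

#' @rdname schedule_async
#' @method glance deck_schedule
#' @export
glance.deck_schedule <- function(x, ...) x$summary

#' Tip wash cycle steps
#'
#' After each media transfer the tips are sterilized with 1% bleach, rinsed
#' in water, and returned to their housing unit, so they can be reused
#' without cross-contamination. This emits that fixed three-phase template
#' as schedulable steps for one plate's tips. A configured wash time of zero
#' omits the steps with a warning.
#'
#' @param plate Culture plate label whose tips are washed.
#' @param cfg A [schedule_config()].
#' @param deck A [deck_layout()]; must include a wash station.
#' @return A tibble of steps (`action`, `plate`, `well`, `volume_uL`,
#'   `channel`, `t_start_min`, `t_end_min`; untimed, times `NA`).
#' @export
wash_cycle_steps <- function(plate, cfg = schedule_config(wash_min = 2),
                             deck = deck_layout()) {
  stopifnot(inherits(cfg, "schedule_config"), inherits(deck, "deck_layout"))
  if (!any(deck$positions$kind == "wash_station")) {
    abort("no wash station on the deck")
  }
  if (cfg$wash_min == 0) {
    warn("wash time is zero; emitting no wash steps")
    return(tibble(index = integer(), action = character(), plate = character(),
                  well = character(), volume_uL = double(),
                  channel = character(), t_start_min = double(),
                  t_end_min = double()))
  }
  tibble(
    index = 1:3,
    action = c("wash", "wash", "wash"),
    phase = c("bleach", "rinse", "return_tips"),
    plate = plate, well = "ALL", volume_uL = c(1000, 1000, 0),
    channel = "ALL96", t_start_min = NA_real_, t_end_min = NA_real_
  )
}

#' Per-well liquid steps for one simulator cycle
#'
#' Converts one cycle of closed-loop records into explicit per-well liquid
#' steps: for each well with a nonzero exchanged volume, one aspirate from
#' the paired media reservoir well and one dispense into the culture well,
#' both of that exact volume (plus the matching waste removal is implicit in
#' the exchange). The total dispensed volume therefore reconciles exactly
#' with the simulator's `vol_exchanged_uL` ledger.
#'
#' @param records Simulator records restricted to one cycle (one `t_hours`).
#' @param deck A [deck_layout()] providing the culture-to-media pairing.
#' @return A tibble of untimed steps (`index`, `action`, `plate`, `well`,
#'   `volume_uL`, `channel`, `t_start_min`, `t_end_min`).
#' @export
compile_service_steps <- function(records, deck = deck_layout()) {
  records <- as_tibble(records)
  if (length(unique(records$t_hours)) > 1) {
    abort("records must contain a single cycle (one t_hours value)")
  }
  pairing <- setNames(deck$pairing$media, deck$pairing$culture)
  unknown <- setdiff(unique(records$plate), names(pairing))
  if (length(unknown)) {
    abort(paste0("plate(s) not on deck: ", paste(unknown, collapse = ", ")))
  }
  live <- filter(records, .data$vol_exchanged_uL > 0)
  if (nrow(live) == 0) {
    return(tibble(index = integer(), action = character(), plate = character(),
                  well = character(), volume_uL = double(),
                  channel = character(), t_start_min = double(),
                  t_end_min = double()))
  }
  bind_rows(
    tibble(action = "aspirate", plate = unname(pairing[live$plate]),
           well = live$well, volume_uL = live$vol_exchanged_uL),
    tibble(action = "dispense", plate = live$plate, well = live$well,
           volume_uL = live$vol_exchanged_uL)
  ) |>
    mutate(channel = "ALL96", t_start_min = NA_real_, t_end_min = NA_real_) |>
    mutate(index = row_number(), .before = 1)
}

#' Write and read pipetting-step logs
#'
#' Step logs are JSON-lines: one object per step with keys `index`,
#' `action`, `plate`, `well`, `volume_uL`, `channel`, `t_start_min`,
#' `t_end_min`. A write-then-read round trip reproduces those fields
#' exactly.
#'
#' @param steps A step tibble (from [schedule_async()]'s `$steps`,
#'   [compile_service_steps()], or [wash_cycle_steps()]).
#' @param path Output file path.
#' @return `emit_command_log()` returns `path` invisibly;
#'   `read_command_log()` returns the steps tibble.
#' @export
emit_command_log <- function(steps, path) {
  steps <- as_tibble(steps)
  cols <- c("index", "action", "plate", "well", "volume_uL", "channel",
            "t_start_min", "t_end_min")
  miss <- setdiff(cols, names(steps))
  if (length(miss)) {
    abort(paste0("steps missing field(s): ", paste(miss, collapse = ", ")))
  }
  lines <- purrr::map_chr(seq_len(nrow(steps)), function(i) {
    row <- as.list(steps[i, cols])
    tryCatch(
      jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA, na = "null"),
      error = function(e) abort(sprintf("step %d is not serializable: %s",
                                        i, conditionMessage(e))))
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname emit_command_log
#' @export
read_command_log <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble(index = integer(), action = character(), plate = character(),
                  well = character(), volume_uL = double(),
                  channel = character(), t_start_min = double(),
                  t_end_min = double()))
  }
  purrr::map(lines, function(l) {
    as_tibble(purrr::map(jsonlite::fromJSON(l), ~ .x %||% NA))
  }) |>
    bind_rows() |>
    mutate(index = as.integer(.data$index),
           across(c("volume_uL", "t_start_min", "t_end_min"), as.numeric))
}
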