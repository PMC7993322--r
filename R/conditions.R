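#' Carbon/nitrogen/phosphorus media-condition grid
#'
#' Builds the Cartesian product of fold-change multipliers for the three
#' nutrient sources relative to standard (1x) M9, replicated, and assigns
#' each replicate deterministically to a well in row-major plate order
#' (plate 1 fills A1, A2, ... before plate 2 starts). The classic screen uses
#' five carbon levels, five nitrogen levels, and four phosphorus levels
#' (2- and 4-fold up and down): 100 conditions, 300 wells in triplicate.
#'
#' Each condition carries a deviation-from-1x metric
#' `|log2 c| + |log2 n| + |log2 p|`, zero exactly at standard media.
#'
#' @param c_levels,n_levels,p_levels Fold-change multipliers (> 0).
#' @param replicates Replicates per condition (>= 1).
#' @param n_plates,rows,cols Deck capacity for the assignment.
#' @return A tibble with one row per (condition, replicate): `condition_id`,
#'   `c_mult`, `n_mult`, `p_mult`, `deviation`, `replicate`, `plate`, `well`.
#' @examples
#' grid <- make_condition_grid(replicates = 3)
#' nrow(grid)                        # 300
#' length(unique(grid$condition_id)) # 100
#' @export
make_condition_grid <- function(c_levels = c(0.25, 0.5, 1, 2, 4),
                                n_levels = c(0.25, 0.5, 1, 2, 4),
                                p_levels = c(0.25, 0.5, 1, 2),
                                replicates = 1,
                                n_plates = 5, rows = 8, cols = 12) {
  if (!length(c_levels) || !length(n_levels) || !length(p_levels)) {
    abort("level lists must be non-empty")
  }
  if (any(c(c_levels, n_levels, p_levels) <= 0)) {
    abort("fold-change multipliers must be > 0")
  }
  if (replicates < 1) abort("replicates must be >= 1")

  grid <- tidyr::expand_grid(
    c_mult = c_levels, n_mult = n_levels, p_mult = p_levels,
    replicate = seq_len(replicates)
  ) |>
    mutate(
      condition_id = sprintf("c%g_n%g_p%g",
                             .data$c_mult, .data$n_mult, .data$p_mult),
      deviation = abs(log2(.data$c_mult)) + abs(log2(.data$n_mult)) +
        abs(log2(.data$p_mult))
    )

  capacity <- n_plates * rows * cols
  if (nrow(grid) > capacity) {
    abort(sprintf(
      "condition grid needs %d wells but the deck provides %d (%d plates x %d wells)",
      nrow(grid), capacity, n_plates, rows * cols))
  }
  idx <- seq_len(nrow(grid)) - 1L
  per_plate <- rows * cols
  grid |>
    mutate(
      plate = paste0("P", idx %/% per_plate + 1L),
      well = index_to_well(idx %% per_plate + 1L, rows, cols)
    ) |>
    select("condition_id", "c_mult", "n_mult", "p_mult", "deviation",
           "replicate", "plate", "well")
}

#' Synthetic nutrient response surface
#'
#' Maps a media condition to an intrinsic growth constant and a fluorescence
#' expression factor. This is a deliberately synthetic, smooth, monotone
#' stand-in for real metabolism, used to test that the landscape pipeline
#' recovers a planted surface: each nutrient contributes a Monod-type
#' saturating multiplier `f(m) = m * (1 + h) / (m + h)` with half-saturation
#' `h >= 0`, so `f(1) = 1` exactly (baseline media returns the baseline
#' values), `f` is strictly increasing in `m` when `h > 0`, and `h = 0`
#' gives zero sensitivity (`f == 1`).
#'
#' @param k_base Baseline growth constant at 1x M9 (1/hour).
#' @param e_base Baseline expression factor at 1x M9 (a.u. per OD).
#' @param k_half Named numeric `c(c = , n = , p = )` of half-saturation
#'   constants for the growth response.
#' @param e_half Same, for the expression response.
#' @return An object of class `response_map`.
#' @examples
#' rm <- response_map()
#' condition_to_growth(make_condition_grid(), rm)
#' @export
response_map <- function(k_base = 0.7, e_base = 1000,
                         k_half = c(c = 0.05, n = 0.05, p = 0.15),
                         e_half = c(c = 0.02, n = 0.02, p = 0.05)) {
  chk <- function(h, nm) {
    if (!all(c("c", "n", "p") %in% names(h)) || any(h < 0)) {
      abort(paste0(nm, " must be a named nonnegative vector with entries c, n, p"))
    }
  }
  chk(k_half, "k_half"); chk(e_half, "e_half")
  if (k_base < 0 || e_base < 0) abort("baseline values must be >= 0")
  structure(list(k_base = k_base, e_base = e_base,
                 k_half = k_half, e_half = e_half),
            class = "response_map")
}

monod_multiplier <- function(m, h) {
  if (h == 0) rep(1, length(m)) else m * (1 + h) / (m + h)
}

#' @rdname response_map
#' @param cond A tibble with columns `c_mult`, `n_mult`, `p_mult` (e.g. from
#'   [make_condition_grid()]).
#' @param response A `response_map`.
#' @return `condition_to_growth()` returns `cond` with columns `k` and
#'   `expression_factor` added.
#' @export
condition_to_growth <- function(cond, response = response_map()) {
  stopifnot(inherits(response, "response_map"))
  cond <- as_tibble(cond)
  need <- c("c_mult", "n_mult", "p_mult")
  if (!all(need %in% names(cond))) {
    abort("cond must have columns c_mult, n_mult, p_mult")
  }
  if (any(cond$c_mult <= 0 | cond$n_mult <= 0 | cond$p_mult <= 0)) {
    abort("multipliers must be > 0")
  }
  kf <- monod_multiplier(cond$c_mult, response$k_half[["c"]]) *
    monod_multiplier(cond$n_mult, response$k_half[["n"]]) *
    monod_multiplier(cond$p_mult, response$k_half[["p"]])
  ef <- monod_multiplier(cond$c_mult, response$e_half[["c"]]) *
    monod_multiplier(cond$n_mult, response$e_half[["n"]]) *
    monod_multiplier(cond$p_mult, response$e_half[["p"]])
  mutate(cond, k = response$k_base * kf,
         expression_factor = response$e_base * ef)
}

#' Per-condition equilibrium landscape summary
#'
#' Averages each well's filtered growth-constant estimate and fluorescence
#' over the equilibrium window (by default the final 12 hours of the run,
#' matching the convergence horizon), then averages and spreads across
#' replicates of the same media condition. The summary row count equals the
#' number of distinct conditions.
#'
#' @param records A `turbidostat_sim` or its records tibble.
#' @param grid Condition assignments from [make_condition_grid()].
#' @param equil_window Length of the terminal averaging window in hours.
#' @param blank_subtract Optional fluorescence blank to subtract from every
#'   fluorescence reading before averaging (default 0, i.e. none).
#' @return A tibble with columns `condition_id`, `c_mult`, `n_mult`,
#'   `p_mult`, `deviation`, `k_mean`, `k_sd`, `fluor_mean`, `fluor_sd`,
#'   `fluor_per_od_mean`, `n_replicates`.
#' @export
summarize_landscape <- function(records, grid, equil_window = 12,
                                blank_subtract = 0) {
  if (inherits(records, "turbidostat_sim")) records <- records$records
  records <- as_tibble(records)
  if (equil_window <= 0) abort("equil_window must be > 0")
  t_max <- max(records$t_hours)
  win <- filter(records, .data$t_hours >= t_max - equil_window)
  if (nrow(win) == 0) abort("equilibrium window contains no records")

  keyed <- win |>
    mutate(fluor = .data$fluor - blank_subtract) |>
    dplyr::inner_join(grid, by = c("plate", "well"))
  if (nrow(keyed) == 0) abort("no records match the grid assignment")
  missing_cond <- setdiff(unique(grid$condition_id), unique(keyed$condition_id))
  if (length(missing_cond)) {
    abort(paste0("conditions without records in the window: ",
                 paste(head(missing_cond, 5), collapse = ", ")))
  }

  keyed |>
    group_by(.data$condition_id, .data$c_mult, .data$n_mult, .data$p_mult,
             .data$deviation, .data$replicate) |>
    summarise(
      k_rep = mean(.data$k_est),
      fluor_rep = mean(.data$fluor),
      fpo_rep = mean(.data$fluor / pmax(.data$od_meas, .Machine$double.eps)),
      .groups = "drop_last"
    ) |>
    summarise(
      k_mean = mean(.data$k_rep),
      k_sd = if (n() > 1) stats::sd(.data$k_rep) else 0,
      fluor_mean = mean(.data$fluor_rep),
      fluor_sd = if (n() > 1) stats::sd(.data$fluor_rep) else 0,
      fluor_per_od_mean = mean(.data$fpo_rep),
      n_replicates = n(),
      .groups = "drop"
    ) |>
    arrange(.data$condition_id)
}

#' Run a full condition-grid turbidostat screen
#'
#' Convenience wrapper: plants the [response_map()] surface onto the grid's
#' wells, runs the closed loop, and summarizes the landscape.
#'
#' @param grid Assignments from [make_condition_grid()].
#' @param response A [response_map()].
#' @param cfg A [controller_config()].
#' @param noise A [noise_model()].
#' @param hours Simulated duration (default 36, a typical screen length).
#' @param od0 Inoculation OD per well.
#' @param volume_ul Working volume per well.
#' @param equil_window Passed to [summarize_landscape()].
#' @return A list with elements `sim` (the `turbidostat_sim`), `summary`
#'   (the landscape table), and `grid`.
#' @export
run_landscape <- function(grid, response = response_map(),
                          cfg = controller_config(), noise = noise_model(),
                          hours = 36, od0 = 0.01, volume_ul = 175,
                          equil_window = 12) {
  planted <- condition_to_growth(grid, response)
  plates <- tibble(
    plate = planted$plate, well = planted$well, od = od0,
    volume_ul = volume_ul, k = planted$k,
    expression_factor = planted$expression_factor
  )
  sim <- run_turbidostat(plates, cfg, noise, hours)
  list(sim = sim,
       summary = summarize_landscape(sim, grid, equil_window),
       grid = grid)
}
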