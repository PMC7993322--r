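#' Read and validate a turbidostat run configuration
#'
#' A run is a single JSON document with blocks `controller`
#' (`x_set`, `y_max`, `dt_hours`, `alpha`, `k_init`), `noise` (`od_cv`,
#' `vol_cv`, `seed`), `plates` (a list of objects with `plate`, `od0`,
#' `volume_ul`, `k`, `expression_factor`, `rows`, `cols`) and `hours`.
#' Missing fields fall back to package defaults. The shape is documented by
#' the schema shipped at `system.file("extdata/run_config.schema.json",
#' package = "turbicell")`; `validate_run_config()` enforces it.
#'
#' @param path Path to the JSON run configuration.
#' @return A list with elements `plates` (a culture-well tibble), `cfg`
#'   (a [controller_config()]), `noise` (a [noise_model()]), `hours`.
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  validate_run_config(doc)
  ctl <- doc$controller %||% list()
  cfg <- controller_config(
    x_set = ctl$x_set %||% 0.8, y_max = ctl$y_max %||% 1,
    dt_hours = ctl$dt_hours %||% 0.5, alpha = ctl$alpha %||% 0.7,
    k_init = ctl$k_init %||% 0
  )
  nz <- doc$noise %||% list()
  noise <- noise_model(od_cv = nz$od_cv %||% 0.05,
                       vol_cv = nz$vol_cv %||% 0.02,
                       seed = nz$seed %||% 1L)
  plates <- purrr::pmap(as_tibble(doc$plates), function(...) {
    p <- list(...)
    culture_plate(
      plate = p$plate, od0 = p$od0 %||% 0.05,
      volume_ul = p$volume_ul %||% 175, k = p$k %||% 0.7,
      expression_factor = p$expression_factor %||% 1000,
      rows = p$rows %||% 8L, cols = p$cols %||% 12L
    )
  }) |> bind_rows()
  list(plates = plates, cfg = cfg, noise = noise,
       hours = doc$hours %||% 24)
}

#' @rdname read_run_config
#' @param doc A parsed configuration list.
#' @return `validate_run_config()` returns `doc` invisibly or aborts with
#'   the first violation found.
#' @export
validate_run_config <- function(doc) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)
  check <- function(ok, msg) if (!ok) abort(paste0("run config: ", msg))
  known <- c("controller", "noise", "plates", "hours")
  check(all(names(doc) %in% known),
        paste0("unknown top-level field(s): ",
               paste(setdiff(names(doc), known), collapse = ", ")))
  if (!is.null(doc$hours)) {
    check(num1(doc$hours) && doc$hours >= 0, "hours must be a number >= 0")
  }
  ctl <- doc$controller
  if (!is.null(ctl)) {
    check(is.list(ctl), "controller must be an object")
    for (f in intersect(names(ctl), c("x_set", "y_max", "dt_hours"))) {
      check(num1(ctl[[f]]) && ctl[[f]] > 0, paste0("controller.", f, " must be > 0"))
    }
    if (!is.null(ctl$alpha)) {
      check(num1(ctl$alpha) && ctl$alpha >= 0 && ctl$alpha <= 1,
            "controller.alpha must be in [0, 1]")
    }
    if (!is.null(ctl$k_init)) {
      check(num1(ctl$k_init) && ctl$k_init >= 0, "controller.k_init must be >= 0")
    }
  }
  nz <- doc$noise
  if (!is.null(nz)) {
    check(is.list(nz), "noise must be an object")
    for (f in intersect(names(nz), c("od_cv", "vol_cv"))) {
      check(num1(nz[[f]]) && nz[[f]] >= 0, paste0("noise.", f, " must be >= 0"))
    }
  }
  check(!is.null(doc$plates) && NROW(doc$plates) >= 1,
        "at least one plate is required")
  pl <- as_tibble(doc$plates)
  check("plate" %in% names(pl), "each plate needs a 'plate' label")
  check(!anyDuplicated(pl$plate), "plate labels must be unique")
  invisible(doc)
}

#' Read and write transfer matrices as CSV
#'
#' The sparse triplet format is a CSV with header
#' `src_well,dst_well,fraction`, A1-style labels, and `"SINK"` allowed as a
#' destination. A dense matrix CSV (first column `well` holding source
#' labels, remaining columns named by destination labels, `SINK` column
#' optional) is read with `read_transfer_matrix(dense = TRUE)`.
#'
#' @param m A [transfer_matrix()].
#' @param path CSV file path.
#' @param rows,cols Plate geometry of the labels.
#' @param dense Read the dense matrix layout instead of triplets.
#' @return `write_transfer_matrix()` returns `path` invisibly;
#'   `read_transfer_matrix()` returns a [transfer_matrix()].
#' @export
write_transfer_matrix <- function(m, path) {
  g <- tm_geometry(m)
  out <- tibble(
    src_well = index_to_well(m$src, g[["rows"]], g[["cols"]]),
    dst_well = ifelse(is.na(m$dst), "SINK",
                      index_to_well(ifelse(is.na(m$dst), 1L, m$dst),
                                    g[["rows"]], g[["cols"]])),
    fraction = m$fraction
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_transfer_matrix
#' @export
read_transfer_matrix <- function(path, rows = 8, cols = 12, dense = FALSE) {
  if (dense) {
    d <- readr::read_csv(path, show_col_types = FALSE)
    src_lab <- d[[1]]
    d <- d[-1]
    d$src_well <- src_lab
    ent <- tidyr::pivot_longer(d, -"src_well", names_to = "dst_well",
                               values_to = "fraction") |>
      filter(!is.na(.data$fraction), .data$fraction > 0)
  } else {
    ent <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             src_well = readr::col_character(),
                             dst_well = readr::col_character(),
                             fraction = readr::col_double()))
  }
  sink <- ent$dst_well == "SINK"
  dst <- rep(NA_integer_, nrow(ent))
  dst[!sink] <- well_to_index(ent$dst_well[!sink], rows, cols)
  transfer_matrix(
    tibble(src = well_to_index(ent$src_well, rows, cols),
           dst = dst, fraction = ent$fraction),
    rows, cols
  )
}

#' Read a plate-state CSV
#'
#' Expects columns `well`, `volume_uL` (or `volume_ul`), `concentration`.
#'
#' @param path CSV file path.
#' @param rows,cols Plate geometry.
#' @return A [plate_state()].
#' @export
read_plate_state <- function(path, rows = 8, cols = 12) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  names(d)[names(d) == "volume_uL"] <- "volume_ul"
  if (!all(c("well", "volume_ul", "concentration") %in% names(d))) {
    abort("plate state CSV needs columns well, volume_uL, concentration")
  }
  st <- plate_state(rows, cols, volume_ul = 0, concentration = 0)
  idx <- well_to_index(d$well, rows, cols)
  st$volume_ul[idx] <- d$volume_ul
  st$concentration[idx] <- d$concentration
  st
}

#' Write a point-spread time series to CSV
#'
#' Long format: `iteration,well,volume_uL,concentration`, plus one CSV per
#' iteration when `per_iteration = TRUE`.
#'
#' @param ps A `point_spread` result.
#' @param path Combined long-format CSV path.
#' @param per_iteration Also write `<path stem>_iter<k>.csv` snapshots.
#' @return `path`, invisibly.
#' @export
write_point_spread <- function(ps, path, per_iteration = FALSE) {
  out <- as_tibble(ps)
  names(out)[names(out) == "volume_ul"] <- "volume_uL"
  readr::write_csv(out, path)
  if (per_iteration) {
    stem <- sub("\\.csv$", "", path)
    for (k in unique(out$iteration)) {
      readr::write_csv(select(filter(out, .data$iteration == k), -"iteration"),
                       sprintf("%s_iter%d.csv", stem, k))
    }
  }
  invisible(path)
}
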