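#' Sparse liquid transfer matrices
#'
#' A transfer matrix describes one iteration of metapopulation liquid
#' handling: rows are source wells, columns are destination wells, values
#' are the fraction of the source well's (pre-iteration) liquid moved. It is
#' stored sparsely as a tibble of entries `(src, dst, fraction)` using
#' 1-based row-major well indices; `dst = NA` is the off-plate SINK
#' (serialized as `"SINK"`), where liquid leaves the system. Per source, the
#' outgoing fractions must sum to at most 1; no entry may have
#' `src == dst`; well-to-well entries are unique per (src, dst) pair (SINK
#' entries may repeat, one per off-plate direction).
#'
#' @param entries A data frame with columns `src`, `dst`, `fraction`
#'   (`dst = NA` for SINK). May be empty.
#' @param rows,cols Plate geometry the indices refer to.
#' @return An object of class `transfer_matrix` (a tibble with geometry
#'   attributes `rows`, `cols`).
#' @examples
#' transfer_matrix(data.frame(src = 1, dst = 2, fraction = 0.5), 8, 12)
#' @export
transfer_matrix <- function(entries, rows = 8, cols = 12) {
  entries <- as_tibble(entries)
  if (nrow(entries) == 0) {
    entries <- tibble(src = integer(), dst = integer(), fraction = double())
  }
  need <- c("src", "dst", "fraction")
  if (!all(need %in% names(entries))) {
    abort("entries must have columns src, dst, fraction")
  }
  entries <- select(entries, "src", "dst", "fraction")
  entries$src <- as.integer(entries$src)
  entries$dst <- as.integer(entries$dst)
  n <- rows * cols
  if (any(is.na(entries$src)) || any(entries$src < 1 | entries$src > n)) {
    abort("src indices must be in 1..n_wells")
  }
  if (any(entries$dst < 1 | entries$dst > n, na.rm = TRUE)) {
    abort("dst indices must be in 1..n_wells or NA (SINK)")
  }
  if (any(entries$fraction <= 0 | entries$fraction > 1)) {
    abort("fractions must be in (0, 1]")
  }
  if (any(!is.na(entries$dst) & entries$src == entries$dst)) {
    abort("self-transfers (src == dst) are not allowed")
  }
  ww <- entries[!is.na(entries$dst), c("src", "dst")]
  if (anyDuplicated(ww)) abort("duplicate (src, dst) entries")
  sums <- tapply(entries$fraction, entries$src, sum)
  if (any(sums > 1 + 1e-9)) {
    bad <- names(sums)[sums > 1 + 1e-9][1]
    abort(sprintf("outgoing fractions of source well %s sum to %.4f > 1",
                  index_to_well(as.integer(bad), rows, cols),
                  sums[[bad]]))
  }
  structure(entries, rows = rows, cols = cols,
            class = c("transfer_matrix", class(entries)))
}

tm_geometry <- function(m) {
  stopifnot(inherits(m, "transfer_matrix"))
  c(rows = attr(m, "rows"), cols = attr(m, "cols"))
}

#' @export
print.transfer_matrix <- function(x, ...) {
  g <- tm_geometry(x)
  cat("<transfer_matrix>", g[["rows"]], "x", g[["cols"]], "plate,", nrow(x),
      "entries (", sum(is.na(x$dst)), "to SINK )\n")
  NextMethod()
}

#' Nearest-neighbour diffusion kernel
#'
#' Models flow or diffusion across the miniaturized landscape of a plate:
#' every well sends an equal share of `rate` to each of its von-Neumann
#' (4-neighbour) grid neighbours, `rate/4` apiece (or `rate/8` to each of 8
#' Moore neighbours). At the plate edge, a `"bounded"` kernel keeps the
#' missing neighbours' share in the well (reflecting boundary, mass
#' conserved) while an `"unbounded"` kernel sends it to the off-plate SINK
#' (mass leaves, as across a river's outflow).
#'
#' @param rows,cols Plate geometry.
#' @param rate Total fraction a fully interior well exports per iteration,
#'   in `[0, 1]`.
#' @param boundary `"bounded"` or `"unbounded"`.
#' @param neighborhood `"von_neumann"` (default) or `"moore"`.
#' @return A [transfer_matrix()].
#' @examples
#' make_diffusion_kernel(8, 12, 0.2)
#' @export
make_diffusion_kernel <- function(rows = 8, cols = 12, rate = 0.2,
                                  boundary = c("bounded", "unbounded"),
                                  neighborhood = c("von_neumann", "moore")) {
  boundary <- match.arg(boundary)
  neighborhood <- match.arg(neighborhood)
  if (rate < 0 || rate > 1) abort("rate must be in [0, 1]")
  offsets <- if (neighborhood == "von_neumann") {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  share <- rate / length(offsets)
  if (share == 0) return(transfer_matrix(NULL, rows, cols))

  idx <- seq_len(rows * cols)
  r <- (idx - 1L) %/% cols + 1L
  c <- (idx - 1L) %% cols + 1L
  ent <- purrr::map(offsets, function(o) {
    rr <- r + o[1]; cc <- c + o[2]
    inside <- rr >= 1 & rr <= rows & cc >= 1 & cc <= cols
    dst <- ifelse(inside, (rr - 1L) * cols + cc, NA_integer_)
    keep <- inside | boundary == "unbounded"
    tibble(src = idx[keep], dst = dst[keep], fraction = share)
  }) |> bind_rows()
  transfer_matrix(arrange(ent, .data$src, .data$dst), rows, cols)
}

#' Geographic barriers
#'
#' A barrier attenuates liquid exchange across a set of well-pair edges,
#' by class: e.g. a "high" barrier (attenuation 0) removes crossing
#' transfers entirely, a "medium" one (attenuation 0.5) halves them. Edges
#' are undirected: both crossing directions are attenuated.
#'
#' @param edges A data frame with columns `a`, `b` (well indices) and
#'   `class` (barrier class name).
#' @param attenuation Named multipliers in `[0, 1]` per class
#'   (default `c(high = 0, medium = 0.5)`).
#' @return An object of class `barrier_spec`.
#' @seealso [row_cut_edges()] to build a full row cut.
#' @export
barrier_spec <- function(edges, attenuation = c(high = 0, medium = 0.5)) {
  edges <- as_tibble(edges)
  if (!all(c("a", "b", "class") %in% names(edges))) {
    abort("edges must have columns a, b, class")
  }
  if (any(attenuation < 0 | attenuation > 1)) {
    abort("attenuation multipliers must be in [0, 1]")
  }
  unknown <- setdiff(unique(edges$class), names(attenuation))
  if (length(unknown)) {
    abort(paste0("unknown barrier class(es): ", paste(unknown, collapse = ", ")))
  }
  structure(list(edges = edges, attenuation = attenuation),
            class = "barrier_spec")
}

#' @rdname barrier_spec
#' @param after_row Barrier sits between `after_row` and `after_row + 1`.
#' @param rows,cols Plate geometry.
#' @param class Barrier class for every edge in the cut.
#' @return `row_cut_edges()` returns an edge data frame for [barrier_spec()]:
#'   all vertical neighbour pairs crossing the cut.
#' @export
row_cut_edges <- function(after_row, rows = 8, cols = 12, class = "high") {
  if (after_row < 1 || after_row >= rows) abort("after_row must be in 1..rows-1")
  tibble(a = (after_row - 1L) * cols + seq_len(cols),
         b = after_row * cols + seq_len(cols),
         class = class)
}

#' Attenuate a transfer matrix across barriers
#'
#' Every entry whose (src, dst) pair crosses a barrier edge (in either
#' direction) has its fraction multiplied by that class's attenuation;
#' entries attenuated to zero are dropped; everything else is untouched.
#' SINK entries never cross a barrier.
#'
#' @param m A [transfer_matrix()].
#' @param b A [barrier_spec()].
#' @return A new [transfer_matrix()].
#' @export
apply_barriers <- function(m, b) {
  stopifnot(inherits(m, "transfer_matrix"), inherits(b, "barrier_spec"))
  g <- tm_geometry(m)
  n <- g[["rows"]] * g[["cols"]]
  if (any(b$edges$a < 1 | b$edges$a > n | b$edges$b < 1 | b$edges$b > n)) {
    abort("barrier edges reference wells outside the plate")
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  att <- setNames(b$attenuation[b$edges$class], key(b$edges$a, b$edges$b))

  ent <- as_tibble(m)
  hit <- !is.na(ent$dst) & key(ent$src, ent$dst) %in% names(att)
  ent$fraction[hit] <- ent$fraction[hit] *
    unname(att[key(ent$src[hit], ent$dst[hit])])
  transfer_matrix(ent[ent$fraction > 0, ], g[["rows"]], g[["cols"]])
}

#' Plate liquid state for transfer simulations
#'
#' Per-well working volume and tracer (dye or organism) concentration.
#'
#' @param rows,cols Plate geometry.
#' @param volume_ul Per-well volume (uL, >= 0), recycled.
#' @param concentration Per-well tracer concentration (a.u./uL), recycled.
#' @return A tibble of class `plate_state` with columns `well`, `volume_ul`,
#'   `concentration` in row-major order.
#' @examples
#' st <- plate_state(8, 12, volume_ul = 100)
#' st$concentration[well_to_index("D6")] <- 1  # seed a drop of dye
#' @export
plate_state <- function(rows = 8, cols = 12, volume_ul = 100,
                        concentration = 0) {
  n <- rows * cols
  volume_ul <- rep_len(volume_ul, n)
  concentration <- rep_len(concentration, n)
  if (any(volume_ul < 0)) abort("volume_ul must be >= 0")
  if (any(concentration < 0)) abort("concentration must be >= 0")
  structure(
    tibble(well = well_labels(rows, cols), volume_ul = volume_ul,
           concentration = concentration),
    rows = rows, cols = cols,
    class = c("plate_state", class(tibble())))
}

check_state_matrix <- function(state, m) {
  stopifnot(inherits(state, "plate_state"), inherits(m, "transfer_matrix"))
  g <- tm_geometry(m)
  if (nrow(state) != g[["rows"]] * g[["cols"]]) {
    abort("plate state and transfer matrix dimensions do not match")
  }
  g
}

#' Apply one transfer-matrix iteration to a plate state
#'
#' Snapshot semantics: every aspirated volume and tracer amount is computed
#' from the pre-iteration state (`out_vol(s -> d) = fraction * volume(s)`),
#' so the execution order of individual transfers cannot change the amounts
#' moved. Each destination's new content is what it retained plus all
#' incoming contributions, ideally mixed; SINK contributions are discarded.
#'
#' @param state A [plate_state()].
#' @param m A [transfer_matrix()] with matching geometry.
#' @return The new `plate_state`.
#' @export
apply_transfer_matrix <- function(state, m) {
  g <- check_state_matrix(state, m)
  vol <- state$volume_ul
  amt <- vol * state$concentration

  ev <- m$fraction * vol[m$src]          # per-entry volume, from snapshot
  ea <- ev * state$concentration[m$src]  # per-entry tracer amount

  out_v <- rowsum_vec(ev, m$src, nrow(state))
  out_a <- rowsum_vec(ea, m$src, nrow(state))
  keep <- !is.na(m$dst)
  in_v <- rowsum_vec(ev[keep], m$dst[keep], nrow(state))
  in_a <- rowsum_vec(ea[keep], m$dst[keep], nrow(state))

  new_vol <- vol - out_v + in_v
  new_amt <- amt - out_a + in_a
  st <- state
  st$volume_ul <- new_vol
  st$concentration <- ifelse(new_vol > 0, new_amt / new_vol, 0)
  st
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Compile a transfer matrix to explicit pipetting steps
#'
#' Emits one aspirate-and-dispense step per matrix entry, with the absolute
#' volume in microlitres precomputed from the pre-iteration snapshot, so
#' that execution order cannot change the amounts moved. Entries whose
#' volume exceeds the tip capacity are split into equal sub-steps; entries
#' that compile to zero volume are dropped with a warning. Executing the
#' steps with [interpret_transfers()] (aspirate phase first, then dispense
#' phase, realizing snapshot mixing) reproduces [apply_transfer_matrix()]
#' exactly.
#'
#' @param state A [plate_state()] (the pre-iteration snapshot).
#' @param m A [transfer_matrix()].
#' @param max_tip_ul Tip capacity per step (uL).
#' @return A tibble of class `transfer_steps`: `index`, `src_well`,
#'   `dst_well` (A1-style labels, `"SINK"` allowed), `volume_uL`.
#' @export
compile_transfers <- function(state, m, max_tip_ul = 1000) {
  g <- check_state_matrix(state, m)
  if (max_tip_ul <= 0) abort("max_tip_ul must be > 0")
  vol <- m$fraction * state$volume_ul[m$src]
  zero <- vol == 0
  if (any(zero)) {
    warn(sprintf("dropping %d zero-volume transfer(s)", sum(zero)))
  }
  src <- index_to_well(m$src, g[["rows"]], g[["cols"]])[!zero]
  dst <- ifelse(is.na(m$dst), "SINK",
                index_to_well(ifelse(is.na(m$dst), 1L, m$dst),
                              g[["rows"]], g[["cols"]]))[!zero]
  vol <- vol[!zero]

  n_split <- pmax(1L, ceiling(vol / max_tip_ul))
  steps <- tibble(
    src_well = rep(src, n_split),
    dst_well = rep(dst, n_split),
    volume_uL = rep(vol / n_split, n_split)
  ) |>
    mutate(index = row_number(), .before = 1)
  structure(steps, rows = g[["rows"]], cols = g[["cols"]],
            class = c("transfer_steps", class(steps)))
}

#' Execute compiled pipetting steps against a plate state
#'
#' The default `"snapshot"` semantics runs the whole aspirate phase first
#' (each aliquot takes the source's pre-phase concentration; removal does
#' not change a well's concentration) and then the dispense phase, which
#' reproduces [apply_transfer_matrix()] exactly. `"sequential"` semantics
#' executes each step's aspirate and dispense immediately in listed order,
#' for sensitivity analyses of order dependence.
#'
#' @param state A [plate_state()].
#' @param steps A `transfer_steps` tibble from [compile_transfers()].
#' @param semantics `"snapshot"` (default) or `"sequential"`.
#' @return The new `plate_state`.
#' @export
interpret_transfers <- function(state, steps,
                                semantics = c("snapshot", "sequential")) {
  semantics <- match.arg(semantics)
  stopifnot(inherits(state, "plate_state"))
  rows <- attr(state, "rows"); cols <- attr(state, "cols")
  src <- well_to_index(steps$src_well, rows, cols)
  sink <- steps$dst_well == "SINK"
  dst <- rep(NA_integer_, nrow(steps))
  dst[!sink] <- well_to_index(steps$dst_well[!sink], rows, cols)
  vol <- steps$volume_uL

  v <- state$volume_ul
  a <- v * state$concentration
  if (semantics == "snapshot") {
    conc0 <- state$concentration
    amt_moved <- vol * conc0[src]
    v <- v - rowsum_vec(vol, src, length(v))
    a <- a - rowsum_vec(amt_moved, src, length(a))
    if (any(v < -1e-9)) abort("aspirate phase over-draws a well")
    keep <- !is.na(dst)
    v <- v + rowsum_vec(vol[keep], dst[keep], length(v))
    a <- a + rowsum_vec(amt_moved[keep], dst[keep], length(a))
  } else {
    for (j in seq_along(vol)) {
      s <- src[j]
      if (vol[j] > v[s] + 1e-9) abort("step over-draws its source well")
      conc_s <- if (v[s] > 0) a[s] / v[s] else 0
      moved <- vol[j] * conc_s
      v[s] <- v[s] - vol[j]; a[s] <- a[s] - moved
      if (!is.na(dst[j])) {
        v[dst[j]] <- v[dst[j]] + vol[j]
        a[dst[j]] <- a[dst[j]] + moved
      }
    }
  }
  st <- state
  st$volume_ul <- v
  st$concentration <- ifelse(v > 0, a / v, 0)
  st
}

#' Point-spread of a tracer under repeated transfers
#'
#' Repeatedly applies a transfer matrix to a plate state (e.g. a drop of dye
#' seeded near the centre) and records the state after every iteration,
#' visualizing flow across the plate landscape.
#'
#' @param state Initial [plate_state()].
#' @param m A [transfer_matrix()].
#' @param iterations Number of iterations (>= 0).
#' @return A tibble of class `point_spread`: `iteration` (0 = initial),
#'   `well`, `volume_ul`, `concentration`.
#' @export
point_spread <- function(state, m, iterations = 10) {
  check_state_matrix(state, m)
  if (iterations < 0) abort("iterations must be >= 0")
  snaps <- vector("list", iterations + 1)
  snaps[[1]] <- mutate(as_tibble(state), iteration = 0L, .before = 1)
  st <- state
  for (i in seq_len(iterations)) {
    st <- apply_transfer_matrix(st, m)
    snaps[[i + 1]] <- mutate(as_tibble(st), iteration = i, .before = 1)
  }
  structure(bind_rows(snaps),
            rows = attr(state, "rows"), cols = attr(state, "cols"),
            class = c("point_spread", class(tibble())))
}
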