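# shared fixture builders and independent reference implementations

# random bounded transfer matrix on a small plate: each source exports to a
# few random destinations with fractions summing below 1
random_bounded_matrix <- function(rows, cols) {
  n <- rows * cols
  ent <- list()
  for (s in seq_len(n)) {
    k <- sample(0:2, 1)
    if (k == 0) next
    d <- sample(setdiff(seq_len(n), s), k)
    f <- runif(k)
    f <- f / sum(f) * runif(1, 0.1, 0.95)
    ent[[length(ent) + 1]] <- data.frame(src = s, dst = d, fraction = f)
  }
  transfer_matrix(do.call(rbind, ent), rows, cols)
}

random_plate_state <- function(rows, cols) {
  st <- plate_state(rows, cols,
                    volume_ul = runif(rows * cols, 50, 200),
                    concentration = runif(rows * cols, 0, 2))
  st
}

# dense matrix-on-amounts reference for apply_transfer_matrix: plain loops,
# no sparsity, no vectorized shortcuts
dense_transfer_reference <- function(state, m) {
  n <- nrow(state)
  vol <- state$volume_ul
  amt <- vol * state$concentration
  new_vol <- vol
  new_amt <- amt
  for (e in seq_len(nrow(m))) {
    s <- m$src[e]
    v_moved <- m$fraction[e] * vol[s]          # snapshot volume
    a_moved <- v_moved * (amt[s] / vol[s])     # snapshot concentration
    new_vol[s] <- new_vol[s] - v_moved
    new_amt[s] <- new_amt[s] - a_moved
    if (!is.na(m$dst[e])) {
      new_vol[m$dst[e]] <- new_vol[m$dst[e]] + v_moved
      new_amt[m$dst[e]] <- new_amt[m$dst[e]] + a_moved
    }
  }
  list(volume_ul = new_vol,
       concentration = ifelse(new_vol > 0, new_amt / new_vol, 0))
}

total_tracer <- function(state) sum(state$volume_ul * state$concentration)

# the study-conditions 96-well inoculation spread: 16 wells at each of six
# starting densities, sterile blanks excluded (0.01 stands in for near-zero)
spread_plate <- function(k = 0.7) {
  culture_plate("P1", od0 = rep(c(0.01, 0.1, 0.2, 0.4, 0.6, 0.8), each = 16),
                k = k)
}

resource_intervals_disjoint <- function(steps) {
  ok <- TRUE
  for (r in unique(steps$resource)) {
    s <- steps[steps$resource == r, ]
    s <- s[order(s$t_start_min), ]
    if (nrow(s) > 1) {
      ok <- ok && all(s$t_start_min[-1] >= s$t_end_min[-nrow(s)] - 1e-9)
    }
  }
  ok
}
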