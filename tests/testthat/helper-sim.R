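# Shared builders for small, fast simulation states.

# a fresh mini state: 180 x 180 um periodic domain, shallow agarose
mini_state <- function(medium = medium_spec(agarose_height = 240),
                       strains = default_panel(), width = 180, height = 120,
                       ...) {
  cfg <- sim_config(domain_width = width, domain_height = height, ...)
  simulation_state(cfg, medium, strains)
}

# place cells at explicit (i, j, k) rows of a matrix
seed_cells <- function(state, pos, code) {
  place_cells(state, pos[, 1], pos[, 2], pos[, 3], code)
  state
}

# a single strain with simple round numbers for hand arithmetic:
# quota 2 fmole, r_max = ln 2 (min doubling 1 hr) => vm = 2 fmole/hr
simple_strain <- function(id = "R", vm_mult = 1, K = 1, death = 0, ...) {
  strain_spec(id, "lysine", quota_alpha = 2, glucose_quota = 2,
              r_max = log(2), monod_K = K, fitness_multiplier = vm_mult,
              death_rate = death, ...)
}

# brute-force association index: independent double loop over all cells
brute_assoc <- function(labels, a, b, partner, mode = "full26",
                        wrap = TRUE) {
  d <- dim(labels)
  labels[labels < 0L] <- 0L  # live only
  if (length(d) == 2L) { labels <- array(labels, c(d, 1L)); d <- dim(labels) }
  off <- expand.grid(dx = -1:1, dy = -1:1,
                     dz = if (mode %in% c("planar8", "lateral8")) 0L else -1:1)
  off <- off[rowSums(off != 0) > 0, ]
  count_for <- function(target) {
    tot <- 0; nfoc <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (labels[i, j, k] != target) next
      np <- 0; ndiff <- 0
      for (r in seq_len(nrow(off))) {
        ii <- i + off$dx[r]; jj <- j + off$dy[r]; kk <- k + off$dz[r]
        if (wrap) {
          ii <- (ii - 1) %% d[1] + 1; jj <- (jj - 1) %% d[2] + 1
        } else if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2]) next
        if (kk < 1 || kk > d[3]) next
        v <- labels[ii, jj, kk]
        if (v != 0 && v != target) ndiff <- ndiff + 1
        if (v == partner) np <- np + 1
      }
      if (ndiff > 0) { tot <- tot + np; nfoc <- nfoc + 1 }
    }
    c(tot = tot, n = nfoc)
  }
  ca <- count_for(a); cb <- count_for(b)
  if (ca["n"] == 0 || cb["n"] == 0) return(NA_real_)
  (ca["tot"] / ca["n"]) / (cb["tot"] / cb["n"])
}
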