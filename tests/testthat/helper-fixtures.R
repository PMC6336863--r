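# small deterministic fixtures shared across test files

# straight radial neurite in +x with nodes every `step` um out to `len` um
straight_neurite <- function(len = 95, step = 5, soma_r = 5) {
  xs <- seq(step, len, by = step)
  if (xs[length(xs)] < len) xs <- c(xs, len)
  new_neuron_morphology(data.frame(
    id = c(1L, seq_along(xs) + 1L),
    type = c(1L, rep(3L, length(xs))),
    x = c(0, xs), y = 0, z = 0,
    radius = c(soma_r, rep(0.5, length(xs))),
    parent = c(-1L, seq_along(xs))))
}

# Y-shaped neurite: trunk to (25, 0) branching there, both tips 45 um out
y_neurite <- function() {
  tip_x <- 25 + (45 - 25) / sqrt(2)
  tip_y <- sqrt(45^2 - tip_x^2)
  new_neuron_morphology(data.frame(
    id = 1:5, type = c(1L, 3L, 3L, 3L, 3L),
    x = c(0, 12, 25, tip_x, tip_x),
    y = c(0, 0, 0, tip_y, -tip_y),
    z = 0, radius = c(5, rep(0.5, 4)),
    parent = c(-1L, 1L, 2L, 3L, 3L)))
}

# spike_trains with identical copies of one train on n electrodes
duplicated_trains <- function(train, n_el, duration_s) {
  spike_trains(data.frame(electrode_id = rep(seq_len(n_el), each = length(train)),
                          time_s = rep(train, n_el)),
               duration_s, n_el)
}

# independent Poisson trains at `rate` Hz
poisson_trains <- function(n_el, rate, duration_s, seed = 1) {
  withr::with_seed(seed, {
    df <- do.call(rbind, lapply(seq_len(n_el), function(e) {
      n <- rpois(1, rate * duration_s)
      data.frame(electrode_id = e, time_s = sort(runif(n, 0, duration_s)))
    }))
    spike_trains(df, duration_s, n_el)
  })
}
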