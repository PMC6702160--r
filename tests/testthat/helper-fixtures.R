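# Shared fixtures: tiny phantoms, hand-built stretch maps, brute-force
# performance oracles, and random cohort tables.

gauss_smooth3_test <- function(a, sigma, spacing = c(1, 1, 1)) {
  dcetrack:::gauss_smooth3(a, sigma, spacing)
}

grid_coords_test <- function(d, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dcetrack:::grid_world_coords(volume_grid(array(0, dim = d), spacing, origin))
}

field_u_test <- function(T) dcetrack:::field_u_matrix(T)

quiet_spec <- function(grid = c(24, 24, 24), ...) {
  phantom_spec(grid_shape = grid, noise_sd = 0, bias_amplitude = 0, ...)
}

# Stretch map with a single voxel and prescribed principal stretches.
stretch_fixture <- function(lambda) {
  structure(list(lambda = matrix(lambda, 1, 3), valid = TRUE,
                 dim = c(1L, 1L, 1L), spacing = c(1, 1, 1),
                 origin = c(0, 0, 0), boundary = FALSE, mode = "singular"),
            class = "stretch_map")
}

# Feature map over a bare vector of values (1 x 1 x n grid, all valid).
map_fixture <- function(values, name = "x") {
  n <- length(values)
  feature_map(name, array(values, dim = c(1, 1, n)),
              array(TRUE, dim = c(1, 1, n)))
}

# Brute-force AUC: enumerate all label-discordant pairs.
auc_brute <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0; npairs <- 0
  for (i in pos) for (j in neg) {
    npairs <- npairs + 1
    tot <- tot + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  tot / npairs
}

# Brute-force Harrell's C: usable pairs have the shorter observed time as an
# event; score ties count one half.
cindex_brute <- function(t, e, s) {
  n <- length(t)
  conc <- 0; usable <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (t[i] < t[j] && e[i] == 1) {
      usable <- usable + 1
      conc <- conc + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
    }
  }
  if (usable == 0) return(NA_real_)
  conc / usable
}

random_outcome_table <- function(n, family) {
  if (family == "logistic") {
    data.frame(pcr = rbinom(n, 1, 0.5))
  } else {
    data.frame(rfs_time = round(rexp(n, 0.3), 2) + 0.01,
               rfs_event = rbinom(n, 1, 0.6))
  }
}
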