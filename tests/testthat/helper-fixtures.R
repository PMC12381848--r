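# Shared fixtures and independent oracles. Heavy fixtures are built once per
# test run and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# Three tight basins (one carrying an exclusive motif): the "clear multi-basin
# structure" fixture used across projection/grid tests.
basin_fixture <- function() {
  memo("basins", function() {
    mk <- function(seed, lab, motif = NULL) {
      generate_basin_ensemble(
        polymer_spec(26, compactness = 0.4, seed = seed, exclusive_motif = motif),
        120, label = lab)
    }
    pooled <- pool_ensembles(list(mk(1, "b1"), mk(2, "b2"),
                                  mk(3, "b3", list(c(3, 22, 8)))))
    delta <- dissimilarity_matrix(pooled)
    proj <- force_scheme(delta, seed = 42)
    list(pooled = pooled, delta = delta, proj = proj)
  })
}

# A small mixed fixture: one broad walk ensemble, one compact walk ensemble.
mixed_fixture <- function() {
  memo("mixed", function() {
    e1 <- generate_polymer_ensemble(polymer_spec(26, compactness = 0, seed = 11),
                                    150, label = "broad")
    e2 <- generate_polymer_ensemble(polymer_spec(26, compactness = 0.8, seed = 12),
                                    150, label = "narrow")
    pooled <- pool_ensembles(list(e1, e2))
    delta <- dissimilarity_matrix(pooled)
    proj <- force_scheme(delta, seed = 7)
    list(pooled = pooled, delta = delta, proj = proj)
  })
}

# Deterministic toy conformations ----------------------------------------

# straight chain along x with given bond length
straight_chain <- function(n, bond = 3.8) {
  cbind((seq_len(n) - 1) * bond, 0, 0)
}

random_conformation <- function(n, seed) {
  set.seed(seed)
  generate_polymer_ensemble(polymer_spec(max(n, 4), seed = seed), 1) |>
    frame_coords(1)
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1], -axis[2], axis[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# Independent oracles ------------------------------------------------------

# term-by-term Q_w for two n x 3 conformations
oracle_qw <- function(mk, ml) {
  n <- nrow(mk)
  total <- 0
  np <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      rk <- sqrt(sum((mk[i, ] - mk[j, ])^2))
      rl <- sqrt(sum((ml[i, ] - ml[j, ])^2))
      sig <- abs(i - j)^0.15
      total <- total + exp(-(rk - rl)^2 / (2 * sig^2))
      np <- np + 1
    }
  }
  total / np
}

oracle_drmsd <- function(mk, ml) {
  n <- nrow(mk)
  ss <- 0
  np <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      rk <- sqrt(sum((mk[i, ] - mk[j, ])^2))
      rl <- sqrt(sum((ml[i, ] - ml[j, ])^2))
      ss <- ss + (rk - rl)^2
      np <- np + 1
    }
  }
  sqrt(ss / np)
}

# naive per-point binning oracle mirroring bin_projection's edge conventions
oracle_bin_counts <- function(x, y, labels, breaks_x, breaks_y) {
  nx <- length(breaks_x) - 1
  ny <- length(breaks_y) - 1
  labs <- sort(unique(labels))
  counts <- array(0L, c(nx, ny, length(labs)), dimnames = list(NULL, NULL, labs))
  for (p in seq_along(x)) {
    ix <- min(max(which(breaks_x <= x[p])), nx)
    iy <- min(max(which(breaks_y <= y[p])), ny)
    w <- match(labels[p], labs)
    counts[ix, iy, w] <- counts[ix, iy, w] + 1L
  }
  counts
}

# mean silhouette of labels over 2D points
silhouette_score <- function(xy, labels) {
  D <- as.matrix(dist(xy))
  n <- nrow(xy)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    a <- mean(D[i, setdiff(own, i)])
    b <- min(tapply(D[i, labels != labels[i]], labels[labels != labels[i]], mean))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# label 8-connected components of a set of (row, col) grid bins
connected_components <- function(bins) {
  n <- nrow(bins)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(comp == 0 &
                    abs(bins[, 1] - bins[i, 1]) <= 1 &
                    abs(bins[, 2] - bins[i, 2]) <= 1)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
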