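# Independent oracles and tiny fixture builders.  These deliberately avoid
# the package's own code paths (no rle(), no vectorised shortcuts) so they
# can serve as ground truth.

# Run-length scan oracle for bolt segmentation: explicit state machine over
# the interval sequence, then merge/filter per parameter combination.
# `v` is the velocity per interval, intervals are uniform at `dt`.
# Returns a list(start_i, end_i, distance) of interval indices per combo.
bolt_scan_oracle <- function(v, dt, theta, combos) {
  m <- length(v)
  runs_s <- integer(0)
  runs_e <- integer(0)
  in_run <- FALSE
  for (i in seq_len(m)) {
    if (v[i] > theta) {
      if (!in_run) {
        runs_s <- c(runs_s, i)
        in_run <- TRUE
      }
    } else if (in_run) {
      runs_e <- c(runs_e, i - 1L)
      in_run <- FALSE
    }
  }
  if (in_run) runs_e <- c(runs_e, m)

  lapply(seq_len(nrow(combos)), function(ci) {
    min_dur <- combos$min_duration_s[ci]
    gap_max <- combos$merge_gap_s[ci]
    ms <- runs_s
    me <- runs_e
    if (length(ms) > 1L) {
      ks <- ms[1]
      ke <- me[1]
      out_s <- integer(0)
      out_e <- integer(0)
      for (j in 2L:length(ms)) {
        gap <- (ms[j] - 1L - ke) * dt
        if (gap <= gap_max + 1e-9) {
          ke <- me[j]
        } else {
          out_s <- c(out_s, ks)
          out_e <- c(out_e, ke)
          ks <- ms[j]
          ke <- me[j]
        }
      }
      ms <- c(out_s, ks)
      me <- c(out_e, ke)
    }
    if (length(ms) > 0L) {
      keep <- (me - ms + 1L) * dt >= min_dur - 1e-9
      ms <- ms[keep]
      me <- me[keep]
    }
    dist <- vapply(seq_along(ms), function(j) sum(v[ms[j]:me[j]]) * dt, numeric(1))
    list(start_i = ms, end_i = me, distance = dist)
  })
}

# Brute-force Benjamini-Hochberg from the definition: for each p(i), the
# adjusted value is min over j with p(j) >= p(i) of p(j) * m / rank(j).
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  q <- ranked * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail by full enumeration of draws (combn).
hyper_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(K) # first K elements carry the annotation
  hits <- apply(draws, 2, function(d) sum(d %in% annotated))
  mean(hits >= k)
}

# Trajectory whose interval velocities equal `speeds` (movement along x).
traj_from_speeds <- function(speeds, dt = 0.1, well = "W1", group = "control") {
  tibble::tibble(
    well = well, group = group,
    t_s = seq(0, by = dt, length.out = length(speeds) + 1L),
    x_mm = c(0, cumsum(speeds * dt)),
    y_mm = 0
  )
}

# Minimal velocity container accepted by segment_bolts (uniform dt).
vel_from_speeds <- function(speeds, dt = 0.1) {
  n <- length(speeds)
  t0 <- (seq_len(n) - 1L) * dt
  tibble::tibble(
    t_start = t0, t_mid = t0 + dt / 2, t_end = t0 + dt,
    v = speeds, dt = dt
  )
}

random_traj <- function(n = 50, dt = 0.1, seed = 1, well = "W1",
                        group = "control") {
  withr::with_seed(seed, {
    tibble::tibble(
      well = well, group = group,
      t_s = seq(0, by = dt, length.out = n),
      x_mm = cumsum(stats::rnorm(n, 0, 0.3)),
      y_mm = cumsum(stats::rnorm(n, 0, 0.3))
    )
  })
}

# Small fully-specified LFQ matrix builder (values on the intensity scale).
lfq_from_matrix <- function(mat, groups = c("control", "control", "treated", "treated")) {
  colnames(mat) <- sprintf("s%d", seq_len(ncol(mat)))
  values <- dplyr::bind_cols(
    tibble::tibble(
      protein_id = sprintf("P%03d", seq_len(nrow(mat))),
      gene_symbol = sprintf("G%03d", seq_len(nrow(mat)))
    ),
    tibble::as_tibble(mat)
  )
  samples <- tibble::tibble(sample = colnames(mat), group = groups)
  lfq_matrix(values, samples)
}

# Exhaustive equivalence harness: enumerates every velocity series of the
# given lengths over `alphabet`, runs segment_bolts on a concatenation of
# the series (separated by long inactive stretches so events never span
# two series), and compares every event against bolt_scan_oracle.
check_bolts_exhaustive <- function(lengths, combos, dt = 0.1, theta = 0.1,
                                   alphabet = c(0, 0.5, 2.0), chunk = 65536L) {
  thr <- activity_thresholds(theta_active = theta)
  pad <- 15L
  mismatches <- 0L
  checked <- 0L
  for (L in lengths) {
    pats <- as.matrix(expand.grid(rep(list(alphabet), L)))
    nser <- nrow(pats)
    block <- L + pad
    for (chunk_start in seq(1L, nser, by = chunk)) {
      idx <- chunk_start:min(chunk_start + chunk - 1L, nser)
      sub <- pats[idx, , drop = FALSE]
      nb <- nrow(sub)
      vcat <- as.vector(t(cbind(sub, matrix(0, nb, pad))))
      n <- length(vcat)
      t0 <- (seq_len(n) - 1) * dt
      vel <- tibble::tibble(t_start = t0, t_mid = t0 + dt / 2,
                            t_end = t0 + dt, v = vcat, dt = dt)
      impl <- lapply(seq_len(nrow(combos)), function(ci) {
        ev <- segment_bolts(vel, thr, combos$min_duration_s[ci],
                            combos$merge_gap_s[ci])
        k0 <- as.integer(round(ev$start_s / dt)) # 0-based start interval
        k1 <- as.integer(round(ev$end_s / dt))   # 0-based exclusive end
        bi <- k0 %/% block
        list(block = bi + 1L,
             start_i = k0 - bi * block + 1L,
             end_i = k1 - bi * block,
             distance = ev$distance_mm)
      })
      impl_split <- lapply(impl, function(z) {
        split(seq_along(z$block), factor(z$block, levels = seq_len(nb)))
      })
      for (s in seq_len(nb)) {
        ora <- bolt_scan_oracle(sub[s, ], dt, theta, combos)
        for (ci in seq_len(nrow(combos))) {
          rows <- impl_split[[ci]][[s]]
          oc <- ora[[ci]]
          ok <- length(rows) == length(oc$start_i) &&
            all(impl[[ci]]$start_i[rows] == oc$start_i) &&
            all(impl[[ci]]$end_i[rows] == oc$end_i) &&
            (length(rows) == 0L ||
               max(abs(impl[[ci]]$distance[rows] - oc$distance)) < 1e-6)
          if (!ok) mismatches <- mismatches + 1L
        }
        checked <- checked + 1L
      }
    }
  }
  list(checked = checked, mismatches = mismatches)
}

bolt_param_grid <- function() {
  expand.grid(min_duration_s = c(0, 0.2, 0.4), merge_gap_s = c(0, 0.1))
}
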