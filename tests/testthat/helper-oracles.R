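# Independent oracles used across the suite. Deliberately written as plain
# loops / closed forms, separate from the package's implementation paths.

# blob-variance kappa straight from the definition (explicit loops)
oracle_kappa <- function(charges) {
  n <- length(charges)
  stopifnot(n >= 6, any(charges != 0))
  sigma_of <- function(q) {
    fp <- sum(q == 1) / length(q)
    fm <- sum(q == -1) / length(q)
    if (fp + fm == 0) 0 else (fp - fm)^2 / (fp + fm)
  }
  delta_of <- function(q, g) {
    s_seq <- sigma_of(q)
    vals <- numeric(length(q) - g + 1)
    for (i in seq_along(vals)) {
      vals[i] <- (sigma_of(q[i:(i + g - 1)]) - s_seq)^2
    }
    mean(vals)
  }
  np <- sum(charges == 1); nm <- sum(charges == -1)
  nz <- sum(charges == 0)
  blocks <- list(rep(1, np), rep(-1, nm), rep(0, nz))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ks <- numeric(2)
  for (gi in 1:2) {
    g <- c(5, 6)[gi]
    d <- delta_of(charges, g)
    dmax <- d  # the sequence's own delta caps kappa at 1 (shared convention)
    for (p in perms) {
      dl <- delta_of(unlist(blocks[p]), g)
      if (dl > dmax) dmax <- dl
    }
    ks[gi] <- if (dmax <= .Machine$double.eps) 0 else d / dmax
  }
  mean(ks)
}

# direct O(N^2) double-sum SCD
oracle_scd <- function(charges) {
  n <- length(charges)
  s <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + charges[i] * charges[j] * sqrt(j - i)
    }
  }
  s / n
}

# charge vector of a cg_sequence without touching package internals
charges_of_seq <- function(seq) {
  q <- integer(length(seq$residues))
  q[seq$residues == "POS"] <- 1L
  q[seq$residues == "NEG"] <- -1L
  q
}

# connected components by boolean transitive closure
oracle_components <- function(edges, n) {
  adj <- diag(TRUE, n)
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      adj[edges[k, 1], edges[k, 2]] <- TRUE
      adj[edges[k, 2], edges[k, 1]] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  labels <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      lab <- lab + 1L
      labels[adj[i, ]] <- lab
    }
  }
  labels
}

# canonical form of a partition labelling (relabel by first occurrence)
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# Boltzmann-integral oracle for <(r - r0)^2> of a 3D harmonic bond
oracle_bond_msq <- function(k, r0, kT) {
  f <- function(r) r^2 * exp(-k * (r - r0)^2 / kT)
  z <- stats::integrate(f, 0, r0 + 30 * sqrt(kT / k))$value
  stats::integrate(function(r) (r - r0)^2 * f(r), 0,
                   r0 + 30 * sqrt(kT / k))$value / z
}

# closed-form radius of gyration of an N-bead straight rod, bond length b
oracle_rod_rg <- function(n, b) {
  b * sqrt((n^2 - 1) / 12)
}

# all 3-letter sequences of a given length, as charge vectors
enumerate_charge_seqs <- function(len) {
  grid <- as.matrix(expand.grid(rep(list(c(1L, -1L, 0L)), len)))
  dimnames(grid) <- NULL
  grid
}

# a small compact interacting test system away from any cutoff boundary
make_test_system <- function(seed = 1, n_chains = 3, len = 6,
                             box = 200, periodic = FALSE) {
  set.seed(seed)
  res <- c("POS", "NEG", "ARO", "POS", "NEG", "ARO")[seq_len(len)]
  seq <- coarse_sequence(res)
  n <- n_chains * len
  repeat {
    base <- matrix(stats::runif(n_chains * 3, 90, 110), ncol = 3)
    pos <- NULL
    for (c_i in seq_len(n_chains)) {
      chain <- matrix(0, len, 3)
      chain[1, ] <- base[c_i, ]
      for (r in 2:len) {
        u <- stats::rnorm(3)
        chain[r, ] <- chain[r - 1, ] + 3.8 * u / sqrt(sum(u^2))
      }
      pos <- rbind(pos, chain)
    }
    d <- as.matrix(stats::dist(pos))
    diag(d) <- Inf
    # keep clear of the repulsion cutoff (8 A) discontinuity and of overlap
    if (min(d) > 2.5 && min(abs(d - 8)) > 0.15 &&
        min(abs(d - 17.5)) > 0.15) break
  }
  system_configuration(pos, rep(seq_len(n_chains), each = len),
                       rep(res, n_chains), box, periodic = periodic,
                       sequence = seq)
}

# central finite-difference gradient of the total energy
fd_forces <- function(sys, params, cond, h = 1e-5) {
  n <- length(sys$positions)
  g <- numeric(n)
  for (k in seq_len(n)) {
    p1 <- sys; p1$positions[k] <- p1$positions[k] + h
    p2 <- sys; p2$positions[k] <- p2$positions[k] - h
    g[k] <- -(total_energy_forces(p1, params, cond)$total -
                total_energy_forces(p2, params, cond)$total) / (2 * h)
  }
  matrix(g, ncol = 3)
}
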