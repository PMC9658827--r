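# Brute-force reference implementations, deliberately naive (scalar loops,
# no shared code with the package internals), used as oracles.

scalar_dist <- function(a, b) {
  sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2)
}

atom_pos <- function(atoms, i) c(atoms$x[i], atoms$y[i], atoms$z[i])

# all-pairs heavy-atom scan for interface residues; returns sorted
# "chain|resno" keys
oracle_interface_residues <- function(model, cutoff) {
  a <- as.data.frame(model)
  a <- a[!a$is_hydrogen, ]
  ch <- sort(unique(a$chain))
  hits <- character(0)
  ia <- which(a$chain == ch[1])
  ib <- which(a$chain == ch[2])
  for (i in ia) {
    for (j in ib) {
      if (scalar_dist(atom_pos(a, i), atom_pos(a, j)) < cutoff) {
        hits <- c(hits,
                  paste(a$chain[i], a$resno[i], sep = "|"),
                  paste(a$chain[j], a$resno[j], sep = "|"))
      }
    }
  }
  sort(unique(hits))
}

# exhaustive enumeration of cross-chain donor/acceptor heavy-atom pairs
# (heavy-atom mode only)
oracle_hbond_count <- function(model, max_da = 3.5, covalent = 1.8,
                               elements = c("N", "O", "S")) {
  a <- as.data.frame(model)
  a <- a[!a$is_hydrogen & a$element %in% elements, ]
  ch <- sort(unique(a$chain))
  n <- 0
  for (i in which(a$chain == ch[1])) {
    for (j in which(a$chain == ch[2])) {
      d <- scalar_dist(atom_pos(a, i), atom_pos(a, j))
      if (d >= covalent && d <= max_da) n <- n + 1
    }
  }
  n
}

# independent mass-weighted COM by scalar accumulation
oracle_com <- function(atoms) {
  sx <- sy <- sz <- sm <- 0
  for (i in seq_len(nrow(atoms))) {
    sx <- sx + atoms$mass[i] * atoms$x[i]
    sy <- sy + atoms$mass[i] * atoms$y[i]
    sz <- sz + atoms$mass[i] * atoms$z[i]
    sm <- sm + atoms$mass[i]
  }
  c(sx, sy, sz) / sm
}

# exhaustive scan over partner residues for the minimum COM distance
oracle_min_com_distance <- function(frame, resno, chain, partner_chain) {
  a <- as.data.frame(frame)
  res <- a[a$chain == chain & a$resno == resno, ]
  com <- oracle_com(res)
  best <- Inf
  best_resno <- NA
  for (pr in sort(unique(a$resno[a$chain == partner_chain]))) {
    pcom <- oracle_com(a[a$chain == partner_chain & a$resno == pr, ])
    d <- scalar_dist(com, pcom)
    if (d < best) {
      best <- d
      best_resno <- pr
    }
  }
  list(distance = best, partner_resno = best_resno)
}

oracle_atomic_contact <- function(frame, resno, chain, partner_chain, cutoff) {
  a <- as.data.frame(frame)
  a <- a[!a$is_hydrogen, ]
  res <- which(a$chain == chain & a$resno == resno)
  par <- which(a$chain == partner_chain)
  for (i in res) {
    for (j in par) {
      if (scalar_dist(atom_pos(a, i), atom_pos(a, j)) < cutoff) return(TRUE)
    }
  }
  FALSE
}

# exhaustive membership tally
oracle_prevalence_counts <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  counts <- integer(length(universe))
  names(counts) <- universe
  for (r in universe) {
    for (s in sets) {
      if (r %in% s) counts[r] <- counts[r] + 1
    }
  }
  counts
}

# random proper rotation matrix
random_rotation <- function() {
  qr_out <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_out)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

interface_keys <- function(tbl) {
  sort(paste(tbl$chain, tbl$resno, sep = "|"))
}

# closed-form 99% sampling intervals for planted-parameter recovery
recovery_intervals <- function(p, mu, sigma, n) {
  list(
    p = stats::qbinom(c(0.005, 0.995), n, p) / n,
    mu = mu + c(-1, 1) * stats::qnorm(0.995) * sigma / sqrt(n),
    # population-SD convention: n * s^2 / sigma^2 ~ chi-square(n - 1)
    sd = sigma * sqrt(stats::qchisq(c(0.005, 0.995), n - 1) / n)
  )
}

in_interval <- function(x, iv) x >= iv[1] & x <= iv[2]

# small two-residue fixture with a controllable closest heavy-atom gap
two_residue_model <- function(gap) {
  as_complex_model(tibble::tibble(
    name = c("CA", "CB", "CA", "CB"),
    element = "C",
    resno = c(1, 1, 2, 2),
    resname = "ALA",
    chain = c("A", "A", "B", "B"),
    x = c(0, 1, 1 + gap, 2 + gap),
    y = 0, z = 0
  ), model_id = "pair")
}
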