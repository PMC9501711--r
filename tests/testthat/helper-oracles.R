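# Independent oracles and small fixture builders used across the suite.
# Each oracle is deliberately coded from first principles, independently of
# the package internals it checks.

# Signed torsion by an independent vector-algebra route (acos magnitude +
# triple-product sign), unlike the package's atan2 formulation.
oracle_dihedral <- function(p1, p2, p3, p4) {
  u <- function(v) v / sqrt(sum(v^2))
  crs <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3], a[1]*b[2]-a[2]*b[1])
  n1 <- u(crs(p2 - p1, p3 - p2))
  n2 <- u(crs(p3 - p2, p4 - p3))
  ang <- acos(max(-1, min(1, sum(n1 * n2)))) * 180 / pi
  s <- sum(crs(n1, n2) * u(p3 - p2))
  if (s < 0) -ang else ang
}

# Breadth-first-search all-pairs bond distance (no igraph).
oracle_bond_distances <- function(n, bonds) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (s in seq_len(n)) {
    front <- s; d <- 0
    while (length(front)) {
      d <- d + 1
      nxt <- unique(unlist(adj[front]))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      front <- nxt
    }
  }
  D
}

# Straightforward matrix-based reimplementation of energy-ranked greedy
# clustering, independent of cluster_poses internals.
oracle_greedy_clusters <- function(confs, energy, run_id, tolerance) {
  n <- length(confs)
  ord <- order(energy, run_id, seq_len(n))
  rms <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
  seeds <- integer(0); assign <- integer(n)
  for (r in ord) {
    hit <- 0L
    for (ci in seq_along(seeds)) {
      if (rms(confs[[seeds[ci]]], confs[[r]]) <= tolerance) { hit <- ci; break }
    }
    if (hit == 0L) { seeds <- c(seeds, r); hit <- length(seeds) }
    assign[r] <- hit
  }
  assign
}

# Random rigid transform (uniform-ish rotation from QR, bounded shift).
random_rigid <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qrM <- qr(M)
  R <- qr.Q(qrM)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = runif(3, -5, 5))
}

# Pair-dictionary plan for one column of the reference H-bond table.
reference_pair_plan <- function(model, ligand) {
  ref <- hbond_reference_distances()
  col <- ref[ref$model == model & ref$ligand == ligand, ]
  data.frame(label = col$label, receptor_atom = col$receptor_atom,
             receptor_resname = col$receptor_resname,
             receptor_resno = col$receptor_resno,
             ligand_atom = col$ligand_atom, distance = col$distance,
             published_compatible = col$published_compatible,
             stringsAsFactors = FALSE)
}
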