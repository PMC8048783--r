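# Independent oracles and fixture builders used across the suite.  None of
# these share code paths with the package implementation.

# --- Horn quaternion superposition oracle ----------------------------------
# Optimal RMSD between paired point sets via the largest eigenvalue of the
# 4x4 quaternion key matrix; independent of the SVD route.
quaternion_rmsd <- function(a, b) {
  n <- nrow(a)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  M <- t(ac) %*% bc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  ga <- sum(ac^2); gb <- sum(bc^2)
  sqrt(max(0, (ga + gb - 2 * lam)) / n)
}

# --- brute-force NAC oracle -------------------------------------------------
# Scalar re-computation of every hydrogen's distance and C-H...O angle.
oracle_classify <- function(traj, criterion) {
  res <- list()
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    o <- xyz[criterion$acceptor, ]
    for (s in criterion$sites) {
      cpos <- xyz[s$carbon, ]
      hit <- FALSE
      for (h in s$hydrogens) {
        hp <- xyz[h, ]
        d <- sqrt(sum((hp - o)^2))
        u <- o - hp; v <- cpos - hp
        th <- acos(min(1, max(-1, sum(u * v) /
                                 sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
        if (d < criterion$d_max &&
            abs(th - criterion$theta_ref) <= criterion$theta_tol) {
          hit <- TRUE
        }
      }
      res[[length(res) + 1]] <- data.frame(frame = f, site = s$label,
                                           nac = hit)
    }
  }
  out <- do.call(rbind, res)
  out[order(out$frame, out$site), ]
}

# per-frame nearest water by exhaustive scan
oracle_nearest_water <- function(traj, acceptor, waters) {
  t(vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    d <- sqrt(rowSums(sweep(xyz[waters, , drop = FALSE], 2,
                            xyz[acceptor, ])^2))
    k <- which.min(d)
    c(distance = d[k], water = waters[k])
  }, c(distance = 0, water = 0)))
}

# --- random small trajectories ---------------------------------------------
random_roster <- function(n) {
  tibble::tibble(
    serial = seq_len(n),
    name = paste0("X", seq_len(n)),
    element = sample(c("C", "H", "O", "N"), n, replace = TRUE),
    resname = sample(c("ALA", "HOH", "STR"), n, replace = TRUE),
    resnum = sample.int(50, n, replace = TRUE),
    chain = sample(c("A", "B"), n, replace = TRUE)
  )
}

random_trajectory <- function(n_atoms, n_frames, sd = 5) {
  trajectory(random_roster(n_atoms),
             array(rnorm(n_atoms * 3 * n_frames, sd = sd),
                   c(n_atoms, 3, n_frames)))
}

# random proper rotation via QR with det fix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rigidly move every frame of a trajectory by the same rotation/translation
rigid_move <- function(traj, rot = random_rotation(),
                       trans = rnorm(3, sd = 10)) {
  out <- traj
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f) %*% rot
    out$coords[, , f] <- sweep(m, 2, -trans)
  }
  out
}

# --- PDB fixture writer -----------------------------------------------------
# Minimal fixed-column writer, independent of the package reader.
write_pdb_fixture <- function(path, models) {
  lines <- character()
  multi <- length(models) > 1
  for (k in seq_along(models)) {
    m <- models[[k]]
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", k))
    for (i in seq_len(nrow(m))) {
      lines <- c(lines, sprintf(
        "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        ifelse(m$het[i], "HETATM", "ATOM"), m$serial[i],
        substr(m$name[i], 1, 4), " ", m$resname[i], m$chain[i],
        m$resnum[i], " ", m$x[i], m$y[i], m$z[i], 1.0, 0.0, m$element[i]))
    }
    if (multi) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_df <- function(n, coords = NULL) {
  if (is.null(coords)) coords <- matrix(rnorm(3 * n, sd = 5), n, 3)
  data.frame(serial = seq_len(n), name = paste0("C", seq_len(n)),
             element = "C", resname = "ALA", resnum = seq_len(n),
             chain = "A", het = FALSE,
             x = coords[, 1], y = coords[, 2], z = coords[, 3])
}

# deterministic scalar uniform draw for parameterised cases
runif_seeded <- function(seed, min = 0, max = 1) {
  withr::with_seed(seed, stats::runif(1, min, max))
}
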