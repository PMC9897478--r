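# shared fixtures and independent oracles

# random weighted point cluster as a structure with explicit scattering weights
make_cluster <- function(n, sd = 20, seed = 1, weights = NULL) {
  set.seed(seed)
  xyz <- matrix(rnorm(3 * n, sd = sd), ncol = 3)
  if (is.null(weights)) weights <- runif(n, 0.5, 1.5)
  structure_model(
    data.frame(serial = seq_len(n), name = "C", element = "C", resname = "TOY",
               resno = seq_len(n), chain = "A", altloc = "", occupancy = 1,
               is_hetero = FALSE, b = weights),
    xyz)
}

# uniform ball of unit-weight pseudo-atoms
make_sphere_cloud <- function(n, R, seed = 1) {
  set.seed(seed)
  pts <- matrix(rnorm(3 * n), ncol = 3)
  pts <- pts * (runif(n)^(1 / 3) * R / sqrt(rowSums(pts^2)))
  structure_model(
    data.frame(serial = seq_len(n), name = "C", element = "C", resname = "TOY",
               resno = seq_len(n), chain = "A", altloc = "", occupancy = 1,
               is_hetero = FALSE, b = 1),
    pts)
}

# exact O(N^2) Debye double sum -- the independent oracle for debye_curve
debye_exact <- function(xyz, w, q_grid) {
  D <- as.matrix(dist(xyz))
  W <- tcrossprod(w)
  vapply(q_grid, function(q) {
    S <- W * ifelse(D == 0, 1, sin(q * D) / (q * D))
    sum(S)
  }, 0)
}

# brute-force rigid-superposition oracle: quaternion grid search + Nelder-Mead
# refinement of the best rotations, entirely independent of the SVD route
rmsd_oracle <- function(x, y, n_grid = 4000, seed = 99) {
  set.seed(seed)
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  quat_rot <- function(qv) {
    qv <- qv / sqrt(sum(qv^2))
    a <- qv[1]; b <- qv[2]; c <- qv[3]; d <- qv[4]
    matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
             2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
             2 * (b * d + a * c), 2 * (c * d - a * b), a^2 - b^2 - c^2 + d^2),
           3, 3)
  }
  rmsd_of <- function(qv) {
    R <- quat_rot(qv)
    sqrt(mean(rowSums((xc %*% t(R) - yc)^2)))
  }
  quats <- matrix(rnorm(4 * n_grid), ncol = 4)
  vals <- apply(quats, 1, rmsd_of)
  best <- order(vals)[1:5]
  refined <- vapply(best, function(i)
    stats::optim(quats[i, ], rmsd_of, control = list(reltol = 1e-14,
                                                     maxit = 5000))$value, 0)
  min(refined)
}

# minimal PDB text fixture: two glutamates on different chains, an altloc'd
# serine, and a calcium HETATM between the carboxylates (synthetic geometry)
write_fixture_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   GLU A 347      10.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  CA  GLU A 347      11.400  10.000  10.000  1.00  0.00           C",
    "ATOM      3  C   GLU A 347      12.100  11.300  10.000  1.00  0.00           C",
    "ATOM      4  O   GLU A 347      11.500  12.380  10.000  1.00  0.00           O",
    "ATOM      5  CB  GLU A 347      12.000   9.000  11.000  1.00  0.00           C",
    "ATOM      6  CG  GLU A 347      13.300   8.500  10.600  1.00  0.00           C",
    "ATOM      7  CD  GLU A 347      13.900   7.500  11.500  1.00  0.00           C",
    "ATOM      8  OE1 GLU A 347      13.300   7.100  12.500  1.00  0.00           O",
    "ATOM      9  OE2 GLU A 347      15.000   7.000  11.200  1.00  0.00           O",
    "ATOM     10  N   SER A 348      13.300  11.400  10.200  1.00  0.00           N",
    "ATOM     11  CA ASER A 348      14.100  12.600  10.300  0.60  0.00           C",
    "ATOM     12  CA BSER A 348      14.150  12.650  10.250  0.40  0.00           C",
    "ATOM     13  OG ASER A 348      15.400  12.300  10.800  0.60  0.00           O",
    "ATOM     14  OG BSER A 348      15.450  12.250  10.850  0.40  0.00           O",
    "ATOM     15  N   GLU B 480      16.500   5.000  12.000  1.00  0.00           N",
    "ATOM     16  CA  GLU B 480      17.400   5.600  12.900  1.00  0.00           C",
    "ATOM     17  CB  GLU B 480      17.000   5.500  14.350  1.00  0.00           C",
    "ATOM     18  CG  GLU B 480      16.600   6.800  15.000  1.00  0.00           C",
    "ATOM     19  CD  GLU B 480      16.200   6.600  16.400  1.00  0.00           C",
    "ATOM     20  OE1 GLU B 480      16.700   5.700  17.100  1.00  0.00           O",
    "ATOM     21  OE2 GLU B 480      15.300   7.400  16.800  1.00  0.00           O",
    "HETATM   22 CA    CA A 601      14.800   6.200  13.500  1.00  0.00          CA",
    "END")
  writeLines(lines, path)
  invisible(path)
}

# cylinder ring-lattice fixture for the pore profiler
make_cylinder <- function(radius = 5, z_lo = -10, z_hi = 10, dz = 0.5,
                          n_per_ring = 72) {
  zs <- seq(z_lo, z_hi, by = dz)
  th <- 2 * pi * seq_len(n_per_ring) / n_per_ring
  xyz <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(th), radius * sin(th), z)))
  n <- nrow(xyz)
  structure_model(
    data.frame(serial = seq_len(n), name = "C", element = "C", resname = "TOY",
               resno = seq_len(n), chain = "A", altloc = "", occupancy = 1,
               is_hetero = FALSE, b = 1),
    xyz)
}

z_axis_frame <- function(origin = c(0, 0, 0)) {
  structure(list(origin = origin, axis = c(0, 0, 1)), class = "axis_frame")
}

# small toy spec to keep trajectory-heavy tests light
small_toy_spec <- function(seed = 1)
  toy_channel_spec(tmd_atoms_per_rod = 4, ecd_atoms = 30, lobe_atoms = 12,
                   seed = seed)

# where accession-gated inputs (deposited PDB / SASBDB curves) would live
accession_path <- function(...) {
  file.path(testthat::test_path("..", "..", "data-accessions"), ...)
}
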