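# heavy-atom name lists typed out independently per residue (the chemistry
# oracle for the hydrogen-template tests)
.peptide_atoms <- list(
  ALA = c("N", "CA", "C", "O", "CB"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  PRO = c("N", "CA", "C", "O", "CB", "CG", "CD"),
  GLY = c("N", "CA", "C", "O"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  GLN = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
  TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2",
          "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
          "CZ", "OH"))

make_peptide <- function(resnames = names(.peptide_atoms)) {
  rows <- do.call(rbind, lapply(seq_along(resnames), function(i) {
    nm <- .peptide_atoms[[resnames[i]]]
    data.frame(name = nm, element = substr(nm, 1, 1), resname = resnames[i],
               resno = i)
  }))
  n <- nrow(rows)
  rows$serial <- seq_len(n); rows$chain <- "A"; rows$altloc <- ""
  rows$occupancy <- 1; rows$is_hetero <- FALSE
  set.seed(42)
  structure_model(rows, matrix(rnorm(3 * n, sd = 10), ncol = 3))
}

test_that("labile hydrogen partitioning follows residue chemistry", {
  pep <- make_peptide()
  full <- contrast_model(d2o_fraction = 1, exchanged_fraction = 1)
  hc <- labile_hydrogen_count(pep, full)
  a <- pep$atoms
  # proline has no amide hydrogen
  expect_equal(hc$n_h_labile[a$resname == "PRO" & a$name == "N"], 0)
  # arginine side chain: NE-H plus two NH2 groups = 5 labile H
  expect_equal(sum(hc$n_h_labile[a$resname == "ARG" & !(a$name %in% c("N", "CA", "C", "O"))]), 5)
  # hand count over the 10-residue chain, full exchange:
  # backbone amides 9 (PRO none) + side chains ARG 5, SER 1, LYS 3, GLN 2,
  # TRP 1, TYR 1 = 13 -> 22 deuteriums in total
  expect_equal(sum(hc$n_d_eff), 22)
  # partial exchange scales the deuterium count linearly
  hc90 <- labile_hydrogen_count(pep, contrast_model(1, 0.90))
  expect_equal(sum(hc90$n_d_eff), 0.90 * 22)
  # glycine CA carries two (non-labile) hydrogens
  expect_equal(hc$n_h_total[a$resname == "GLY" & a$name == "CA"], 2)
})

test_that("shielded selections keep their labile hydrogens as 1H", {
  pep <- make_peptide()
  shielded <- contrast_model(1, 1, shielded_selection = "resname ARG")
  hc <- labile_hydrogen_count(pep, shielded)
  expect_equal(sum(hc$n_d_eff[pep$atoms$resname == "ARG"]), 0)
  expect_equal(sum(hc$n_d_eff), 22 - 6)  # ARG amide + 5 side chain removed
})

test_that("unknown residues contribute zero labile hydrogens with a warning", {
  st <- make_cluster(5)
  st$atoms$resname <- "XYZ"
  st$atoms$b <- NULL
  expect_warning(hc <- labile_hydrogen_count(st), "unknown residue")
  expect_equal(sum(hc$n_h_labile), 0)
})

test_that("excess scattering length is affine in the solvent D2O fraction", {
  pep <- make_peptide()
  db0 <- excess_scattering_lengths(pep, contrast_model(0, 0.9))
  db50 <- excess_scattering_lengths(pep, contrast_model(0.5, 0.9))
  db100 <- excess_scattering_lengths(pep, contrast_model(1, 0.9))
  expect_equal(db50, (db0 + db100) / 2, tolerance = 1e-12)
  # a hypothetical atom with b = rho_solvent * v has zero excess
  cm <- contrast_model(1, 0)
  rho <- solvent_sld(cm)
  st <- make_cluster(1)
  st$atoms$b <- NULL
  st$atoms$element <- "C"
  cm$b_table[["C"]] <- rho * (cm$volume_table[["C"]])
  st$atoms$resname <- "GLY"; st$atoms$name <- "C"
  expect_equal(excess_scattering_lengths(st, cm), 0, tolerance = 1e-12)
})

test_that("matching composition sums: peptide total excess vs hand formula", {
  # composition-level oracle: total excess = sum over elements of b - rho*v,
  # plus hydrogen bookkeeping, computed here from tables independent of the
  # per-atom loop
  pep <- make_peptide(c("ALA", "GLY"))
  cm <- contrast_model(1, 1)
  db <- excess_scattering_lengths(pep, cm)
  rho <- solvent_sld(cm)
  b <- cm$b_table; v <- cm$volume_table
  # ALA: N CA C O CB; H: amide(1,D) + CA(1) + CB(3); GLY: amide D + 2 CA-H
  total_hand <-
    (2 * b[["N"]] + 4 * b[["C"]] + 2 * b[["O"]] + b[["C"]]) +   # heavy atoms
    2 * b[["D"]] + 6 * b[["H"]] -                               # 2 amide D, 6 C-H
    rho * (2 * v[["N"]] + 5 * v[["C"]] + 2 * v[["O"]] + 8 * v[["H"]])
  expect_equal(sum(db), unname(total_hand), tolerance = 1e-10)
})

test_that("Debye curve reproduces closed forms for one and two atoms", {
  one <- make_cluster(1, weights = 1)
  dc1 <- debye_curve(one, q_grid = c(0, 0.1, 0.3))
  expect_equal(dc1$intensity, rep(1, 3))
  two <- make_cluster(2, weights = c(1, 1))
  d <- 7.3
  two$xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
  q <- c(0, 0.05, 0.1, 0.2, 0.35)
  dc2 <- debye_curve(two, q_grid = q, bin_width = 0.01)
  expect_equal(dc2$intensity[1], 4)
  expect_equal(dc2$intensity, 2 + 2 * ifelse(q == 0, 1, sin(q * d) / (q * d)),
               tolerance = 1e-6)
})

test_that("histogram Debye matches the exact double-sum oracle", {
  st <- make_cluster(300, sd = 20, seed = 42)
  q <- seq(0.01, 0.5, length.out = 50)
  exact <- debye_exact(st$xyz, st$atoms$b, q)
  errs <- vapply(c(0.5, 0.25, 0.1), function(bw) {
    dc <- debye_curve(st, q_grid = q, bin_width = bw)
    max(abs(dc$intensity - exact) / abs(exact))
  }, 0)
  expect_lt(errs[1], 0.002)          # 0.2% at the default bin width
  expect_lt(errs[3], errs[1])        # convergence as bin width shrinks
  expect_lt(errs[3], 2e-4)
})

test_that("forward scattering equals the squared summed contrast", {
  st <- make_cluster(120, seed = 8)
  i0 <- debye_curve(st, q_grid = c(0, 0.01))$intensity[1]
  expect_equal(i0, sum(st$atoms$b)^2, tolerance = 1e-9)
})

test_that("Debye curve is invariant under rigid-body transforms", {
  st <- make_cluster(150, seed = 10)
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- set_coords(st, sweep(st$xyz %*% t(R), 2, c(30, -12, 4), `+`))
  q <- default_q_grid(40)
  expect_equal(debye_curve(moved, q_grid = q)$intensity,
               debye_curve(st, q_grid = q)$intensity, tolerance = 1e-9)
})

test_that("Guinier analysis is exact on ideal Gaussian curves", {
  rg <- 50; i0 <- 1
  q <- seq(0.002, 0.05, length.out = 60)
  curve <- scattering_curve(q, i0 * exp(-q^2 * rg^2 / 3),
                            sigma = rep(1e-4, 60))
  g <- guinier_fit(curve)
  expect_equal(g$rg, rg, tolerance = 1e-6)
  expect_equal(g$i0, i0, tolerance = 1e-6)
  expect_lte(g$qrg_max_used, 1.3 + 1e-6)
  # rising curve has no Guinier regime
  bad <- scattering_curve(q, exp(q^2 * 100), sigma = rep(1e-4, 60))
  expect_error(guinier_fit(bad), "no Guinier regime")
})

test_that("Guinier of the noiseless toy-pentamer curve matches coordinate Rg", {
  toy <- build_toy_channel()
  rg_coord <- radius_of_gyration(toy$model, weighting = "excess_b")
  dc <- debye_curve(toy$model,
                    q_grid = exp(seq(log(0.003), log(0.2), length.out = 120)))
  g <- guinier_fit(dc, qrg_limit = 0.8)  # tight window for noiseless model curves
  expect_equal(g$rg, rg_coord, tolerance = 0.005)
})

test_that("Guinier tracks coordinate Rg across toy sizes 20-60 A", {
  for (R in c(26, 45, 64, 77)) {          # sphere radius -> Rg = R*sqrt(3/5)
    sph <- make_sphere_cloud(1500, R, seed = R)
    rg_coord <- radius_of_gyration(sph, weighting = "excess_b")
    dc <- debye_curve(sph, q_grid = exp(seq(log(0.002), log(0.8 / rg_coord),
                                            length.out = 80)))
    g <- guinier_fit(dc, qrg_limit = 0.8)
    expect_equal(g$rg, rg_coord, tolerance = 0.01)
  }
})

test_that("molecular weight from I(0) follows the absolute-scale formula", {
  # synthetic closure: build the absolute I(0) a particle of known mass
  # produces, then invert it
  toy <- build_toy_channel(toy_channel_spec(mode = "alanine"))
  cm <- contrast_model()
  cs <- contrast_summary(toy$model, cm)
  conc <- 2.5                               # mg/mL
  i0_abs <- conc * 1e-3 * (cs$mass_kda * 1e3) * cs$drho_m_cm_per_g^2 / 6.02214076e23
  mw <- molecular_weight_from_i0(i0_abs, conc, cs$drho_m_cm_per_g)
  expect_equal(mw, cs$mass_kda, tolerance = 0.02)
  # doubling concentration at fixed I(0) halves the estimate
  expect_equal(molecular_weight_from_i0(i0_abs, 2 * conc, cs$drho_m_cm_per_g),
               mw / 2, tolerance = 1e-9)
  expect_error(molecular_weight_from_i0(i0_abs, conc, 0), "zero contrast")
})

test_that("scale/background fitting is exact on self-fits and calibrated on noise", {
  st <- make_cluster(200, seed = 21)
  q <- default_q_grid(80)
  model <- debye_curve(st, q_grid = q)
  data <- scattering_curve(q, model$intensity,
                           sigma = 0.01 * abs(model$intensity))
  self_fit <- fit_scale_background(data, data)
  expect_equal(self_fit$scale, 1, tolerance = 1e-9)
  expect_equal(self_fit$background, 0, tolerance = 1e-6)
  expect_lt(self_fit$chi2_reduced, 1e-12)
  # planted scale and background recovered within 3 standard errors
  i0 <- model$intensity[1]
  sig <- 0.01 * abs(model$intensity) + 1e-4 * i0
  scales <- backs <- chi2s <- numeric(10)
  for (k in 1:10) {
    set.seed(500 + k)
    noisy <- scattering_curve(q, 2.5 * model$intensity + 0.01 * i0 +
                                rnorm(80, 0, sig), sigma = sig)
    ft <- fit_scale_background(model, noisy)
    scales[k] <- ft$scale; backs[k] <- ft$background; chi2s[k] <- ft$chi2_reduced
    # analytic parameter covariance from the weighted normal equations
    w <- 1 / sig^2
    m <- model$intensity
    cov <- solve(rbind(c(sum(w * m^2), sum(w * m)), c(sum(w * m), sum(w))))
    expect_lt(abs(ft$scale - 2.5), 3 * sqrt(cov[1, 1]) + 1e-12)
    expect_lt(abs(ft$background - 0.01 * i0), 3 * sqrt(cov[2, 2]) + 1e-12)
  }
  expect_equal(mean(chi2s), 1, tolerance = 0.15)
})

test_that("reduced chi-square is invariant to common rescaling of data and sigma", {
  st <- make_cluster(100, seed = 33)
  q <- default_q_grid(60)
  model <- debye_curve(st, q_grid = q)
  set.seed(9)
  sig <- 0.02 * abs(model$intensity)
  data <- scattering_curve(q, model$intensity + rnorm(60, 0, sig), sigma = sig)
  f1 <- fit_scale_background(model, data)
  data2 <- scattering_curve(q, 7.7 * data$intensity, sigma = 7.7 * data$sigma)
  f2 <- fit_scale_background(model, data2)
  expect_equal(f2$chi2_reduced, f1$chi2_reduced, tolerance = 1e-9)
  expect_equal(f2$scale, 7.7 * f1$scale, tolerance = 1e-9)
})

test_that("curve merging switches source exactly at the limit", {
  q1 <- seq(0.004, 0.12, by = 0.002)
  q2 <- seq(0.085, 0.35, by = 0.005)
  lo <- scattering_curve(q1, rep(1, length(q1)), sigma = rep(0.1, length(q1)))
  hi <- scattering_curve(q2, rep(2, length(q2)), sigma = rep(0.1, length(q2)))
  m <- merge_curves(lo, 0.09, hi)
  expect_true(all(m$intensity[m$q <= 0.09] == 1))
  expect_true(all(m$intensity[m$q > 0.09] == 2))
  expect_equal(length(m$q), sum(q1 <= 0.09) + sum(q2 > 0.09))
  expect_false(is.unsorted(m$q, strictly = TRUE))
  # merging a curve with itself returns the original
  self <- merge_curves(lo, 0.05, lo)
  expect_equal(self$q, lo$q)
  expect_equal(self$intensity, lo$intensity)
})

test_that("constant background subtraction round-trips and auto-estimates tails", {
  q <- seq(0.01, 0.35, length.out = 120)
  set.seed(4)
  base <- exp(-q^2 * 900) + 0.003
  noise_sd <- 2e-4
  curve <- scattering_curve(q, base + rnorm(120, 0, noise_sd),
                            sigma = rep(noise_sd, 120))
  sub0 <- subtract_constant(curve, 0)
  expect_equal(sub0$intensity, curve$intensity)
  rt <- subtract_constant(subtract_constant(curve, 0.1), -0.1)
  expect_equal(rt$intensity, curve$intensity, tolerance = 1e-12)
  auto <- subtract_constant(curve, "auto")
  est <- auto$metadata$background_subtracted
  expect_equal(est, 0.003, tolerance = 3 * noise_sd / sqrt(12) / 0.003)
  expect_equal(auto$sigma, curve$sigma)
})

test_that("curve ASCII round-trip preserves data and skips comments", {
  q <- seq(0.01, 0.3, length.out = 40)
  cur <- scattering_curve(q, exp(-q^2 * 400), sigma = rep(0.01, 40))
  path <- withr::local_tempfile(fileext = ".dat")
  write_curve(cur, path)
  txt <- c("# instrument header", readLines(path), "# trailing comment")
  writeLines(txt, path)
  back <- read_curve(path)
  expect_equal(back$q, cur$q, tolerance = 1e-7)
  expect_equal(back$intensity, cur$intensity, tolerance = 1e-7)
})
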