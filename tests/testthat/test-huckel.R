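# Hueckel oracle: spectra, frontier orbitals, planted redox maps.

P0 <- huckel_params(noise_sd = 0)

test_that("analytic spectra of benzene, ethylene and butadiene", {
  a <- P0$alpha; b <- P0$beta
  # benzene: cycle-graph eigenvalues alpha + 2*beta*cos(2*pi*k/6)
  pi_b <- extract_pi_system("c1ccccc1", P0)
  expect_equal(pi_b$n_pi_electrons, 6L)
  expect_equal(huckel_solve(pi_b, P0),
               sort(a + c(2, 1, 1, -1, -1, -2) * b), tolerance = 1e-12)
  # ethylene
  pi_e <- extract_pi_system("C=C", P0)
  expect_equal(huckel_solve(pi_e, P0), sort(a + c(1, -1) * b),
               tolerance = 1e-12)
  # butadiene: path-graph eigenvalues alpha + 2*beta*cos(pi*k/5)
  phi <- (1 + sqrt(5)) / 2
  pi_d <- extract_pi_system("C=CC=C", P0)
  expect_equal(huckel_solve(pi_d, P0),
               sort(a + c(phi, phi - 1, 1 - phi, -phi) * b),
               tolerance = 1e-9)
})

test_that("naphthalene spectrum matches the textbook coefficients", {
  x <- c(2.30278, 1.61803, 1.30278, 1.00000, 0.61803)
  want <- sort(P0$alpha + c(x, -x) * P0$beta)
  pi_n <- extract_pi_system("c1ccc2ccccc2c1", P0)
  expect_equal(huckel_solve(pi_n, P0), want, tolerance = 1e-4)
})

test_that("frontier orbitals and gaps", {
  pi_b <- extract_pi_system("c1ccccc1", P0)
  fr <- frontier_gap(huckel_solve(pi_b, P0), 6L)
  expect_equal(fr$gap, 2 * abs(P0$beta), tolerance = 1e-12)
  expect_equal(-fr$eps_homo, 9.3, tolerance = 1e-12)
  expect_equal(-fr$eps_lumo, 3.9, tolerance = 1e-12)
  # square cyclobutadiene: degenerate nonbonding pair, zero gap
  fr_cb <- frontier_gap(huckel_solve(extract_pi_system("C1=CC=C1", P0), P0), 4L)
  expect_equal(fr_cb$gap, 0, tolerance = 1e-9)
  # ethylene
  fr_e <- frontier_gap(huckel_solve(extract_pi_system("C=C", P0), P0), 2L)
  expect_equal(fr_e$gap, 2 * abs(P0$beta), tolerance = 1e-12)
  expect_error(frontier_gap(c(-1, 0, 1), 3L), "odd")
  expect_error(frontier_gap(c(-1, 1), 4L), "no LUMO")
})

test_that("heteroatom Hamiltonians use the h/k tables", {
  pi_py <- extract_pi_system("c1ccncc1", P0)
  d <- diag(pi_py$coef)
  expect_equal(sum(abs(d - 0.5) < 1e-12), 1)   # one pyridine N
  expect_equal(sum(d == 0), 5)
  expect_equal(pi_py$n_pi_electrons, 6L)
  # C-N bonds carry k = 0.8
  npos <- which(abs(d - 0.5) < 1e-12)
  expect_equal(unname(pi_py$coef[npos, ][pi_py$coef[npos, ] != 0 &
                                           seq_len(6) != npos][1]), 0.8)
  pi_pyr <- extract_pi_system("c1cc[nH]c1", P0)
  expect_equal(pi_pyr$n_pi_electrons, 6L)
  expect_equal(sum(abs(diag(pi_pyr$coef) - 1.5) < 1e-12), 1)
  pi_fur <- extract_pi_system("c1ccoc1", P0)
  expect_equal(sum(abs(diag(pi_fur$coef) - 2.0) < 1e-12), 1)
})

test_that("Coulson-Rushbrooke pairing for alternant hydrocarbons", {
  alternants <- c("C=C", "C=CC=C", "C=CC=CC=C", "C=CC=CC=CC=C",
                  "c1ccccc1", "c1ccc2ccccc2c1",
                  "c1ccc2cc3ccccc3cc2c1",           # anthracene
                  "c1ccc(-c2ccccc2)cc1",            # biphenyl
                  "C=Cc1ccccc1",                    # styrene
                  "c1ccc(C=Cc2ccccc2)cc1")          # stilbene
  for (smi in alternants) {
    en <- huckel_solve(extract_pi_system(smi, P0), P0)
    # spectrum symmetric about alpha
    expect_equal(sort(en - P0$alpha), sort(-(en - P0$alpha)),
                 tolerance = 1e-9, info = smi)
  }
})

test_that("polyene gap decreases with chain length", {
  chains <- c("C=C", "C=CC=C", "C=CC=CC=C", "C=CC=CC=CC=C")
  gaps <- vapply(chains, function(smi) {
    pi <- extract_pi_system(smi, P0)
    frontier_gap(huckel_solve(pi, P0), pi$n_pi_electrons)$gap
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("molecules without a pi system use the sigma model", {
  expect_null(extract_pi_system("C1CCCCC1", P0))
  o <- oracle_properties("C1CCCCC1", P0)
  expect_equal(o$gap, 11.0)
  expect_equal(o$ea, o$ip - o$gap, tolerance = 1e-12)
  # heteroatom corrections shift the gap
  o2 <- oracle_properties("C1CCCS1", P0)
  expect_equal(o2$gap, 11.0 - 0.6)
})

test_that("disconnected pi systems fill electrons over the union spectrum", {
  # two benzene rings joined by an sp3 spiro-like linker: block-diagonal
  pi <- extract_pi_system("c1ccc(CC2(CCC2)c2ccccc2)cc1", P0)
  expect_equal(pi$n_pi_electrons, 12L)
  en <- huckel_solve(pi, P0)
  fr <- frontier_gap(en, 12L)
  expect_equal(fr$gap, 2 * abs(P0$beta), tolerance = 1e-9)
})

test_that("planted redox maps and their noise behave as configured", {
  p_id <- huckel_params(noise_sd = 0, ox_slope = 1, ox_intercept = -4.28)
  o <- oracle_properties("c1ccccc1", p_id)
  expect_equal(o$eox, o$ip - 4.28, tolerance = 1e-12)

  recs <- tiny_dataset()$records
  l1 <- label_molecules(recs, huckel_params(), seed = 11)
  l2 <- label_molecules(recs, huckel_params(), seed = 11)
  expect_identical(l1, l2)

  l0 <- label_molecules(recs, huckel_params(noise_sd = 0), seed = 11)
  fit <- linear_correlation(l0$ip_eV, l0$eox_V)
  expect_equal(fit$slope, 0.92, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # with noise, the population R2 is slope^2 Var / (slope^2 Var + sd^2)
  big <- do.call(rbind, replicate(20, recs, simplify = FALSE))
  big$mol_id <- sprintf("m%05d", seq_len(nrow(big)))
  ln <- label_molecules(big, huckel_params(noise_sd = 0.15), seed = 12)
  v <- stats::var(ln$ip_eV)
  r2_pop <- 0.92^2 * v / (0.92^2 * v + 0.15^2)
  fitn <- linear_correlation(ln$ip_eV, ln$eox_V)
  expect_equal(fitn$r_squared, r2_pop, tolerance = 0.02)
})

test_that("unsupported elements in the pi system are reported", {
  p_bad <- huckel_params(h_table = list(C = c(one = 0, two = 0)))
  expect_error(extract_pi_system("c1ccncc1", p_bad), "no Coulomb.*N")
})
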