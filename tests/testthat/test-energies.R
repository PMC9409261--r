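test_that("the NFA combination is the signed four-term sum with its invariances", {
  expect_equal(nfa_combine(-100.5, -60.2, -45.3, -5.2), -0.2, tolerance = 1e-12)
  # uniform shifts cancel; the formula is linear in each argument
  withr::with_seed(3, {
    for (k in 1:25) {
      e <- rnorm(4, sd = 50)
      shift <- rnorm(1, sd = 1000)
      expect_equal(nfa_combine(e[1] + shift, e[2] + shift, e[3] + shift, e[4] + shift),
                   nfa_combine(e[1], e[2], e[3], e[4]), tolerance = 1e-9)
      lam <- rnorm(1)
      expect_equal(nfa_combine(lam * e[1], e[2], e[3], e[4]) -
                     nfa_combine(0, e[2], e[3], e[4]),
                   lam * e[1], tolerance = 1e-9)
    }
  })
  expect_error(nfa_combine(NA, 1, 2, 3), "finite")
  expect_error(nfa_combine(Inf, 1, 2, 3), "finite")
  # record form
  expect_equal(nfa_combine(list(e_sys = 1, e_minus_A = 2, e_minus_D = 3,
                                e_minus_AD = 4)), 0)
})

test_that("Coulomb arithmetic matches the hand-computed point-charge case", {
  ff <- forcefield_params(coulomb_constant = 332.0636)
  # unit charges, LJ off: k q1 q2 / r with r chosen so the energy is -100
  e <- helixhb:::pairwise_energy(c(0, 0, 0), 1, NA, c(3.320636, 0, 0), -1, NA, ff)
  expect_equal(e, -100.0, tolerance = 1e-9)
  expect_error(helixhb:::pairwise_energy(c(0, 0, 0), 1, NA, c(0, 0, 0), -1, NA, ff),
               "degenerate")
})

test_that("the peptide-group pair energy sums the 16 cross terms and nothing else", {
  wh <- fixture_helix("310", 4)
  pairs <- detect_hbond_pairs(wh, 3)
  ff <- forcefield_params()
  # zeroed parameters give exactly zero
  ff0 <- ff
  ff0$charges <- lapply(ff0$charges, function(x) x * 0)
  ff0$epsilon <- ff0$epsilon * 0
  expect_identical(mm_pair_energy(wh, pairs[2, ], ff0), 0)
  # independent accumulation over the 8 named atoms
  pr <- pairs[2, ]
  acc <- list(c(pr$acceptor_res, "C"), c(pr$acceptor_res, "O"),
              c(pr$acceptor_res + 1, "N"), c(pr$acceptor_res + 1, "H"))
  don <- list(c(pr$donor_res - 1, "C"), c(pr$donor_res - 1, "O"),
              c(pr$donor_res, "N"), c(pr$donor_res, "H"))
  eref <- 0
  for (i in acc) for (j in don) {
    xi <- helixhb:::atom_xyz(wh, as.integer(i[1]), i[2])
    xj <- helixhb:::atom_xyz(wh, as.integer(j[1]), j[2])
    r <- sqrt(sum((xi - xj)^2))
    qi <- ff$charges$ALA[[i[2]]]
    qj <- ff$charges$ALA[[j[2]]]
    rmin <- unname(ff$rmin2[i[2]] + ff$rmin2[j[2]])
    eps <- unname(sqrt(ff$epsilon[i[2]] * ff$epsilon[j[2]]))
    eref <- eref + ff$coulomb * qi * qj / r + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  expect_equal(mm_pair_energy(wh, pr, ff), eref, tolerance = 1e-12)
})

test_that("the MM backend is deterministic and its NFA equals direct arithmetic on MH", {
  be <- mm_backend()
  wh <- fixture_helix("310", 5)
  expect_identical(be(wh), be(wh))  # bitwise
  ff <- forcefield_params()
  pairs <- detect_hbond_pairs(wh, 3)
  for (i in seq_len(nrow(pairs))) {
    mh <- extract_model(wh, pairs[i, ], "MH")
    fs <- make_nfa_fragments(mh)
    e_nfa <- nfa_combine(be(fs$sys), be(fs$minus_A), be(fs$minus_D), be(fs$minus_AD))
    # direct interaction of the deleted groups: acceptor C=O with donor N-H
    direct <- 0
    for (iat in list(c(0L, "C", "ACE"), c(0L, "O", "ACE"))) {
      for (jat in list(c(3L, "N", "NME"), c(3L, "H", "NME"))) {
        xi <- helixhb:::atom_xyz(mh, as.integer(iat[1]), iat[2])
        xj <- helixhb:::atom_xyz(mh, as.integer(jat[1]), jat[2])
        r <- sqrt(sum((xi - xj)^2))
        qi <- ff$charges[[iat[3]]][[iat[2]]]
        qj <- ff$charges[[jat[3]]][[jat[2]]]
        rmin <- unname(ff$rmin2[iat[2]] + ff$rmin2[jat[2]])
        eps <- unname(sqrt(ff$epsilon[iat[2]] * ff$epsilon[jat[2]]))
        direct <- direct + ff$coulomb * qi * qj / r +
          eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
      }
    }
    expect_lt(abs(e_nfa - direct), 1e-10)
  }
})

test_that("energy tables load, convert units, and validate quadruples", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(model = "m1", fragment = c("sys", "minusA", "minusD", "minusAD"),
                    energy = c(-500.000, -500.001, -500.001, -500.002),
                    unit = "hartree")
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  rec <- load_energy_table(path)
  # 1e-3 hartree differences become 0.6275094740631 kcal/mol
  expect_equal(rec$e_sys - rec$e_minus_A, 0.6275094740631, tolerance = 1e-6)
  expect_equal(nfa_combine(rec), 0, tolerance = 1e-6)

  flat <- tab
  flat$energy <- -1
  flat$unit <- "kcal/mol"
  write.table(flat, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(nfa_combine(load_energy_table(path)), 0)

  dup <- rbind(tab, tab[1, ])
  write.table(dup, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_energy_table(path), "duplicate")

  incomplete <- tab[1:3, ]
  write.table(incomplete, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_energy_table(path), "incomplete|missing")

  weird <- tab
  weird$unit <- "eV"
  write.table(weird, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_energy_table(path), "unit")
})

test_that("the energy pipeline runs per pair and kind, and an additive backend gives zero", {
  wh <- fixture_helix("310", 4)
  expect_identical(nrow(hbond_energy_pipeline(wh, character(0), mm_backend())), 0L)
  # an atom-additive backend has no pair interactions: NFA must return 0
  additive <- function(s) sum(s$atoms$x + 2 * s$atoms$y - s$atoms$z)
  tab <- hbond_energy_pipeline(wh, c("WH", "ST", "MH"), additive)
  expect_identical(nrow(tab), 9L)
  expect_lt(max(abs(tab$e_hb)), 1e-9)
  # with the MM backend, the pairwise decomposition makes WH/ST/MH agree for
  # pairs whose acceptor keeps the same charge role (the cap carbonyl charge
  # differs from the alanine one in the fourth decimal)
  mm_tab <- hbond_energy_pipeline(wh, c("ST", "MH"), mm_backend())
  st <- mm_tab$e_hb[mm_tab$kind == "ST"]
  mh <- mm_tab$e_hb[mm_tab$kind == "MH"]
  expect_equal(st, mh, tolerance = 1e-9)
})
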