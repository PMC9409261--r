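test_that("dihedral measurement matches independent oracles and handles boundaries", {
  # frozen values from an external structural-biology library (float32, 1e-4)
  frozen <- list(
    list(p = list(c(0.345584192064786, 0.8216181435011584, 0.33043707618338714),
                  c(-1.303157231604361, 0.9053558666731177, 0.4463745723640113),
                  c(-0.5369532353602852, 0.5811181041963531, 0.36457239618607573),
                  c(0.294132496655526, 0.02842224131579679, 0.5467129866124469)),
         v = 120.04905),
    list(p = list(c(-0.7364540870016669, -0.16290994799305278, -0.48211931267997826),
                  c(0.5988462126346276, 0.03972210748165899, -0.2924567509650886),
                  c(-0.7819084623568421, -0.2571922406188707, 0.008142180518343508),
                  c(-0.2756029052993704, 1.2940638143982073, 1.0067243153057943)),
         v = -119.08953),
    list(p = list(c(-2.7111624789659685, -1.8890132459676727, -0.17477209205516195),
                  c(-0.42219041157635356, 0.2136429974986111, 0.21732193102256359),
                  c(2.1178387550510482, -1.1120207626922813, -0.37760500712699807),
                  c(2.0427716074923303, 0.6467029962018469, 0.6630633723762617)),
         v = -162.7192))
  for (cs in frozen) {
    expect_equal(dihedral_points(cs$p[[1]], cs$p[[2]], cs$p[[3]], cs$p[[4]]),
                 cs$v, tolerance = 1e-4)
  }
  # in-test projection-formula oracle on random points, 1e-9 degrees
  withr::with_seed(42, {
    for (k in 1:20) {
      p <- lapply(1:4, function(i) rnorm(3))
      expect_equal(dihedral_points(p[[1]], p[[2]], p[[3]], p[[4]]),
                   oracle_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                   tolerance = 1e-9)
    }
  })
  # planar cis -> 0; trans boundary reported as -180
  expect_equal(dihedral_points(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0)
  expect_equal(dihedral_points(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)), -180)
  # collinear triple is degenerate
  expect_error(dihedral_points(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("builder produces the documented atom bookkeeping", {
  for (n in c(1L, 2L, 4L, 7L)) {
    wh <- build_capped_polyalanine(n, -49, -26)
    expect_identical(nrow(wh$atoms), 6L + 10L * n + 6L)
    expect_identical(sort(unique(wh$atoms$residue_index)), 0:(n + 1))
    expect_identical(wh$atoms$residue_name[wh$atoms$residue_index == 0][1], "ACE")
    expect_identical(wh$atoms$residue_name[wh$atoms$residue_index == n + 1][1], "NME")
    for (i in seq_len(n)) {
      nm <- wh$atoms$name[wh$atoms$residue_index == i]
      expect_true(all(c("N", "H", "CA", "C", "O") %in% nm))
    }
  }
  # the n = 1 structure is valid but supports no offset-3 pair
  tiny <- build_capped_polyalanine(1, 0, 0)
  expect_identical(nrow(tiny$atoms), 22L)
  expect_identical(nrow(detect_hbond_pairs(tiny, 3)), 0L)
})

test_that("re-measured dihedrals equal the construction targets", {
  ang_diff <- function(a, b) {
    d <- (a - b) %% 360
    pmin(d, 360 - d)
  }
  cases <- rbind(c(-49, -26), c(-57, -47), c(63.5, 34.25), c(-120, 140))
  for (k in seq_len(nrow(cases))) {
    wh <- build_capped_polyalanine(3, cases[k, 1], cases[k, 2])
    pp <- measure_phi_psi(wh)
    expect_lt(max(ang_diff(pp$phi, cases[k, 1])), 1e-6)
    expect_lt(max(ang_diff(pp$psi, cases[k, 2])), 1e-6)
    expect_lt(max(ang_diff(pp$omega, 180)), 1e-6)
  }
})

test_that("built alanines are L-enantiomers", {
  wh <- fixture_helix("310", 4)
  for (i in 1:4) {
    # N-C-CA-CB improper is near -123 deg for L-amino acids (+123 for D)
    imp <- measure_dihedral(wh, list(list(i, "CB"), list(i, "CA"),
                                     list(i, "N"), list(i, "C")))
    expect_lt(imp, -100)
    expect_gt(imp, -145)
  }
})

test_that("rigid motion leaves internal coordinates unchanged", {
  wh <- fixture_helix("310", 3)
  moved <- transform_structure(wh, random_rotation(7), c(11.2, -3.4, 5.9))
  sel <- list(list(0, "C"), list(1, "N"), list(1, "CA"), list(1, "C"))
  expect_equal(measure_dihedral(moved, sel), measure_dihedral(wh, sel),
               tolerance = 1e-9)
  d0 <- dist(as.matrix(wh$atoms[, c("x", "y", "z")]))
  d1 <- dist(as.matrix(moved$atoms[, c("x", "y", "z")]))
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("invalid construction arguments are rejected", {
  expect_error(build_capped_polyalanine(0, -49, -26), "n_ala")
  expect_error(build_capped_polyalanine(2.5, -49, -26), "n_ala")
  expect_error(geometry_params(b_c_o = 0), "positive")
  expect_error(geometry_params(a_n_ca_c = 190), "angles")
  expect_error(geometry_params(nonsense = 1), "unknown")
})

test_that("PDB write/read round trip preserves the model", {
  wh <- fixture_helix("310", 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(wh, path)
  back <- read_pdb(path)
  expect_identical(back$atoms$name, wh$atoms$name)
  expect_identical(back$atoms$residue_index, wh$atoms$residue_index)
  expect_identical(back$atoms$residue_name, wh$atoms$residue_name)
  dmax <- max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                  as.matrix(wh$atoms[, c("x", "y", "z")])))
  expect_lte(dmax, 5e-4)  # PDB fixed-width 3-decimal precision
  expect_identical(back$n_ala, 4L)
})

test_that("malformed PDB input fails with a line number; missing atoms surface downstream", {
  wh <- fixture_helix("310", 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(wh, path)
  lines <- readLines(path)
  bad <- lines
  i <- which(grepl("^ATOM", bad))[3]
  substr(bad[i], 31, 38) <- "   xx.xx"
  badpath <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, badpath)
  expect_error(read_pdb(badpath), paste0("line ", i))
  # drop the amide H of the 4-2 donor residue (resno 5): parsing succeeds,
  # pair detection reports the missing donor atom
  is_h5 <- grepl("^ATOM", lines) &
    trimws(substr(lines, 13, 16)) == "H" &
    trimws(substr(lines, 23, 26)) == "5"
  expect_identical(sum(is_h5), 1L)
  droppath <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[!is_h5], droppath)
  crippled <- read_pdb(droppath)
  expect_identical(nrow(crippled$atoms), nrow(wh$atoms) - 1L)
  expect_error(detect_hbond_pairs(crippled, 3), "missing")
})
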