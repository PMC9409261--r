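shared_coords_identical <- function(derived, parent) {
  # every derived atom that keeps its (residue, name) identity in the parent
  # must sit at bit-identical coordinates; compares via the original residue
  # window recorded in the derived labels is avoided -- instead match on
  # coordinates of C/O/N/H backbone atoms which are never renamed
  ok <- TRUE
  pa <- parent$atoms
  da <- derived$atoms
  key <- function(a) paste(a$name, round(a$x, 9), round(a$y, 9), round(a$z, 9))
  backbone <- da$name %in% c("C", "O", "N", "H")
  ok <- all(key(da[backbone, ]) %in% key(pa[pa$name %in% c("C", "O", "N", "H"), ]))
  ok
}

test_that("single-turn extraction keeps the turn and converts the pair residues to caps", {
  wh <- fixture_helix("310", 4)
  pairs <- detect_hbond_pairs(wh, 3)
  st <- extract_model(wh, pairs[2, ], "ST")   # pair 4-2
  expect_identical(nrow(st$atoms), 32L)       # Ace-(Ala)2-Nme
  expect_identical(st$n_ala, 2L)
  expect_identical(unique(st$atoms$residue_name[st$atoms$residue_index == 0]), "ACE")
  expect_identical(unique(st$atoms$residue_name[st$atoms$residue_index == 3]), "NME")
  expect_true(shared_coords_identical(st, wh))
  # the target pair maps onto the cap groups and keeps its geometry exactly
  tp <- attr(st, "target_pair")
  expect_identical(c(tp$acceptor_res, tp$donor_res), c(0L, 3L))
  expect_identical(hbond_distance(st, tp), hbond_distance(wh, pairs[2, ]))
})

test_that("minimal-H-bond models are two N-methylacetamide molecules sharing coordinates", {
  wh <- fixture_helix("310", 5)
  pairs <- detect_hbond_pairs(wh, 3)
  for (i in seq_len(nrow(pairs))) {
    mh <- extract_model(wh, pairs[i, ], "MH")
    expect_identical(nrow(mh$atoms), 24L)
    expect_identical(as.integer(table(mh$atoms$residue_index)), rep(6L, 4))
    tp <- attr(mh, "target_pair")
    expect_identical(hbond_distance(mh, tp), hbond_distance(wh, pairs[i, ]))
    expect_true(shared_coords_identical(mh, wh))
  }
})

test_that("extended single-turn windows follow the stated residue extensions", {
  wh <- fixture_helix("310", 7)
  pairs <- detect_hbond_pairs(wh, 3)
  # pair 7-3: acceptor residue 2, donor residue 5
  p3 <- pairs[3, ]
  sizes <- c(ST = 2L, ST_EC = 3L, ST_EN = 3L, ST_ECN = 4L, ST_E2N = 4L)
  for (kind in names(sizes)) {
    m <- extract_model(wh, p3, kind)
    expect_identical(m$n_ala, sizes[[kind]])
    expect_identical(nrow(m$atoms), 12L + 10L * sizes[[kind]])
    expect_true(shared_coords_identical(m, wh))
    expect_identical(hbond_distance(m, attr(m, "target_pair")),
                     hbond_distance(wh, p3))
  }
  # windows that would leave the chain are rejected
  expect_error(extract_model(wh, pairs[1, ], "ST_E2N"), "not derivable")
  expect_error(extract_model(wh, pairs[1, ], "ST_EN"), "not derivable")
  expect_error(extract_model(wh, pairs[6, ], "ST_EC"), "not derivable")
})

test_that("NFA fragment sets keep atom counts and commute", {
  wh <- fixture_helix("310", 4)
  pairs <- detect_hbond_pairs(wh, 3)
  fs <- make_nfa_fragments(wh, pairs[1, ])
  # two atoms deleted, two caps added: counts are preserved
  expect_identical(nrow(fs$minus_A$atoms), nrow(wh$atoms))
  expect_identical(nrow(fs$minus_D$atoms), nrow(wh$atoms))
  expect_identical(nrow(fs$minus_AD$atoms), nrow(wh$atoms))
  expect_false(any(fs$minus_A$atoms$name[fs$minus_A$atoms$residue_index == 0] %in%
                     c("C", "O")))
  # deletion order does not matter, atom for atom
  alt <- helixhb:::delete_group(helixhb:::delete_group(wh, pairs[1, ], "donor"),
                                pairs[1, ], "acceptor")
  reord <- function(a) {
    a <- a[order(a$residue_index, a$name), c("name", "residue_index", "x", "y", "z")]
    rownames(a) <- NULL
    a
  }
  expect_identical(reord(alt$atoms), reord(fs$minus_AD$atoms))
})

test_that("deletion commutes for every pair, model kind, and helix class", {
  for (helix in c("310", "alpha")) {
    off <- if (helix == "310") 3 else 4
    wh <- fixture_helix(helix, 5)
    pairs <- detect_hbond_pairs(wh, off)
    for (i in seq_len(nrow(pairs))) {
      for (kind in c("WH", "ST", "MH")) {
        m <- extract_model(wh, pairs[i, ], kind)
        tp <- attr(m, "target_pair")
        ad1 <- helixhb:::delete_group(helixhb:::delete_group(m, tp, "acceptor"),
                                      tp, "donor")
        ad2 <- helixhb:::delete_group(helixhb:::delete_group(m, tp, "donor"),
                                      tp, "acceptor")
        a1 <- ad1$atoms[order(ad1$atoms$residue_index, ad1$atoms$name), ]
        a2 <- ad2$atoms[order(ad2$atoms$residue_index, ad2$atoms$name), ]
        expect_identical(a1$name, a2$name)
        expect_identical(max(abs(a1$x - a2$x) + abs(a1$y - a2$y) + abs(a1$z - a2$z)), 0)
      }
    }
  }
})

test_that("cap hydrogens sit on the former bond vectors at standard lengths", {
  wh <- fixture_helix("310", 4)
  pairs <- detect_hbond_pairs(wh, 3)
  pr <- pairs[2, ]
  minus_a <- helixhb:::delete_group(wh, pr, "acceptor")
  a <- pr$acceptor_res
  c_old <- helixhb:::atom_xyz(wh, a, "C")
  ca <- helixhb:::atom_xyz(minus_a, a, "CA")
  hx <- helixhb:::atom_xyz(minus_a, a, "HX1")
  expect_equal(sqrt(sum((hx - ca)^2)), 1.090, tolerance = 1e-12)
  # collinear with the severed CA->C bond
  cosang <- sum((hx - ca) * (c_old - ca)) /
    sqrt(sum((hx - ca)^2) * sum((c_old - ca)^2))
  expect_equal(cosang, 1, tolerance = 1e-12)
  hn <- helixhb:::atom_xyz(minus_a, a + 1, "HX1")
  n <- helixhb:::atom_xyz(minus_a, a + 1, "N")
  expect_equal(sqrt(sum((hn - n)^2)), 1.010, tolerance = 1e-12)
})
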