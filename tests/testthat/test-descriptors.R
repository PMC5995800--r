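test_that("ethane yields the single hand-enumerated quadruple", {
  prof <- enumerate_descriptors(parse_smiles("CC"), max_length = 1L,
                                families = list(c("sd1", "ld", "sd2", "bd")))
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$sd1, "-CH3")
  expect_equal(prof$ld, 1L)
  expect_equal(prof$sd2, "-CH3")
  expect_equal(prof$bd, "...")
  expect_equal(prof$count, 1L)
})

test_that("benzene ring and token families match hand enumeration", {
  mol <- parse_smiles("c1ccccc1")
  bare <- enumerate_descriptors(mol, families = list("sd1"))
  expect_equal(sum(bare$count), 7L)  # 6 aromatic carbons + 1 ring entity
  expect_equal(bare$count[bare$sd1 == "CycAr06"], 1L)
  expect_equal(bare$count[bare$sd1 == "-C(Ar)<"], 6L)
  full <- enumerate_descriptors(mol, families = list(c("sd1", "ld", "sd2", "bd")))
  ortho <- full[full$ld %in% 1L & full$sd2 == "-C(Ar)<", ]
  expect_equal(ortho$bd, ".A.")
  expect_equal(ortho$count, 6L)
})

test_that("bond-path codes classify single, pi and aromatic paths", {
  expect_equal(path_bond_code(parse_smiles("CC"), 1, 2), "...")
  expect_equal(path_bond_code(parse_smiles("C=CC"), 1, 3), "p..")
  tol <- parse_smiles("Cc1ccccc1")
  para <- which.max(tol$dist[1, ])
  expect_equal(path_bond_code(tol, 1, para), ".A.")
  # substituent-to-ring-attachment path has no aromatic bond but touches
  # the aromatic system
  etb <- parse_smiles("CCc1ccccc1")
  expect_equal(path_bond_code(etb, 1, 3), ".a.")
  # pi bond on a path ending at the aromatic system
  alb <- parse_smiles("C=CCc1ccccc1")
  expect_equal(path_bond_code(alb, 1, 4), "pA.")
  expect_error(path_bond_code(parse_smiles("CC"), 1, 1), "distinct")
})

test_that("the bare-token family conserves heavy-atom plus ring count", {
  for (smi in c("CCO", "c1ccccc1", "CC(=O)Nc1ccc(O)cc1",
                "C1=CC2=NC3=CC=CC=C3N2C=N1")) {
    mol <- parse_smiles(smi)
    prof <- enumerate_descriptors(mol, families = list("sd1"))
    expect_equal(sum(prof$count), nrow(mol$atoms) + length(mol$rings),
                 label = smi)
  }
})

test_that("projected families are consistent with the full quadruples", {
  mol <- parse_smiles("CC(=O)Nc1ccc(O)cc1")
  full <- enumerate_descriptors(mol, families = list(c("sd1", "ld", "sd2", "bd")))
  proj <- enumerate_descriptors(mol, families = list(c("sd1", "ld", "sd2")))
  # restrict to lengths >= 1 (at length 0 the BD slot is empty, so the
  # full quadruple and its BD-free projection share one key)
  for (r in which(proj$ld >= 1L)) {
    matching <- full$ld %in% proj$ld[r] & full$sd1 == proj$sd1[r] & full$sd2 == proj$sd2[r]
    expect_equal(sum(full$count[matching]), proj$count[r])
  }
  # single-token projections count both ends of every pair
  ends <- enumerate_descriptors(mol, families = list(c("sd1", "ld")))
  for (r in which(ends$ld >= 1L)) {
    same_ld <- full$ld %in% ends$ld[r]
    end_multiplicity <- (full$sd1 == ends$sd1[r]) + (full$sd2 == ends$sd1[r])
    expect_equal(sum(full$count[same_ld] * end_multiplicity[same_ld]), ends$count[r])
  }
})

test_that("total descriptor count is monotone in the length cap", {
  mol <- parse_smiles("CC(=O)Nc1ccc(O)cc1")
  totals <- vapply(0:6, function(L) sum(enumerate_descriptors(mol, max_length = L)$count),
                   numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("isomorphism invariance: alternative SMILES give identical profiles", {
  pairs <- list(
    c("Cc1ccccc1", "c1ccc(C)cc1"),
    c("c1ccncc1", "n1ccccc1"),
    c("CC(=O)O", "OC(C)=O")
  )
  for (pr in pairs) {
    p1 <- enumerate_descriptors(parse_smiles(pr[1], cache = FALSE))
    p2 <- enumerate_descriptors(parse_smiles(pr[2], cache = FALSE))
    expect_equal(descriptor_keys(p1), descriptor_keys(p2), label = pr[1])
    expect_equal(p1$count, p2$count, label = pr[1])
  }
})

test_that("profiles match the independent brute-force enumerator", {
  skip_if_not_installed("igraph")
  for (smi in c("CCO", "C=CC", "c1ccccc1", "Cc1ccccc1", "CC(=O)C",
                "c1cc[nH]c1", "C1CCCCC1", "CC(C)C=O")) {
    mol <- parse_smiles(smi, cache = FALSE)
    got <- profile_instances(enumerate_descriptors(mol))
    want <- brute_profile_keys(mol)
    expect_equal(got, want, label = smi)
  }
})

test_that("invalid family specifications are rejected", {
  mol <- parse_smiles("CC")
  expect_error(enumerate_descriptors(mol, families = list()), "non-empty")
  expect_error(enumerate_descriptors(mol, families = list("sd2")), "sd2 without sd1")
  expect_error(enumerate_descriptors(mol, families = list("xx")), "invalid")
})
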