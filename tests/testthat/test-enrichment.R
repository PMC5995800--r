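test_that("class frequencies follow the occurrence and compound urn models", {
  profiles <- list(
    make_profile("a1", c("X|||", "Y|||"), c(4L, 6L)),   # active
    make_profile("a2", c("X|||"), 2L),                  # active
    make_profile("i1", c("Y|||", "Z|||"), c(5L, 5L))    # inactive
  )
  labels <- c(1L, 1L, 0L)

  occ <- class_frequencies(profiles, labels, mode = "occurrence")
  expect_equal(occ$pa[occ$sd1 == "X"], 6 / 12)   # 6 of 12 active instances
  expect_equal(occ$pi[occ$sd1 == "X"], 0)        # absent from inactive class
  expect_equal(occ$pa[occ$sd1 == "Y"], 6 / 12)
  expect_equal(occ$pi[occ$sd1 == "Y"], 5 / 10)

  cmp <- class_frequencies(profiles, labels, mode = "compound")
  expect_equal(cmp$pa[cmp$sd1 == "X"], 2 / 2)    # both actives contain X
  expect_equal(cmp$pa[cmp$sd1 == "Z"], 0)
  expect_equal(cmp$pi[cmp$sd1 == "Z"], 1 / 1)

  expect_error(class_frequencies(profiles, c(1L, 1L, 1L)), "inactive class")
  expect_error(class_frequencies(profiles, c(0L, 0L, 0L)), "active class")
})

test_that("hypergeometric tail matches hand enumeration and the certain event", {
  # 2 marked among 4, draw 2: P(both marked) = 1/6
  expect_equal(hypergeometric_pr(2, 2, 2, 4, "enriched"), 1 / 6, tolerance = 1e-14)
  expect_equal(hypergeometric_pr(0, 0, 3, 7, "enriched"), 1)
  expect_error(hypergeometric_pr(3, 2, 2, 4), "feasible")
  expect_error(hypergeometric_pr(1, 5, 2, 4), "inconsistent")
})

test_that("hypergeometric tails agree with enumeration and phyper on sampled tuples", {
  tuples <- valid_hyper_tuples(9)
  set.seed(71)
  tuples <- tuples[sample(nrow(tuples), 150), , drop = FALSE]
  for (r in seq_len(nrow(tuples))) {
    k <- unname(tuples[r, "k"]); K <- unname(tuples[r, "K"])
    n <- unname(tuples[r, "n"]); N <- unname(tuples[r, "N"])
    up <- hypergeometric_pr(k, K, n, N, "enriched")
    lo <- hypergeometric_pr(k, K, n, N, "depleted")
    expect_equal(up, brute_hypergeom(k, K, n, N, "enriched"), tolerance = 1e-12)
    expect_equal(lo, brute_hypergeom(k, K, n, N, "depleted"), tolerance = 1e-12)
    expect_equal(up, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
    # tail-sum identity: P(X>=k) + P(X<=k) - P(X=k) = 1
    expect_equal(up + lo - hypergeometric_point(k, K, n, N), 1, tolerance = 1e-12)
  }
})

test_that("the enriched tail is non-increasing in the observed count", {
  for (margins in list(c(6, 10, 20), c(3, 5, 12), c(8, 8, 16))) {
    K <- margins[1]; n <- margins[2]; N <- margins[3]
    ks <- max(0, n - (N - K)):min(K, n)
    tail <- vapply(ks, hypergeometric_pr, numeric(1), total_key = K,
                   n_active = n, n_total = N, direction = "enriched")
    expect_true(all(diff(tail) <= 1e-14))
  }
})

test_that("the presence/absence rule fires exactly per the printed criteria", {
  # published example rows exercise the rule at its boundary
  ex <- data.frame(pa = c(0.2245, 0.2204, 0.5),
                   pi = c(0.2164, 0.2214, 0.1),
                   pr = c(3.79e-2, 4.18e-2, 0.2))
  got <- check_pharmacophore_table(ex)
  expect_equal(got$label, c("presence", "absence", "neutral"))

  # classify_pharmacophores labels are consistent with its own pr
  profiles <- list(make_profile("a", c("X|||", "Y|||"), c(9L, 1L)),
                   make_profile("i", c("X|||", "Y|||"), c(1L, 9L)))
  enr <- classify_pharmacophores(class_frequencies(profiles, c(1L, 0L)), alpha = 0.05)
  expect_true(all((enr$label == "presence") == (enr$pr <= 0.05 & enr$pa > enr$pi)))
  expect_true(all((enr$label == "absence") == (enr$pr <= 0.05 & enr$pi > enr$pa)))
  expect_error(classify_pharmacophores(class_frequencies(profiles, c(1L, 0L)), alpha = 0),
               "alpha")
})

test_that("ties between class frequencies are neutral", {
  profiles <- list(make_profile("a", "X|||", 5L), make_profile("i", "X|||", 5L))
  enr <- classify_pharmacophores(class_frequencies(profiles, c(1L, 0L)))
  expect_equal(enr$label, "neutral")
  expect_equal(enr$pa, enr$pi)
})

test_that("screening flags a planted fragment and keeps shared scaffolds neutral", {
  lib <- gen_library(20, 20, seed = 301)
  enr <- screen_library(lib$molecules, lib$labels)
  marker <- enr[enr$sd1 == lib$marker & enr$sd2 == "" & is.na(enr$ld) & enr$bd == "", ]
  expect_equal(nrow(marker), 1L)
  expect_equal(marker$label, "presence")
  expect_true(marker$pa > marker$pi)

  # identical compound sets in both classes: every key is neutral
  mols <- lapply(c("c1ccc2[nH]cnc2c1", "Cc1ccc2[nH]cnc2c1"), parse_smiles)
  same <- screen_library(c(mols, mols), c(1L, 1L, 0L, 0L))
  expect_true(all(same$label == "neutral"))
  expect_equal(same$pa, same$pi)
})

test_that("Benjamini-Hochberg adjustment can only reduce the flagged set", {
  lib <- gen_library(15, 15, seed = 302)
  plain <- screen_library(lib$molecules, lib$labels)
  bh <- screen_library(lib$molecules, lib$labels, adjust = "BH")
  expect_lte(sum(bh$label != "neutral"), sum(plain$label != "neutral"))
  flagged_bh <- descriptor_keys(bh[bh$label != "neutral", ])
  flagged_plain <- descriptor_keys(plain[plain$label != "neutral", ])
  expect_true(all(flagged_bh %in% flagged_plain))
})
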