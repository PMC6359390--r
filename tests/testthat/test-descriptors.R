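test_that("methantriyl counting follows its definition on small cases", {
  expect_equal(count_methantriyl("CCO"), 0L)       # ethanol
  expect_equal(count_methantriyl("CC(C)C"), 1L)    # isobutane
  expect_equal(count_methantriyl("c1ccccc1"), 0L)  # aromatic CH excluded
  expect_equal(count_methantriyl(quinolones()$CIP), 1L)
  expect_equal(count_methantriyl(quinolones()$MOX), 3L)
})

test_that("stereo atom counting includes unassigned potential centres", {
  expect_equal(count_stereo_atoms("C[C@@H](O)CC"), 1L)  # (R)-butan-2-ol
  expect_equal(count_stereo_atoms("CC(O)CC"), 1L)       # racemic, same
  expect_equal(count_stereo_atoms("CC(C)C"), 0L)
  expect_equal(count_stereo_atoms(quinolones()$CIP), 0L)
  expect_equal(count_stereo_atoms(quinolones()$ORB), 2L)
})

test_that("E-state indices reproduce the hand-computed isobutane value", {
  # 4-atom graph: I(CH) = 4/3, I(CH3) = 2; three perturbations
  # (4/3 - 2)/(1+1)^2 give S(CH) = 4/3 - 1/2 = 5/6.
  es <- estate_indices("CC(C)C")
  central <- which(es$methantriyl)
  expect_length(central, 1L)
  expect_equal(es$estate[central], 5 / 6, tolerance = 1e-12)
  expect_equal(sum_estate_methantriyl("CC(C)C"), 5 / 6, tolerance = 1e-12)
})

test_that("single-atom molecules degenerate to the intrinsic state", {
  es <- estate_indices("C")
  expect_true(es$degenerate)
  expect_equal(es$estate, es$intrinsic)
})

test_that("E-state perturbations conserve: sum(S - I) = 0", {
  for (id in c("CIP", "GAR", "RUF", "TOZ", "PIP")) {
    es <- estate_indices(quinolones()[[id]])
    expect_equal(sum(es$estate - es$intrinsic), 0, tolerance = 1e-9)
  }
})

test_that("molecules with no methantriyl carbon score S(>CH-) = 0", {
  expect_equal(sum_estate_methantriyl(quinolones()$NAL), 0)
  expect_equal(sum_estate_methantriyl(quinolones()$DIF), 0)
})

test_that("graph descriptors are invariant to SMILES atom ordering and
           explicit hydrogens", {
  variants <- c(
    "OC(=O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O",     # bundled CIP
    "C1CN(CCN1)c1cc2c(cc1F)c(=O)c(C(O)=O)cn2C1CC1")   # reordered CIP
  ref <- c(count_methantriyl(variants[1]),
           count_stereo_atoms(variants[1]),
           sum_estate_methantriyl(variants[1]))
  got <- c(count_methantriyl(variants[2]),
           count_stereo_atoms(variants[2]),
           sum_estate_methantriyl(variants[2]))
  expect_equal(got, ref, tolerance = 1e-9)

  iso_h <- "C([H])([H])([H])C([H])(C([H])([H])[H])C([H])([H])[H]"
  expect_equal(count_methantriyl(iso_h), 1L)
  expect_equal(sum_estate_methantriyl(iso_h), 5 / 6, tolerance = 1e-12)
})

test_that("computed count descriptors match the supplied table exactly", {
  d <- compute_descriptors(quinolones(),
                           c("N(>CH-)", "N(Stereo)", "S(>CH-)"))
  t2 <- load_descriptor_table("table2")
  expect_equal(d[rownames(t2), "N(>CH-)"], t2[, "N(>CH-)"],
               ignore_attr = TRUE)
  expect_equal(d[rownames(t2), "N(Stereo)"], t2[, "N(Stereo)"],
               ignore_attr = TRUE)
  expect_equal(unname(attr(d, "provenance")["S(>CH-)"]), "computed")
})

test_that("preprocessing drops constant, sparse and correlated columns", {
  t2 <- load_descriptor_table("table2")
  y <- log_activities(load_cr_table("table1_cli"))
  x <- cbind(t2, constant = 1,
             rare = c(5, rep(0, nrow(t2) - 1)))
  x <- descriptor_matrix(x)
  out <- preprocess_descriptors(x, y, sparse_frac = 0.1, r_cut = 0.5)
  expect_equal(out$report$dropped_constant, "constant")
  expect_equal(out$report$dropped_sparse, "rare")
  # the two count descriptors are correlated above 0.5 across the table;
  # exactly one of them must be dropped and the pair reported
  dc <- out$report$dropped_correlated
  pair_rows <- dc$kept %in% c("N(>CH-)", "N(Stereo)") &
    dc$dropped %in% c("N(>CH-)", "N(Stereo)")
  expect_true(any(pair_rows))
  expect_gt(abs(dc$r[pair_rows][1]), 0.5)
  expect_equal(sum(c("N(>CH-)", "N(Stereo)") %in% colnames(out$matrix)), 1L)
})

test_that("preprocessing keeps the member more correlated with activity", {
  withr::with_seed(4, {
    z <- rnorm(30)
    x <- descriptor_matrix(cbind(good = z + rnorm(30, 0, 0.1),
                                 bad = z + rnorm(30, 0, 0.1)) |>
                             `rownames<-`(sprintf("c%02d", 1:30)))
    y <- setNames(x[, "good"] * 2 + rnorm(30, 0, 0.05), rownames(x))
    out <- preprocess_descriptors(x, y, r_cut = 0.5)
    expect_equal(colnames(out$matrix), "good")
    expect_equal(out$report$dropped_correlated$dropped, "bad")
  })
})

test_that("an r_cut of 1 disables correlation filtering", {
  t2 <- load_descriptor_table("table2")
  y <- log_activities(load_cr_table("table1_cli"))
  out <- preprocess_descriptors(t2, y, r_cut = 1)
  expect_equal(ncol(out$matrix), 4L)
  expect_equal(nrow(out$report$dropped_correlated), 0L)
})

test_that("dropping every column is an error", {
  x <- descriptor_matrix(matrix(1, 5, 2,
                                dimnames = list(letters[1:5], c("a", "b"))))
  y <- setNames(rnorm(5), letters[1:5])
  expect_error(preprocess_descriptors(x, y), "all descriptor columns")
})
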