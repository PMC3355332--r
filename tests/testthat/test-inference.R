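test_that("legal genotype sets follow linkage and sex", {
  expect_setequal(legal_genotypes(c("C", "T"), "autosomal", "female"),
                  c("C/C", "C/T", "T/T"))
  expect_setequal(legal_genotypes(c("C", "T"), "x_linked", "male"),
                  c("C/-", "T/-"))
  expect_setequal(legal_genotypes(c("C", "T"), "x_linked", "unknown"),
                  c("C/C", "C/T", "T/T", "C/-", "T/-"))
  expect_setequal(legal_genotypes(c("C", "T"), "z_linked", "female"),
                  c("C/-", "T/-"))
  # 3 alleles: 6 diploid genotypes
  expect_length(legal_genotypes(c("A", "C", "T")), 6L)
})

test_that("transmissible alleles honor hemizygous null transmission", {
  al <- c("C", "T")
  expect_setequal(transmissible_alleles("C/T", al, "autosomal", "sire", "male"),
                  c("C", "T"))
  # x-linked sire: Y-null to sons, his X to daughters
  expect_equal(transmissible_alleles("C/-", al, "x_linked", "sire", "male"), "-")
  expect_equal(transmissible_alleles("C/-", al, "x_linked", "sire", "female"),
               "C")
  # z-linked dam: W-null to daughters, her Z to sons
  expect_equal(transmissible_alleles("T/-", al, "z_linked", "dam", "female"),
               "-")
  expect_equal(transmissible_alleles("T/-", al, "z_linked", "dam", "male"), "T")
  # unknown child sex: union over both sexes
  expect_setequal(transmissible_alleles("C/-", al, "x_linked", "sire",
                                        "unknown"), c("C", "-"))
  # unconstrained parent: the full alphabet
  expect_setequal(transmissible_alleles("*", al, "autosomal", "dam", "female"),
                  al)
})

test_that("forced inference resolves a missing child and a missing sire", {
  ped <- make_trio()
  # sire C/C x dam T/T -> child must be C/T
  mat <- trio_genotypes(ped, list(F = "C/C", M = "T/T"))
  pr <- propagate_marker(ped, mat, "mk1")
  expect_equal(pr$candidates$C, "C/T")
  expect_false(any(pr$conflicted))

  # child C/C, dam C/T, sire missing -> sire must carry a C
  mat <- trio_genotypes(ped, list(C = "C/C", M = "C/T"))
  pr <- propagate_marker(ped, mat, "mk1")
  expect_setequal(pr$candidates$F, c("C/C", "C/T"))
})

test_that("partial calls constrain inference as one known allele", {
  ped <- make_trio()
  mat <- trio_genotypes(ped, list(F = "T/?", M = "C/C", C = "T/T"))
  pr <- propagate_marker(ped, mat, "mk1")
  # child is T/T so the sire transmitted a T; partial already says T
  expect_setequal(pr$candidates$F, c("T/T", "C/T"))
})

test_that("propagation equals whole-pedigree enumeration on random pedigrees", {
  # genotype elimination is exact on tree pedigrees; checked against an
  # independent brute-force oracle over autosomal and sex-linked markers
  n_checked <- 0L
  for (s in 1:60) {
    ped <- random_tree_pedigree(8, seed = s)
    set.seed(s)
    linkage <- sample(c("autosomal", "autosomal", "x_linked", "z_linked"), 1)
    alleles <- if (stats::runif(1) < 0.5) c("C", "T") else c("A", "C", "T")
    mat <- random_marker_dataset(ped, alleles, linkage, seed = s)
    pr <- propagate_marker(ped, mat, "mk1")
    expect_false(any(pr$conflicted)) # data is consistent by construction
    or <- oracle_candidate_sets(ped, mat, "mk1")
    for (id in ped$ind$id) {
      expect_setequal(pr$candidates[[id]], or[[id]])
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 300L)
})

test_that("candidate sets are deterministic and marker-order independent", {
  ped <- eval_pedigree()
  mat <- gene_drop(ped, copies = 2, seed = 5)
  mat <- erase_generation(mat, ped, 1, 0.5, seed = 5)
  pr1 <- propagate_marker(ped, mat, "auto_ct_1_1_2")
  pr2 <- propagate_marker(ped, mat, "auto_ct_1_1_2")
  expect_identical(pr1, pr2)
  # permute the marker columns: per-marker results unchanged
  perm <- rev(seq_len(nrow(mat$markers)))
  mat2 <- genotype_matrix(mat$ids, mat$markers[perm, , drop = FALSE],
                          mat$a1[, perm, drop = FALSE],
                          mat$a2[, perm, drop = FALSE])
  pr3 <- propagate_marker(ped, mat2, "auto_ct_1_1_2")
  expect_identical(pr1$candidates, pr3$candidates)
})

test_that("contradictory facts conflict the silent intermediate, not the facts", {
  # grandparents force the dam to be C/C, but her observed child carries a
  # maternal T: the erased dam is marked conflicted and reset towards her
  # parents; the observed genotypes are never touched
  ped <- pedigree(c("GS", "GD", "S", "D", "K"),
                  sire = c(NA, NA, NA, "GS", "S"),
                  dam = c(NA, NA, NA, "GD", "D"),
                  sex = c("male", "female", "male", "female", "unknown"))
  mat <- trio_genotypes(ped, list(GS = "C/C", GD = "C/C", S = "T/T",
                                  K = "T/T"))
  pr <- propagate_marker(ped, mat, "mk1")
  expect_true(pr$conflicted[["D"]])
  expect_equal(pr$candidates$K, "T/T")
  expect_equal(pr$candidates$D, "C/C") # anchored to her parents' side
})

test_that("partial genotype labels render at bi- and multi-allelic markers", {
  expect_equal(render_partial("C/T", c("C", "T")), "C/T")
  expect_equal(render_partial(c("T/T", "C/T"), c("C", "T")), "T/?")
  expect_equal(render_partial(c("C/C", "C/T", "T/T"), c("C", "T")), "?/?")
  # multi-allelic bracket form: slots {A,T} x {A,C,T}
  cand <- c("A/A", "A/C", "A/T", "C/T", "T/T")
  expect_equal(render_partial(cand, c("A", "C", "T")),
               "[A or T]/[A or C or T]")
  # hemizygous: known null slot
  expect_equal(render_partial(c("C/-", "T/-"), c("C", "T")), "-/?")
})
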