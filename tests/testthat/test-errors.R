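test_that("classification implements the three error categories", {
  expect_equal(unname(classify_call(c("C", "T"), "C", "T")),
               c(FALSE, FALSE, FALSE))
  # hemizygous male scored homozygous: nil from sire only
  fl <- classify_call(c("C", "C"), t_sire = "-", t_dam = c("C", "T"))
  expect_equal(unname(fl), c(TRUE, FALSE, FALSE))
  # allele from neither parent: all three
  fl <- classify_call(c("A", "A"), t_sire = c("C", "T"), t_dam = "C")
  expect_equal(unname(fl), c(TRUE, TRUE, TRUE))
  # shared allele missing from sire only, no novel allele
  fl <- classify_call(c("C", "T"), t_sire = "G", t_dam = c("C", "T"))
  expect_equal(unname(fl), c(TRUE, FALSE, FALSE))
  expect_error(classify_call(c("C", "T"), character(), "C"), "nonempty")
})

test_that("nil-from-both-parents without a novel allele is unattainable", {
  # fuzz over random draws from a 3-symbol alphabet plus exhaustive
  # enumeration of all (child pair, sire set, dam set) combinations
  syms <- c("A", "B", "C")
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(syms, k, simplify = FALSE)), recursive = FALSE)
  pairs <- expand.grid(a = syms, b = syms, stringsAsFactors = FALSE)
  combos <- character()
  for (p in seq_len(nrow(pairs))) for (ts in subsets) for (td in subsets) {
    fl <- classify_call(c(pairs$a[p], pairs$b[p]), ts, td)
    expect_false(fl[["nil_from_sire"]] && fl[["nil_from_dam"]] &&
                   !fl[["novel_allele"]])
    if (any(fl)) combos <- c(combos, paste(as.integer(fl), collapse = ""))
  }
  # exactly six attainable non-empty flag combinations
  expect_length(unique(combos), 6L)

  set.seed(99)
  for (i in 1:10000) {
    ca <- sample(syms, 2, TRUE)
    ts <- sample(syms, sample(3, 1))
    td <- sample(syms, sample(3, 1))
    fl <- classify_call(ca, ts, td)
    expect_false(fl[["nil_from_sire"]] && fl[["nil_from_dam"]] &&
                   !fl[["novel_allele"]])
  }
})

test_that("severity bins are zero-anchored thirds of the view maximum", {
  expect_equal(severity_bin(0, 10), 0L)
  expect_equal(severity_bin(10, 10), 3L)
  expect_equal(severity_bin(1, 3), 1L)
  expect_equal(severity_bin(2, 3), 2L)
  expect_equal(severity_bin(3, 3), 3L)
  expect_equal(severity_bin(0, 0), 0L)
  expect_equal(severity_bin(c(0, 1, 4, 9), 9), c(0L, 1L, 2L, 3L))
})

test_that("gene-dropped datasets check clean for any seed", {
  for (s in c(3, 11, 27)) {
    ped <- sim_pedigree(3, 3, offspring_per_family = 4,
                        unsexed_fraction = 0.2, seed = s)
    mat <- gene_drop(ped, copies = 3, seed = s)
    rep <- check_dataset(ped, mat)
    expect_equal(sum(rep$individuals$total), 0)
  }
})

test_that("fast and slow classification paths agree", {
  # force the whole dataset down the propagation path by erasing one cell of
  # an isolated individual, then compare the shared fully observed columns
  ped <- eval_pedigree()
  mat <- gene_drop(ped, copies = 2, seed = 13)
  inj <- inject_genotype(mat, ped, 3, seed = 13)
  bad <- inj$genotypes
  rep_fast <- check_dataset(ped, bad)
  bad_slow <- bad
  # erase a founder's calls: founders are never classified, but the columns
  # now contain missing data and take the fixpoint path
  bad_slow$a1["S3", ] <- "?"
  bad_slow$a2["S3", ] <- "?"
  rep_slow <- check_dataset(ped, bad_slow)
  keep <- setdiff(rownames(rep_fast$nil_from_sire), c("S3"))
  # S3's own children may gain leniency from the erased founder, everyone
  # else must classify identically
  unaffected <- setdiff(keep, relatives(ped, "S3", "descendants"))
  expect_identical(rep_fast$nil_from_sire[unaffected, ],
                   rep_slow$nil_from_sire[unaffected, ])
  expect_identical(rep_fast$nil_from_dam[unaffected, ],
                   rep_slow$nil_from_dam[unaffected, ])
  expect_identical(rep_fast$novel_allele[unaffected, ],
                   rep_slow$novel_allele[unaffected, ])
})

test_that("error-free founders and inferred cells yield unflagged findings", {
  ped <- make_trio()
  mat <- trio_genotypes(ped, list(F = "C/C", M = "T/T"))
  rep <- check_dataset(ped, mat)
  ff <- findings(rep)
  expect_equal(nrow(ff), 3L)
  expect_false(any(ff$nil_from_sire | ff$nil_from_dam | ff$novel_allele))
  expect_true(ff$inferred[ff$individual == "C"])
  # flagged and inferred are mutually exclusive by construction
  ff2 <- findings(rep, flagged_only = TRUE)
  expect_equal(nrow(ff2), 0L)
})

test_that("checking refuses to run on an invalid pedigree", {
  p <- pedigree(c("A", "B", "C"), sire = c(NA, NA, "A"), dam = c(NA, NA, "B"),
                sex = c("female", "female", NA))
  mat <- genotype_matrix(p$ind$id, marker_def("m1", list(c("C", "T"))))
  expect_error(check_dataset(p, mat), "SEX_ROLE_CONFLICT")
})

test_that("aggregates sum consistently across views", {
  ped <- eval_pedigree()
  mat <- gene_drop(ped, copies = 3, seed = 21)
  inj <- inject_genotype(mat, ped, 5, seed = 21)
  rep <- check_dataset(ped, inj$genotypes)
  # marker totals and individual totals both sum to the grid totals
  expect_equal(sum(rep$individuals$nil_from_sire), sum(rep$nil_from_sire))
  expect_equal(sum(rep$markers$nil_from_sire), sum(rep$nil_from_sire))
  # family counts are the sums over their members
  fams <- derive_families(ped)$families
  for (key in rep$families$key) {
    members <- fams[[key]]$children
    rows <- match(members, rep$individuals$id)
    expect_equal(rep$families$total[rep$families$key == key],
                 sum(rep$individuals$total[rows]))
  }
})

test_that("single-marker states are exhaustive and mutually exclusive", {
  ped <- eval_pedigree()
  mat <- gene_drop(ped, copies = 1, seed = 31)
  inj <- inject_genotype(mat, ped, 5, seed = 31)
  bad <- erase_generation(inj$genotypes, ped, 1, 0.4, seed = 31)
  rep <- check_dataset(ped, bad)
  err <- rep$nil_from_sire | rep$nil_from_dam | rep$novel_allele
  # a cell is never both flagged and inferred
  expect_false(any(err & rep$inferred))
})

test_that("JSON report serializes findings and aggregate tables", {
  ped <- make_trio()
  mat <- trio_genotypes(ped, list(F = "C/C", M = "C/C", C = "T/T"))
  rep <- check_dataset(ped, mat)
  js <- jsonlite::fromJSON(report_to_json(rep))
  expect_named(js, c("findings", "individuals", "markers", "families"))
  expect_equal(js$findings$individual, "C")
  expect_true(js$findings$novel_allele)
})
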