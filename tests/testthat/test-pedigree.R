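test_that("native TSV parsing loads trios and normalizes sex codes", {
  txt <- c("id\tsire\tdam\tsex",
           "# a comment",
           "F\t\t\tM",
           "M\t\t\tF",
           "C\tF\tM\t")
  ped <- read_pedigree(txt)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped$ind), 3L)
  expect_equal(ped$ind$sex, c("male", "female", "unknown"))
  expect_equal(ped$ind$sire[3L], "F")
  expect_equal(ped$ind$dam[3L], "M")
  expect_true(all(is.na(ped$ind$sire[1:2])))
})

test_that("malformed rows and duplicate ids are rejected at parse time", {
  expect_error(read_pedigree(c("id\tsire\tdam\tsex", "A\tB")), "line 2")
  expect_error(read_pedigree(c("id\tsire\tdam\tsex", "A\t\t\tM", "A\t\t\tF")),
               "duplicate")
  expect_error(read_pedigree(c("id\tsire\tdam", "A\t\t")), "header")
})

test_that("PLINK PED import maps parent and sex codes", {
  txt <- c("FAM1 F 0 0 1 C C", "FAM1 M 0 0 2 C T", "FAM1 C F M 0 T T")
  ped <- read_pedigree(txt, dialect = "plink_ped")
  expect_equal(ped$ind$id, c("F", "M", "C"))
  expect_equal(ped$ind$sex, c("male", "female", "unknown"))
  expect_true(is.na(ped$ind$sire[1L]))
  expect_equal(ped$ind$sire[3L], "F")
})

test_that("pedigree writer round-trips through the parser", {
  ped <- eval_pedigree()
  txt <- write_pedigree(ped)
  ped2 <- read_pedigree(txt)
  expect_identical(ped$ind, ped2$ind)
})

test_that("validation flags each issue class and accepts a clean trio", {
  expect_equal(nrow(validate_pedigree(make_trio())), 0L)

  # unknown parent
  p <- pedigree(c("A", "B"), sire = c(NA, "ghost"), dam = NA)
  iss <- validate_pedigree(p)
  expect_equal(iss$code, "UNKNOWN_PARENT")
  expect_equal(iss$subject_id, "ghost")

  # sex-role conflict: female referenced as sire
  p <- pedigree(c("A", "B", "C"), sire = c(NA, NA, "A"), dam = c(NA, NA, "B"),
                sex = c("female", "female", NA))
  iss <- validate_pedigree(p)
  expect_true(any(iss$code == "SEX_ROLE_CONFLICT" & iss$subject_id == "A"))

  # unsexed individuals may parent without conflict
  p <- pedigree(c("A", "B", "C"), sire = c(NA, NA, "A"), dam = c(NA, NA, "B"),
                sex = "unknown")
  expect_false(any(validate_pedigree(p)$code == "SEX_ROLE_CONFLICT"))

  # dual role
  p <- pedigree(c("A", "B", "C", "D"), sire = c(NA, NA, "A", "B"),
                dam = c(NA, NA, "B", "A"), sex = "unknown")
  iss <- validate_pedigree(p)
  expect_setequal(iss$subject_id[iss$code == "DUAL_ROLE"], c("A", "B"))

  # self-parenting is a cycle
  p <- pedigree(c("A", "B"), sire = c("A", NA), dam = NA, sex = "unknown")
  expect_true(any(validate_pedigree(p)$code == "CYCLE"))

  # longer ancestry cycle
  p <- pedigree(c("A", "B", "C"), sire = c("C", "A", "B"), dam = NA,
                sex = "unknown")
  expect_true(all(validate_pedigree(p)$code == "CYCLE"))
})

test_that("create_missing_founders materializes referenced parents", {
  txt <- c("id\tsire\tdam\tsex", "C\tF\tM\tU")
  ped <- read_pedigree(txt, create_missing_founders = TRUE)
  expect_setequal(ped$ind$id, c("C", "F", "M"))
  expect_equal(nrow(validate_pedigree(ped)), 0L)
})

test_that("generation assignment follows the longest path and lifts late founders", {
  expect_equal(assign_generations(make_trio()),
               c(F = 0L, M = 0L, C = 1L))
  chain <- pedigree(c("A", "B", "C"), sire = c(NA, "A", "B"), dam = NA,
                    sex = "unknown")
  expect_equal(assign_generations(chain), c(A = 0L, B = 1L, C = 2L))

  # late founder X mated to a generation-1 dam displays at generation 1
  p <- pedigree(c("S", "D", "B", "X", "K"),
                sire = c(NA, NA, "S", NA, "X"),
                dam = c(NA, NA, "D", NA, "B"),
                sex = c("male", "female", "female", "male", "unknown"))
  g <- assign_generations(p)
  expect_equal(unname(g["X"]), 1L)
  expect_equal(unname(g["K"]), 2L)
  # children always sit strictly below each present parent
  for (i in seq_len(nrow(p$ind))) {
    for (par in stats::na.omit(c(p$ind$sire[i], p$ind$dam[i])))
      expect_gt(g[[p$ind$id[i]]], g[[par]])
  }
})

test_that("generation mapping is a topological grading on generated pedigrees", {
  for (s in 1:5) {
    ped <- sim_pedigree(n_generations = 4, families_per_generation = 3,
                        offspring_per_family = 4, unsexed_fraction = 0.3,
                        seed = s)
    g <- assign_generations(ped)
    ind <- ped$ind
    for (i in seq_len(nrow(ind))) {
      for (par in stats::na.omit(c(ind$sire[i], ind$dam[i])))
        expect_gt(g[[ind$id[i]]], g[[par]])
    }
  }
})

test_that("families partition non-founders; sire-sib sets union over partners", {
  p <- pedigree(c("S", "D1", "D2", "a", "b", "c", "d"),
                sire = c(NA, NA, NA, "S", "S", "S", "S"),
                dam = c(NA, NA, NA, "D1", "D1", "D2", "D2"),
                sex = c("male", "female", "female", rep("unknown", 4)))
  fam <- derive_families(p)
  expect_length(fam$families, 2L)
  expect_setequal(fam$sire_index$S, c("a", "b", "c", "d"))
  # partition: total family sizes == non-founders
  expect_equal(sum(lengths(lapply(fam$families, `[[`, "children"))), 4L)

  # a dam mothering two families appears in two family records
  dams <- vapply(fam$families, `[[`, "", "dam")
  p2 <- eval_pedigree()
  fam2 <- derive_families(p2)
  expect_equal(sum(vapply(fam2$families, `[[`, "", "sire") == "A3"), 2L)
})

test_that("litter tags partition family children; untagged families form one litter", {
  p <- pedigree(c("S", "D", "a", "b", "c"),
                sire = c(NA, NA, "S", "S", "S"),
                dam = c(NA, NA, "D", "D", "D"),
                sex = "unknown", litter = c(NA, NA, "x", "x", "y"))
  f <- derive_families(p)$families[[1L]]
  expect_equal(sort(unname(lengths(f$litters))), c(1L, 2L))
  p2 <- pedigree(c("S", "D", "a"), c(NA, NA, "S"), c(NA, NA, "D"), "unknown")
  f2 <- derive_families(p2)$families[[1L]]
  expect_length(f2$litters, 1L)
})

test_that("ancestors and descendants are mutually consistent closures", {
  ped <- sim_pedigree(n_generations = 3, families_per_generation = 4,
                      offspring_per_family = 4, seed = 7)
  expect_error(relatives(ped, "nope"), "unknown")
  ids <- ped$ind$id
  for (x in ids[seq(1, length(ids), by = 5)]) {
    for (y in relatives(ped, x, "descendants"))
      expect_true(x %in% relatives(ped, y, "ancestors"))
  }
  # brute-force reachability oracle on the child map
  kids_of <- split(rep(ids, 2L), c(ped$ind$sire, ped$ind$dam))
  bfs <- function(x) {
    seen <- character(); frontier <- x
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(kids_of[frontier])), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    sort(seen)
  }
  for (x in ids[seq(1, length(ids), by = 7)])
    expect_equal(relatives(ped, x, "descendants"), bfs(x))
})
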