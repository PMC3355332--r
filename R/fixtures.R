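# Packaged evaluation fixtures: deterministic pedigrees plus a registry of
# corruption scenarios with machine-checkable expected error patterns.

#' A hand-built three-generation evaluation pedigree
#'
#' A 55-individual cross designed so that every injection category has
#' eligible targets: sires with multiple partners, two breeding full sisters
#' (`A1`, `A2`) sharing the mate `B1`, breeding paternal half-sisters,
#' tagged litters, and unsexed non-breeders. Founders are `S1..S3` (sires)
#' and `D1..D6` (dams); F1 ids are letter-prefixed; F2 ids are `P01..P28`.
#'
#' @return a [pedigree] that validates cleanly.
#' @export
eval_pedigree <- function() {
  f1 <- list(
    # sire, dam, ids, sexes, litters
    list("S1", "D1", c("A1", "A2", "A3", "A4"), c("F", "F", "M", "U"),
         c("L1", "L1", "L2", "L2")),
    list("S1", "D2", c("B1", "B2", "B3"), c("M", "F", "U"), NA),
    list("S2", "D3", c("C1", "C2", "C3"), c("M", "F", "F"), NA),
    list("S2", "D4", c("E1", "E2"), c("M", "F"), NA),
    list("S3", "D5", c("G1", "G2", "G3", "G4"), c("M", "F", "U", "F"), NA),
    list("S3", "D6", c("H1", "H2"), c("M", "F"), NA))
  f2 <- list(
    list("A3", "C2", c("P01", "P02", "P03", "P04"), c("M", "F", "U", "F"),
         c("L1", "L1", "L2", "L2")),
    list("A3", "E2", c("P05", "P06", "P07"), c("F", "M", "F"), NA),
    list("B1", "A1", c("P08", "P09", "P10", "P11"), c("M", "F", "F", "U"), NA),
    list("B1", "A2", c("P12", "P13", "P14", "P15"), c("F", "M", "F", "F"), NA),
    list("C1", "G2", c("P16", "P17", "P18", "P19"), c("M", "F", "M", "F"), NA),
    list("E1", "G4", c("P20", "P21", "P22"), c("F", "F", "M"), NA),
    list("G1", "B2", c("P23", "P24", "P25"), c("M", "U", "F"), NA),
    list("H1", "C3", c("P26", "P27", "P28"), c("F", "M", "F"), NA))
  founders <- data.frame(
    id = c(paste0("S", 1:3), paste0("D", 1:6)),
    sire = NA_character_, dam = NA_character_,
    sex = rep(c("M", "F"), c(3L, 6L)), litter = NA_character_,
    stringsAsFactors = FALSE)
  fam_rows <- function(f) data.frame(
    id = f[[3L]], sire = f[[1L]], dam = f[[2L]], sex = f[[4L]],
    litter = if (all(is.na(f[[5L]]))) NA_character_ else f[[5L]],
    stringsAsFactors = FALSE)
  all <- rbind(founders, do.call(rbind, lapply(c(f1, f2), fam_rows)))
  pedigree(all$id, all$sire, all$dam, all$sex, all$litter)
}

#' A chicken-style female-skewed F2 mapping pedigree
#'
#' Deterministically builds a three-generation pedigree with the generation
#' and sex composition of a commercial chicken F2 mapping population:
#' 76 founders (28 male, 48 female), 118 F1 (16 male, 102 female) and 1598
#' all-female F2, 1792 individuals in total. All F1 individuals breed (the
#' 16 males take multiple partners); the seed shuffles which F1 children are
#' male.
#'
#' @param seed integer seed.
#' @return a [pedigree].
#' @export
chicken_pedigree <- function(seed = 1) {
  f0_sires <- sprintf("F0M%02d", 1:28)
  f0_dams <- sprintf("F0F%02d", 1:48)
  # 48 F0 families: each dam once, sires round-robin
  f1_ids <- sprintf("F1X%03d", 1:118)
  f1_sire <- f0_sires[(seq_len(48) - 1L) %% 28L + 1L]
  fam_of_f1 <- (seq_len(118) - 1L) %% 48L + 1L
  f1_sex <- rep("F", 118)
  f1_sex[with_seed(seed, sample(118, 16))] <- "M"
  f1_males <- f1_ids[f1_sex == "M"]
  f1_females <- f1_ids[f1_sex == "F"]
  # 102 F1 families: each F1 female once, F1 males round-robin
  f2_ids <- sprintf("F2X%04d", 1:1598)
  f2_sire_of_fam <- f1_males[(seq_len(102) - 1L) %% 16L + 1L]
  fam_of_f2 <- (seq_len(1598) - 1L) %% 102L + 1L
  all <- rbind(
    data.frame(id = c(f0_sires, f0_dams), sire = NA_character_,
               dam = NA_character_, sex = rep(c("M", "F"), c(28L, 48L)),
               stringsAsFactors = FALSE),
    data.frame(id = f1_ids, sire = f1_sire[fam_of_f1],
               dam = f0_dams[fam_of_f1], sex = f1_sex,
               stringsAsFactors = FALSE),
    data.frame(id = f2_ids, sire = f2_sire_of_fam[fam_of_f2],
               dam = f1_females[fam_of_f2], sex = "F",
               stringsAsFactors = FALSE))
  pedigree(all$id, all$sire, all$dam, all$sex)
}

# ---- scenario registry -----------------------------------------------------

scenario_env <- new.env(parent = emptyenv())

desc_set <- function(ped, ids)
  unique(unlist(lapply(ids, relatives, ped = ped, direction = "descendants")))

register_scenario <- function(name, kind, category = NA, erasure = 0,
                              targets = NULL, expected, expect) {
  scenario_env[[name]] <- list(name = name, kind = kind, category = category,
                               erasure = erasure, targets = targets,
                               expected = expected, expect = expect)
}

# standard predicates (ctx: report, ped, truth, gen, error)
exp_confined_to_targets <- function(ctx) {
  fl <- flagged_ids(ctx$report)
  length(fl) > 0 && all(fl %in% ctx$truth$targets) &&
    all(ctx$truth$targets %in% fl)
}
exp_targets_and_descendants <- function(all_targets_flagged = FALSE,
                                        offspring_flagged = FALSE) {
  function(ctx) {
    tg <- ctx$truth$targets
    allowed <- c(tg, desc_set(ctx$ped, tg))
    fl <- flagged_ids(ctx$report)
    ok <- length(fl) > 0 && all(fl %in% allowed)
    if (all_targets_flagged) ok <- ok && all(tg %in% fl)
    if (offspring_flagged) ok <- ok && any(fl %in% desc_set(ctx$ped, tg))
    ok
  }
}

init_scenarios <- function() {
  if (length(ls(scenario_env))) return(invisible())
  ped_expected <- paste("at least one flag; flags confined to the re-parented",
                        "individuals, each of which is flagged")
  ped_names <- c(ped_alter_sire_individual = 1, ped_alter_sire_family = 2,
                 ped_alter_sire_litter = 3, ped_alter_sire_sibs = 4,
                 ped_alter_dam_individual = 5, ped_alter_dam_family = 6,
                 ped_alter_dam_litter = 7, ped_alter_parents_individual = 8,
                 ped_alter_parents_family = 9, ped_alter_parents_litter = 10)
  for (nm in names(ped_names))
    register_scenario(nm, "pedigree", ped_names[[nm]],
                      expected = ped_expected, expect = exp_confined_to_targets)
  register_scenario("ped_flip_sex_breeding_sire", "pedigree", 11,
    expected = "validation reports SEX_ROLE_CONFLICT; checking refuses to run",
    expect = function(ctx) {
      iss <- validate_pedigree(ctx$ped)
      any(iss$code == "SEX_ROLE_CONFLICT" &
            iss$subject_id %in% ctx$truth$targets) && !is.null(ctx$error)
    })

  register_scenario("geno_copy_all", "genotype", 1,
    expected = "flags confined to the recipient and its descendants",
    expect = function(ctx) {
      recip <- ctx$truth$targets[2L]
      allowed <- c(recip, desc_set(ctx$ped, recip))
      fl <- flagged_ids(ctx$report)
      length(fl) > 0 && all(fl %in% allowed) && recip %in% fl
    })
  register_scenario("geno_copy_some", "genotype", 2,
    expected = "flags confined to the recipient and its descendants",
    expect = function(ctx) {
      recip <- ctx$truth$targets[2L]
      allowed <- c(recip, desc_set(ctx$ped, recip))
      fl <- flagged_ids(ctx$report)
      length(fl) > 0 && all(fl %in% allowed)
    })
  register_scenario("geno_swap_all", "genotype", 3,
    expected = paste("both swapped individuals flagged with all three error",
                     "types; flags otherwise confined to their descendants"),
    expect = function(ctx) {
      tg <- ctx$truth$targets
      ok <- exp_targets_and_descendants(TRUE, TRUE)(ctx)
      rows <- match(tg, rownames(ctx$report$nil_from_sire))
      ok && any(ctx$report$nil_from_sire[rows, ]) &&
        any(ctx$report$nil_from_dam[rows, ]) &&
        any(ctx$report$novel_allele[rows, ])
    })
  register_scenario("geno_swap_some", "genotype", 4,
    expected = "flags confined to the swapped pair and their descendants",
    expect = exp_targets_and_descendants())
  register_scenario("geno_mix_random", "genotype", 5,
    expected = "flags confined to the corrupted individual and its descendants",
    expect = exp_targets_and_descendants())
  novel_names <- c(geno_novel_father_family = 6, geno_novel_father_litter = 7,
                   geno_novel_father_sire_sibs = 8,
                   geno_novel_father_individual = 9)
  for (nm in names(novel_names))
    register_scenario(nm, "genotype", novel_names[[nm]],
      expected = paste("every regenotyped individual flagged; flags confined",
                       "to them and their descendants"),
      expect = exp_targets_and_descendants(all_targets_flagged = TRUE))
  register_scenario("geno_sexlinked_homozygous", "genotype", 10,
    expected = paste("only nil-from-sire flags, only at the rewritten marker,",
                     "and never on a recorded-female individual"),
    expect = function(ctx) {
      rep <- ctx$report
      total_other <- sum(rep$nil_from_dam) + sum(rep$novel_allele)
      mk <- unique(ctx$truth$changes$marker)
      flag_cols <- colnames(rep$nil_from_sire)[colSums(rep$nil_from_sire) > 0]
      fl <- flagged_ids(rep)
      sexes <- ctx$ped$ind$sex[match(fl, ctx$ped$ind$id)]
      sum(rep$nil_from_sire) > 0 && total_other == 0 &&
        all(flag_cols %in% mk) && !any(sexes == "female") &&
        any(sexes == "male")
    })
  swap_names <- c(geno_swap_rows_cross_generation = 11,
                  geno_swap_rows_same_generation = 12,
                  geno_swap_rows_sire_sibs = 13)
  for (nm in names(swap_names))
    register_scenario(nm, "genotype", swap_names[[nm]],
      expected = "flags confined to the swapped pair and their descendants",
      expect = exp_targets_and_descendants())
  register_scenario("geno_swap_rows_full_sibs", "genotype", 14,
    expected = paste("the swapped full sibs carry no flags; their descendants",
                     "do"),
    expect = function(ctx) {
      tg <- ctx$truth$targets
      fl <- flagged_ids(ctx$report)
      length(fl) > 0 && !any(tg %in% fl) &&
        all(fl %in% desc_set(ctx$ped, tg))
    })

  # displacement trio: two breeding full sisters re-assigned to a wrong sire,
  # checked with complete data and with the F1 generation half and fully erased
  register_scenario("wrong_sire_sisters_full", "wrong_sire", NA, erasure = 0,
    expected = "flags exactly at the two re-assigned sisters",
    expect = function(ctx) {
      fl <- flagged_ids(ctx$report)
      setequal(fl, ctx$truth$targets)
    })
  register_scenario("wrong_sire_sisters_erased50", "wrong_sire", NA,
    erasure = 0.5,
    expected = "flags confined to the sisters and their F2 offspring",
    expect = function(ctx) {
      tg <- ctx$truth$targets
      allowed <- c(tg, desc_set(ctx$ped, tg))
      fl <- flagged_ids(ctx$report)
      length(fl) > 0 && all(fl %in% allowed)
    })
  register_scenario("wrong_sire_sisters_erased100", "wrong_sire", NA,
    erasure = 1,
    expected = paste("no flags in the fully erased F1 (inferred data cannot",
                     "be wrong); flags pushed down to the sisters' F2",
                     "offspring"),
    expect = function(ctx) {
      tg <- ctx$truth$targets
      fl <- flagged_ids(ctx$report)
      f1 <- names(ctx$gen)[ctx$gen == 1]
      length(fl) > 0 && !any(fl %in% f1) &&
        all(fl %in% desc_set(ctx$ped, tg))
    })
  invisible()
}

#' List registered corruption scenarios
#' @return character vector of scenario names.
#' @export
scenario_names <- function() {
  init_scenarios()
  sort(ls(scenario_env))
}

#' Build a corruption scenario
#'
#' Constructs the evaluation pedigree, gene-drops a consistent 70-marker
#' dataset (10 copies of each template), applies the scenario's injection
#' and erasure, and returns the corrupted dataset together with its
#' ground truth and a manifest whose `expect` predicate states the error
#' pattern the checker must reproduce.
#'
#' @param name a registered scenario name (see [scenario_names()]).
#' @param seed integer seed driving the gene drop and the injection.
#' @return list with `pedigree`, `genotypes`, `truth`, `manifest`.
#' @export
build_scenario <- function(name, seed = 1) {
  init_scenarios()
  sc <- scenario_env[[name]]
  if (is.null(sc)) stop("unknown scenario: ", name)
  ped <- eval_pedigree()
  mat <- gene_drop(ped, copies = 10, seed = seed)
  truth <- NULL
  if (sc$kind == "pedigree") {
    inj <- inject_pedigree(ped, sc$category, target = sc$targets, seed = seed)
    ped <- inj$pedigree
    truth <- inj$truth
  } else if (sc$kind == "genotype") {
    inj <- inject_genotype(mat, ped, sc$category, targets = sc$targets,
                           seed = seed)
    mat <- inj$genotypes
    truth <- inj$truth
  } else { # wrong_sire: both sisters A1, A2 re-assigned from S1 to S2
    sisters <- c("A1", "A2")
    ped2 <- set_parent(ped, sisters, "sire", "S2")
    truth <- list(kind = "pedigree", category = NA_integer_,
                  targets = sisters,
                  description = "re-assigned full sisters A1, A2 to sire S2",
                  changes = data.frame(id = sisters, field = "sire",
                                       old = "S1", new = "S2",
                                       stringsAsFactors = FALSE))
    ped <- ped2
  }
  if (sc$erasure > 0)
    mat <- erase_generation(mat, ped, 1L, sc$erasure, seed = seed + 100L)
  manifest <- list(scenario = name, kind = sc$kind, category = sc$category,
                   erasure = sc$erasure, expected = sc$expected,
                   expect = sc$expect)
  list(pedigree = ped, genotypes = mat, truth = truth, manifest = manifest)
}

#' Run the scenario suite
#'
#' Builds every requested scenario for every seed, runs [check_dataset()]
#' (catching the validation refusal that the sex-flip scenario expects) and
#' evaluates each manifest predicate.
#'
#' @param seeds integer vector of seeds.
#' @param names scenario names (default: all registered).
#' @return data.frame with columns `scenario`, `seed`, `pass`, `n_flags`.
#' @export
run_scenarios <- function(seeds = 1L, names = scenario_names()) {
  out <- list()
  for (nm in names) for (sd in seeds) {
    fx <- build_scenario(nm, seed = sd)
    err <- NULL
    report <- tryCatch(check_dataset(fx$pedigree, fx$genotypes),
                       error = function(e) { err <<- e; NULL })
    gen <- tryCatch(assign_generations(fx$pedigree), error = function(e) NULL)
    ctx <- list(report = report, ped = fx$pedigree, truth = fx$truth,
                gen = gen, error = err)
    pass <- isTRUE(tryCatch(fx$manifest$expect(ctx), error = function(e) FALSE))
    nfl <- if (is.null(report)) NA_integer_ else
      sum(report$individuals$total)
    out[[length(out) + 1L]] <- data.frame(
      scenario = nm, seed = sd, pass = pass, n_flags = nfl,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(scenario = character(), seed = integer(),
                      pass = logical(), n_flags = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
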