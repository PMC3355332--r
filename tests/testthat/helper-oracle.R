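# Independent oracles and small generators used across the test suite.
# The transmission/compatibility rules here are written from the inheritance
# model directly (not shared with the package internals) so that the
# fixpoint propagation can be checked against whole-pedigree enumeration.

oracle_trans <- function(g, role, linkage, child_sex) {
  al <- strsplit(g, "/", fixed = TRUE)[[1L]]
  if (linkage == "x_linked" && role == "sire") {
    if (child_sex == "male") return("-")
    return(setdiff(al, "-"))
  }
  if (linkage == "z_linked" && role == "dam") {
    if (child_sex == "female") return("-")
    return(setdiff(al, "-"))
  }
  al
}

oracle_ok_child <- function(gc, gs, gd, linkage, sex) {
  if (sex == "unknown")
    return(oracle_ok_child(gc, gs, gd, linkage, "male") ||
             oracle_ok_child(gc, gs, gd, linkage, "female"))
  p <- strsplit(gc, "/", fixed = TRUE)[[1L]]
  ts <- oracle_trans(gs, "sire", linkage, sex)
  td <- oracle_trans(gd, "dam", linkage, sex)
  (p[1L] %in% ts && p[2L] %in% td) || (p[2L] %in% ts && p[1L] %in% td)
}

# Whole-pedigree enumeration: every individual ranges over its initial
# candidate set; assignments where any nuclear family is inconsistent are
# discarded; each individual's oracle set is the genotypes it takes among
# the survivors.
oracle_candidate_sets <- function(ped, mat, marker) {
  j <- match(marker, mat$markers$name)
  linkage <- mat$markers$linkage[j]
  alleles <- mat$markers$alleles[[j]]
  ind <- ped$ind
  ids <- ind$id
  sets <- lapply(seq_along(ids), function(i) {
    a1 <- mat$a1[ids[i], j]; a2 <- mat$a2[ids[i], j]
    known <- setdiff(c(a1, a2), "?")
    if (length(known) == 2L || (length(known) == 1L && a1 == a2))
      return(paste0(a1, "/", a2))
    legal <- legal_genotypes(alleles, linkage, ind$sex[i])
    if (length(known) == 1L)
      legal <- legal[vapply(strsplit(legal, "/", fixed = TRUE),
                            function(p) known %in% p, TRUE)]
    legal
  })
  grid <- do.call(expand.grid, c(stats::setNames(sets, ids),
                                 stringsAsFactors = FALSE))
  keep <- rep(TRUE, nrow(grid))
  all_g <- sort(unique(unlist(sets)))
  for (i in seq_along(ids)) {
    s <- ind$sire[i]; d <- ind$dam[i]
    if (is.na(s) && is.na(d)) next
    stopifnot(!is.na(s), !is.na(d)) # generators give 0 or 2 parents
    combos <- expand.grid(gs = all_g, gd = all_g, gc = all_g,
                          stringsAsFactors = FALSE)
    lut <- stats::setNames(
      mapply(oracle_ok_child, combos$gc, combos$gs, combos$gd,
             MoreArgs = list(linkage = linkage, sex = ind$sex[i])),
      paste(combos$gs, combos$gd, combos$gc, sep = "|"))
    keys <- paste(grid[[s]], grid[[d]], grid[[ids[i]]], sep = "|")
    keep <- keep & unname(lut[keys])
  }
  grid <- grid[keep, , drop = FALSE]
  lapply(stats::setNames(ids, ids), function(id) sort(unique(grid[[id]])))
}

# Random small tree-structured pedigree (marriage-node tree: every mate
# brought in is a fresh founder, so no inbreeding loops) with <= n_max
# individuals, every non-founder having both parents recorded.
random_tree_pedigree <- function(n_max = 8, seed = 1) {
  set.seed(seed)
  id <- c("I1", "I2")
  sire <- c(NA, NA); dam <- c(NA, NA)
  sex <- c("male", "female")
  nkids <- sample(1:3, 1)
  for (k in seq_len(nkids)) {
    id <- c(id, paste0("I", length(id) + 1L))
    sire <- c(sire, "I1"); dam <- c(dam, "I2")
    sex <- c(sex, sample(c("male", "female", "unknown"), 1,
                         prob = c(.4, .4, .2)))
  }
  # optionally extend one or two children into new families with founder mates
  repeat {
    if (length(id) >= n_max - 1L || stats::runif(1) < 0.35) break
    kids <- which(!is.na(sire) & sex != "unknown")
    if (!length(kids)) break
    p <- if (length(kids) == 1L) kids else sample(kids, 1)
    mate_sex <- if (sex[p] == "male") "female" else "male"
    mate <- paste0("I", length(id) + 1L)
    id <- c(id, mate); sire <- c(sire, NA); dam <- c(dam, NA)
    sex <- c(sex, mate_sex)
    for (k in seq_len(sample(1:2, 1))) {
      if (length(id) >= n_max) break
      id <- c(id, paste0("I", length(id) + 1L))
      s <- if (sex[p] == "male") id[p] else mate
      d <- if (sex[p] == "male") mate else id[p]
      sire <- c(sire, s); dam <- c(dam, d)
      sex <- c(sex, sample(c("male", "female", "unknown"), 1,
                           prob = c(.4, .4, .2)))
    }
  }
  pedigree(id, sire, dam, sex)
}

# Consistent single-marker dataset on a pedigree: gene-drop by hand (with
# unknown-sex individuals resolved by a latent coin), then erase/partialize
# a random subset, keeping the enumeration size manageable.
random_marker_dataset <- function(ped, alleles, linkage, seed = 1,
                                  max_grid = 30000) {
  set.seed(seed + 1000L)
  ind <- ped$ind
  ids <- ind$id
  latent <- ifelse(ind$sex == "unknown",
                   sample(c("male", "female"), nrow(ind), TRUE), ind$sex)
  g <- assign_generations(ped)
  a1 <- a2 <- stats::setNames(rep("?", length(ids)), ids)
  for (i in order(g[ids])) {
    s <- ind$sire[i]; d <- ind$dam[i]
    if (is.na(s)) {
      pat <- sample(alleles, 1)
      mat_ <- sample(alleles, 1)
      if (linkage == "x_linked" && latent[i] == "male") pat <- "-"
      if (linkage == "z_linked" && latent[i] == "female") mat_ <- "-"
    } else {
      pat <- if (linkage == "x_linked") {
        if (latent[i] == "male") "-" else setdiff(c(a1[s], a2[s]), "-")[1L]
      } else sample(c(a1[s], a2[s]), 1)
      mat_ <- if (linkage == "z_linked") {
        if (latent[i] == "female") "-" else setdiff(c(a1[d], a2[d]), "-")[1L]
      } else sample(c(a1[d], a2[d]), 1)
    }
    a1[i] <- pat; a2[i] <- mat_
  }
  mk <- marker_def("mk1", list(alleles), linkage)
  build <- function(erase, partial) {
    x1 <- a1; x2 <- a2
    x1[erase] <- "?"; x2[erase] <- "?"
    for (p in partial) x2[p] <- "?" # keep one known allele
    genotype_matrix(ids, mk, matrix(x1, ncol = 1), matrix(x2, ncol = 1))
  }
  grid_size <- function(mat) {
    prod(vapply(seq_along(ids), function(i) {
      known <- setdiff(c(mat$a1[i, 1], mat$a2[i, 1]), "?")
      if (length(known) == 2L || (length(known) == 1L && mat$a1[i, 1] == mat$a2[i, 1]))
        1L else length(legal_genotypes(alleles, linkage, ind$sex[i]))
    }, 1L))
  }
  n <- length(ids)
  erase <- which(stats::runif(n) < 0.45)
  partial <- integer()
  rest <- setdiff(seq_len(n), erase)
  if (length(rest) && stats::runif(1) < 0.4)
    partial <- rest[sample.int(length(rest), 1L)]
  mat <- build(erase, partial)
  while (grid_size(mat) > max_grid && length(erase)) {
    erase <- erase[-1L] # re-observe until the enumeration is tractable
    mat <- build(erase, partial)
  }
  mat
}

# convenience trio used in several files
make_trio <- function(child_sex = "unknown") {
  pedigree(c("F", "M", "C"), c(NA, NA, "F"), c(NA, NA, "M"),
           c("male", "female", child_sex))
}

trio_genotypes <- function(ped, calls, markers = NULL) {
  # calls: named list id -> "X/Y" for a single marker "mk1"
  if (is.null(markers)) markers <- marker_def("mk1", list(c("C", "T")))
  a1 <- a2 <- matrix("?", nrow(ped$ind), nrow(markers),
                     dimnames = list(ped$ind$id, markers$name))
  for (id in names(calls)) {
    p <- strsplit(calls[[id]], "/", fixed = TRUE)[[1L]]
    a1[id, 1L] <- p[1L]; a2[id, 1L] <- p[2L]
  }
  genotype_matrix(ped$ind$id, markers, a1, a2)
}
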