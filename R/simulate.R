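#' The marker template registry
#'
#' Exactly seven base templates: five autosomal bi-allelic C/T markers with
#' founder C:T allele ratios 1:1, 1:2, 1:3, 1:4 and 1:5 (the ratio `1:k` is
#' applied as founder allele frequencies, `P(C) = 1/(1+k)`, so that drawn
#' C:T allele counts approximate `1:k`), one mammalian-style male sex-linked
#' pair (C, T with a Y-null) and one avian-style female sex-linked pair
#' (C, T with a W-null).
#'
#' @return data.frame with columns `name`, `linkage`, `p_c` (founder
#'   frequency of C) and list-column `alleles`.
#' @export
marker_templates <- function() {
  k <- 1:5
  out <- marker_def(
    name = c(paste0("auto_ct_1_", k), "xlink_ct", "zlink_ct"),
    alleles = list(c("C", "T")),
    linkage = c(rep("autosomal", 5L), "x_linked", "z_linked"))
  out$p_c <- c(1 / (1 + k), 0.5, 0.5)
  out
}

#' Generate a pedigree from a breeding design
#'
#' Deterministic for a seed. Generation 0 founders are created to parent the
#' requested first-generation families; each later generation holds
#' `families_per_generation` families whose parents are drawn from the
#' previous generation's offspring. Sires take roughly two partners each
#' (mirroring livestock designs where a male is crossed with multiple
#' partners). Future breeders are designated interleaved across families so
#' that both full-sib and paternal half-sib (sire-sib) breeder pairs exist,
#' and are force-sexed; remaining offspring are sexed by `sex_ratio` and
#' then a fraction `unsexed_fraction` of these non-breeders is set to
#' unknown sex.
#'
#' @param n_generations total number of generations (founders count as one).
#' @param families_per_generation families in each offspring generation.
#' @param offspring_per_family children per family; exactly one of this and
#'   `target_total` must be given.
#' @param target_total total pedigree size; offspring are spread evenly with
#'   the remainder distributed over last-generation families.
#' @param sex_ratio proportion of non-breeder offspring recorded male.
#' @param unsexed_fraction fraction of non-breeders with unknown sex.
#' @param litters_per_family split each family's offspring into this many
#'   consecutive litters (tagged `L1`, `L2`, ...); 1 = untagged.
#' @param seed integer seed.
#' @return a [pedigree].
#' @export
sim_pedigree <- function(n_generations = 3, families_per_generation = 4,
                         offspring_per_family = NULL, target_total = NULL,
                         sex_ratio = 0.5, unsexed_fraction = 0,
                         litters_per_family = 1, seed = 1) {
  if (is.null(offspring_per_family) == is.null(target_total))
    stop("give exactly one of offspring_per_family / target_total")
  stopifnot(n_generations >= 2, families_per_generation >= 1,
            sex_ratio >= 0, sex_ratio <= 1,
            unsexed_fraction >= 0, unsexed_fraction <= 1)
  nf <- families_per_generation
  n_sires <- max(1L, ceiling(nf / 2))
  n_dams <- nf
  n_founders <- n_sires + n_dams
  n_off_gens <- n_generations - 1L

  if (!is.null(target_total)) {
    n_off <- target_total - n_founders
    if (n_off < n_off_gens * nf)
      stop("infeasible spec: target_total too small for the requested families")
    base <- n_off %/% (n_off_gens * nf)
    rem <- n_off - base * n_off_gens * nf
    per_fam <- matrix(base, n_off_gens, nf)
    # remainder spread over last-generation families
    if (rem > 0) {
      add <- rem %/% nf
      per_fam[n_off_gens, ] <- per_fam[n_off_gens, ] + add
      extra <- rem - add * nf
      if (extra > 0)
        per_fam[n_off_gens, seq_len(extra)] <- per_fam[n_off_gens, seq_len(extra)] + 1L
    }
  } else {
    per_fam <- matrix(offspring_per_family, n_off_gens, nf)
  }
  if (any(per_fam[-n_off_gens, , drop = FALSE] < 1) && n_off_gens > 1)
    stop("infeasible spec: intermediate generations need >= 1 child per family")
  if (any(rowSums(per_fam)[-n_off_gens] < n_founders) && n_off_gens > 1)
    stop("infeasible spec: not enough offspring per generation to supply breeders")

  with_seed(seed, {
    counter <- 0L
    new_ids <- function(k) {
      out <- sprintf("ID%05d", counter + seq_len(k))
      counter <<- counter + k
      out
    }
    rows <- list()
    sires <- new_ids(n_sires)
    dams <- new_ids(n_dams)
    rows[[1L]] <- data.frame(id = c(sires, dams), sire = NA_character_,
                             dam = NA_character_,
                             sex = rep(c("male", "female"), c(n_sires, n_dams)),
                             litter = NA_character_, stringsAsFactors = FALSE)
    for (g in seq_len(n_off_gens)) {
      fam_sire <- rep(sires, length.out = nf)
      fam_dam <- dams[seq_len(nf)]
      kids_by_fam <- vector("list", nf)
      for (f in seq_len(nf)) {
        k <- per_fam[g, f]
        ids <- new_ids(k)
        lit <- if (litters_per_family > 1)
          paste0("L", ceiling(seq_len(k) / ceiling(k / litters_per_family)))
        else NA_character_
        kids_by_fam[[f]] <- data.frame(
          id = ids, sire = fam_sire[f], dam = fam_dam[f],
          sex = NA_character_, litter = lit, stringsAsFactors = FALSE)
      }
      kids <- do.call(rbind, kids_by_fam)
      # interleave offspring across families: fam1[1], fam2[1], ..., fam1[2], ...
      maxk <- max(vapply(kids_by_fam, nrow, 0L))
      interleaved <- unlist(lapply(seq_len(maxk), function(p)
        vapply(kids_by_fam, function(k)
          if (nrow(k) >= p) k$id[p] else NA_character_, "")))
      interleaved <- interleaved[!is.na(interleaved)]
      if (g < n_off_gens) {
        next_sires <- interleaved[seq_len(n_sires)]
        next_dams <- interleaved[n_sires + seq_len(n_dams)]
      } else {
        next_sires <- next_dams <- character()
      }
      kids$sex <- ifelse(kids$id %in% next_sires, "male",
                         ifelse(kids$id %in% next_dams, "female", NA))
      nonb <- which(is.na(kids$sex))
      kids$sex[nonb] <- ifelse(stats::runif(length(nonb)) < sex_ratio,
                               "male", "female")
      if (unsexed_fraction > 0 && length(nonb)) {
        k_un <- round(unsexed_fraction * length(nonb))
        if (k_un > 0)
          kids$sex[sample(nonb, k_un)] <- "unknown"
      }
      rows[[g + 1L]] <- kids
      sires <- next_sires
      dams <- next_dams
    }
    all <- do.call(rbind, rows)
    pedigree(all$id, all$sire, all$dam, all$sex, all$litter)
  })
}

#' Gene-drop a consistent genotype dataset
#'
#' Seeds each marker template `copies` times (marker count = `7 * copies`
#' with the default registry). Founder alleles are drawn from the template's
#' founder frequencies; every non-founder receives one allele from each
#' parent by a fair draw, honoring linkage (sons receive the Y-null from an
#' x-linked sire; daughters the W-null from a z-linked dam). The result is
#' consistent by construction: [check_dataset()] reports zero flags.
#'
#' Unsexed non-breeders are given a private latent sex for the draw (their
#' calls stay legal under the union semantics used for unknown-sex
#' individuals); an unsexed *breeder* at a sex-linked template is an error.
#'
#' @param ped a validated [pedigree].
#' @param templates a template registry as from [marker_templates()].
#' @param copies how many times to seed each template.
#' @param seed integer seed.
#' @return a `genotypes` object.
#' @export
gene_drop <- function(ped, templates = marker_templates(), copies = 1,
                      seed = 1) {
  stopifnot(inherits(ped, "pedigree"), copies >= 1)
  ind <- ped$ind
  n <- nrow(ind)
  tpl_idx <- rep(seq_len(nrow(templates)), copies)
  mnames <- paste0(templates$name[tpl_idx], "_",
                   rep(seq_len(copies), each = nrow(templates)))
  m <- length(mnames)
  linkage <- templates$linkage[tpl_idx]
  p_c <- (templates$p_c %||% rep(0.5, nrow(templates)))[tpl_idx]
  alleles <- templates$alleles[tpl_idx]
  first <- vapply(alleles, `[`, "", 1L)  # "C"
  second <- vapply(alleles, `[`, "", 2L) # "T"

  is_breeder <- ind$id %in% c(ind$sire, ind$dam)
  if (any(ind$sex == "unknown" & is_breeder) && any(linkage != "autosomal")) {
    bad <- ind$id[ind$sex == "unknown" & is_breeder][1L]
    stop("breeder of unknown sex at a sex-linked marker: ", bad)
  }

  gen <- assign_generations(ped)
  ord <- order(gen[ind$id], ind$id)
  si <- match(ind$sire, ind$id)
  di <- match(ind$dam, ind$id)

  with_seed(seed, {
    latent <- ifelse(ind$sex == "unknown",
                     ifelse(stats::runif(n) < 0.5, "male", "female"),
                     ind$sex)
    a1 <- matrix(NA_character_, n, m)
    a2 <- matrix(NA_character_, n, m)
    xl <- linkage == "x_linked"
    zl <- linkage == "z_linked"
    draw_founder <- function(sex) {
      f1 <- ifelse(stats::runif(m) < p_c, first, second)
      f2 <- ifelse(stats::runif(m) < p_c, first, second)
      if (sex == "male") f2[xl] <- NULL_ALLELE
      if (sex == "female") f2[zl] <- NULL_ALLELE
      list(f1, f2)
    }
    pick <- function(p1, p2) ifelse(stats::runif(m) < 0.5, p1, p2)
    for (i in ord) {
      sx <- latent[i]
      if (is.na(si[i]) && is.na(di[i])) {
        f <- draw_founder(sx)
        a1[i, ] <- f[[1L]]; a2[i, ] <- f[[2L]]
        next
      }
      # parent allele vectors; an absent parent is a virtual founder
      if (is.na(si[i])) {
        f <- draw_founder("male"); s1 <- f[[1L]]; s2 <- f[[2L]]
      } else { s1 <- a1[si[i], ]; s2 <- a2[si[i], ] }
      if (is.na(di[i])) {
        f <- draw_founder("female"); d1 <- f[[1L]]; d2 <- f[[2L]]
      } else { d1 <- a1[di[i], ]; d2 <- a2[di[i], ] }
      pat <- pick(s1, s2)
      mat_ <- pick(d1, d2)
      # hemizygous transmission overrides the coin:
      # x-linked sire passes the Y-null to sons, his X to daughters
      if (any(xl)) {
        if (sx == "male") pat[xl] <- NULL_ALLELE
        else pat[xl] <- ifelse(s1[xl] == NULL_ALLELE, s2[xl], s1[xl])
      }
      # z-linked dam passes the W-null to daughters, her Z to sons
      if (any(zl)) {
        if (sx == "female") mat_[zl] <- NULL_ALLELE
        else mat_[zl] <- ifelse(d1[zl] == NULL_ALLELE, d2[zl], d1[zl])
      }
      a1[i, ] <- pat; a2[i, ] <- mat_
    }
    genotype_matrix(ind$id, marker_def(mnames, alleles, linkage), a1, a2)
  })
}

#' Erase a generation's genotype calls
#'
#' Sets exactly `round(fraction * n_cells)` calls of the chosen generation
#' to missing, sampled without replacement (exact-count erasure keeps the
#' resulting completeness fractions deterministic). Other cells are
#' untouched.
#'
#' @param mat a `genotypes` object.
#' @param ped the matching [pedigree].
#' @param generation integer generation level or label like `"F1"`.
#' @param fraction fraction of that generation's cells to erase, in `[0, 1]`.
#' @param seed integer seed.
#' @return a new `genotypes` object.
#' @export
erase_generation <- function(mat, ped, generation, fraction, seed = 1) {
  stopifnot(inherits(mat, "genotypes"), inherits(ped, "pedigree"),
            fraction >= 0, fraction <= 1)
  gen <- assign_generations(ped)
  if (is.character(generation))
    generation <- as.integer(sub("^[Ff]", "", generation))
  if (is.na(generation) || !generation %in% gen)
    stop("unknown generation: no individuals at that level")
  ids <- names(gen)[gen == generation]
  rows <- match(ids, mat$ids)
  cells <- as.matrix(expand.grid(row = rows, col = seq_len(ncol(mat$a1))))
  k <- round(fraction * nrow(cells))
  if (k == 0) return(mat)
  with_seed(seed, {
    hit <- cells[sample(nrow(cells), k), , drop = FALSE]
    idx <- cbind(hit[, "row"], hit[, "col"])
    mat$a1[idx] <- UNKNOWN_ALLELE
    mat$a2[idx] <- UNKNOWN_ALLELE
    mat
  })
}
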