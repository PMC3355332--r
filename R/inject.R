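# Error-injection catalogue.
#
# Pedigree categories (inject_pedigree):
#   1 alter sire of an individual      5 alter dam of an individual
#   2 alter sire of a family           6 alter dam of a family
#   3 alter sire of a litter           7 alter dam of a litter
#   4 alter sire of a sire-sib set     8 alter both parents of an individual
#   9 alter both parents of a family  10 alter both parents of a litter
#  11 flip the recorded sex of an individual
#
# Genotype categories (inject_genotype):
#   1 copy all calls donor -> recipient      8 regenotype a sire-sib set with
#   2 copy a fraction of calls                 a novel father
#   3 swap all calls between two ids         9 regenotype an individual with a
#   4 swap a fraction of calls                 novel father
#   5 mix random legal calls into an id     10 score a sex-linked marker as
#   6 regenotype a family with a novel         homozygous (and treat it as
#     father                                   autosomal, i.e. unrecognized)
#   7 regenotype a litter with a novel      11-14 swap the full genotype rows
#     father                                   of two ids (non-sibs across
#                                              generations / non-sibs within a
#                                              generation / sire-sibs / full
#                                              sibs)

# deterministic choice: sorted, then seed-shuffled
pick_one <- function(x, seed, k = 1L) {
  x <- sort(x)
  if (length(x) < k) stop("no eligible target for this injection")
  with_seed(seed, x[sample(length(x), k)])
}

replacement_parent <- function(ped, old_parent, role, exclude, seed) {
  gen <- assign_generations(ped)
  ind <- ped$ind
  same_gen <- ind$id[gen[ind$id] == gen[[old_parent]]]
  want_sex <- if (role == "sire") "male" else "female"
  used <- if (role == "sire") stats::na.omit(unique(ind$sire)) else
    stats::na.omit(unique(ind$dam))
  pool <- setdiff(intersect(same_gen, used), c(old_parent, exclude))
  pool <- pool[ind$sex[match(pool, ind$id)] != setdiff(c("male", "female"), want_sex)]
  if (!length(pool)) { # fall back to any correctly sexed same-generation id
    pool <- setdiff(same_gen[ind$sex[match(same_gen, ind$id)] == want_sex],
                    c(old_parent, exclude))
  }
  if (!length(pool)) stop("no eligible replacement ", role, " available")
  pick_one(pool, seed)
}

set_parent <- function(ped, ids, role, new_parent) {
  col <- if (role == "sire") "sire" else "dam"
  ped$ind[[col]][match(ids, ped$ind$id)] <- new_parent
  ped
}

#' Inject a pedigree error
#'
#' Applies one of the 11 cataloged pedigree corruptions (see the category
#' table in the source, or the package vignette). Reassigned parents are
#' drawn deterministically per seed from breeding individuals of the same
#' generation and compatible sex; self-parenting and cycles cannot arise
#' because replacements stay in the original parent's generation.
#'
#' @param ped a validated [pedigree].
#' @param category integer 1-11.
#' @param target optional: the individual (categories 1, 5, 8, 11), family
#'   key `"sire|dam"` (2, 6, 9), litter `"sire|dam|tag"` (3, 7, 10) or sire
#'   id (4) to corrupt; chosen deterministically per seed when absent.
#' @param seed integer seed.
#' @return list with `pedigree` (corrupted), `truth` (a ground-truth record
#'   whose inverse, [revert_injection()], restores the input exactly).
#' @export
inject_pedigree <- function(ped, category, target = NULL, seed = 1) {
  stopifnot(inherits(ped, "pedigree"), category %in% 1:11)
  ind <- ped$ind
  fams <- derive_families(ped)
  roles <- switch(as.character(category),
                  "1" = , "2" = , "3" = , "4" = "sire",
                  "5" = , "6" = , "7" = "dam",
                  "8" = , "9" = , "10" = c("sire", "dam"),
                  "11" = "sex")
  scope <- switch(as.character(category),
                  "1" = , "5" = , "8" = "individual",
                  "2" = , "6" = , "9" = "family",
                  "3" = , "7" = , "10" = "litter",
                  "4" = "sire_sibs", "11" = "sex")

  if (identical(scope, "sex")) {
    if (is.null(target)) {
      breeding_sires <- stats::na.omit(unique(ind$sire))
      target <- pick_one(breeding_sires, seed)
    }
    row <- match(target, ind$id)
    old_sex <- ind$sex[row]
    new_sex <- if (old_sex == "male") "female" else "male"
    ped$ind$sex[row] <- new_sex
    truth <- list(kind = "pedigree", category = 11L, targets = target,
                  description = paste0("flipped recorded sex of ", target,
                                       " from ", old_sex, " to ", new_sex),
                  changes = data.frame(id = target, field = "sex",
                                       old = old_sex, new = new_sex,
                                       stringsAsFactors = FALSE))
    return(list(pedigree = ped, truth = truth))
  }

  # pick the child set to re-parent
  children <- if (scope == "individual") {
    has_role <- !is.na(ind[[roles[1L]]])
    if (is.null(target)) target <- pick_one(ind$id[has_role], seed)
    target
  } else if (scope == "family") {
    keys <- names(fams$families)[vapply(fams$families, function(f)
      all(!is.na(c(f$sire, f$dam)[match(roles, c("sire", "dam"))])), TRUE)]
    if (is.null(target)) target <- pick_one(keys, seed)
    fams$families[[target]]$children
  } else if (scope == "litter") {
    lits <- unlist(lapply(fams$families, function(f)
      stats::setNames(f$litters, paste0(f$key, "|", names(f$litters)))),
      recursive = FALSE)
    ok <- vapply(names(lits), function(k) {
      fk <- sub("\\|[^|]*$", "", k)
      f <- fams$families[[fk]]
      all(!is.na(c(f$sire, f$dam)[match(roles, c("sire", "dam"))]))
    }, TRUE)
    if (is.null(target)) target <- pick_one(names(lits)[ok], seed)
    lits[[target]]
  } else { # sire_sibs
    if (is.null(target)) target <- pick_one(names(fams$sire_index), seed)
    fams$sire_index[[target]]
  }

  changes <- list()
  for (k in seq_along(roles)) {
    role <- roles[k]
    old_parents <- unique(ind[[role]][match(children, ind$id)])
    if (any(is.na(old_parents)))
      stop("target children lack a recorded ", role)
    old_parent <- old_parents[1L]
    newp <- replacement_parent(ped, old_parent, role,
                               exclude = children, seed = seed + k)
    ped <- set_parent(ped, children, role, newp)
    changes[[k]] <- data.frame(id = children, field = role,
                               old = ind[[role]][match(children, ind$id)],
                               new = newp, stringsAsFactors = FALSE)
  }
  changes <- do.call(rbind, changes)
  truth <- list(kind = "pedigree", category = as.integer(category),
                targets = children,
                description = paste0("category ", category, ": re-assigned ",
                                     paste(roles, collapse = "+"), " of ",
                                     length(children), " individual(s)"),
                changes = changes)
  list(pedigree = ped, truth = truth)
}

# relationship predicates used by the pair-picking categories
share_parent <- function(ind, a, b, which = c("any", "sire", "dam", "both")) {
  which <- match.arg(which)
  ra <- ind[match(a, ind$id), ]; rb <- ind[match(b, ind$id), ]
  same_s <- !is.na(ra$sire) && !is.na(rb$sire) && ra$sire == rb$sire
  same_d <- !is.na(ra$dam) && !is.na(rb$dam) && ra$dam == rb$dam
  switch(which, any = same_s || same_d, sire = same_s, dam = same_d,
         both = same_s && same_d)
}

unrelated_pair <- function(ped, a, b) {
  !share_parent(ped$ind, a, b, "any") &&
    !(a %in% relatives(ped, b, "ancestors")) &&
    !(a %in% relatives(ped, b, "descendants"))
}

has_offspring <- function(ped, id) id %in% c(ped$ind$sire, ped$ind$dam)

# find an eligible (a, b) pair; constraint is a function(a, b) -> logical
pick_pair <- function(ped, constraint, seed, prefer = NULL) {
  ids <- sort(ped$ind$id)
  pairs <- list()
  for (a in ids) for (b in ids) if (a < b && constraint(a, b))
    pairs[[length(pairs) + 1L]] <- c(a, b)
  if (!length(pairs)) stop("no eligible target pair for this injection")
  if (!is.null(prefer)) {
    good <- Filter(function(p) prefer(p[1L], p[2L]), pairs)
    if (length(good)) pairs <- good
  }
  with_seed(seed, pairs[[sample(length(pairs), 1L)]])
}

#' Inject a genotype error
#'
#' Applies one of the 14 cataloged genotype corruptions (see the category
#' table in the source). All randomness is seed-deterministic and the
#' returned ground truth restores the input exactly via
#' [revert_injection()].
#'
#' @param mat a `genotypes` object.
#' @param ped the matching [pedigree].
#' @param category integer 1-14.
#' @param targets optional character vector naming the target id(s): a
#'   (donor, recipient) pair for 1-4 and 11-14, one id for 5 and 9, a family
#'   key for 6, a litter key for 7, a sire id for 8; `NULL` picks
#'   deterministically.
#' @param fraction for the "some genotypes" categories 2, 4 and 5 (default
#'   0.5).
#' @param marker for category 10: a sex-linked marker name (default: the
#'   first sex-linked marker).
#' @param seed integer seed.
#' @return list with `genotypes`, `truth` (and `targets` inside the truth).
#' @export
inject_genotype <- function(mat, ped, category, targets = NULL,
                            fraction = 0.5, marker = NULL, seed = 1) {
  stopifnot(inherits(mat, "genotypes"), inherits(ped, "pedigree"),
            category %in% 1:14)
  ind <- ped$ind
  gen <- assign_generations(ped)
  m <- ncol(mat$a1)
  cell_changes <- function(ids, cols = seq_len(m)) {
    grid <- expand.grid(row = match(ids, mat$ids), col = cols)
    data.frame(id = mat$ids[grid$row], marker = mat$markers$name[grid$col],
               old_a1 = mat$a1[as.matrix(grid)], old_a2 = mat$a2[as.matrix(grid)],
               stringsAsFactors = FALSE)
  }
  typed <- function(id) !all(mat$a1[id, ] == UNKNOWN_ALLELE)

  result <- NULL
  if (category %in% c(1:4, 11:14)) {
    constraint <- switch(as.character(category),
      "1" = , "2" = , "3" = , "4" = function(a, b)
        gen[[a]] == gen[[b]] && unrelated_pair(ped, a, b) &&
          typed(a) && typed(b) &&
          # non-founders: a mis-sampled individual should be reconcilable
          # upwards against its own recorded parents
          (!is.na(ind$sire[match(a, ind$id)]) || !is.na(ind$dam[match(a, ind$id)])) &&
          (!is.na(ind$sire[match(b, ind$id)]) || !is.na(ind$dam[match(b, ind$id)])),
      "11" = function(a, b) gen[[a]] != gen[[b]] &&
        !share_parent(ind, a, b, "any") && typed(a) && typed(b) &&
        !(a %in% relatives(ped, b, "ancestors")) &&
        !(a %in% relatives(ped, b, "descendants")),
      "12" = function(a, b) gen[[a]] == gen[[b]] &&
        !share_parent(ind, a, b, "any") && typed(a) && typed(b),
      "13" = function(a, b) gen[[a]] == gen[[b]] &&
        share_parent(ind, a, b, "sire") && !share_parent(ind, a, b, "dam") &&
        typed(a) && typed(b),
      "14" = function(a, b) share_parent(ind, a, b, "both") &&
        typed(a) && typed(b))
    prefer <- function(a, b) {
      same_sex <- ind$sex[match(a, ind$id)] == ind$sex[match(b, ind$id)] &&
        ind$sex[match(a, ind$id)] != "unknown"
      has_offspring(ped, a) && has_offspring(ped, b) &&
        (!category %in% 13:14 || same_sex)
    }
    if (is.null(targets)) {
      targets <- pick_pair(ped, constraint, seed, prefer)
    } else if (!constraint(targets[1L], targets[2L])) {
      stop("targets violate the category's relatedness requirement")
    }
    a <- targets[1L]; b <- targets[2L]
    changes <- cell_changes(c(a, b))
    if (category %in% c(1, 2)) { # copy a -> b
      cols <- if (category == 2)
        with_seed(seed, sort(sample(m, round(fraction * m)))) else seq_len(m)
      changes <- cell_changes(b, cols)
      mat$a1[b, cols] <- mat$a1[a, cols]
      mat$a2[b, cols] <- mat$a2[a, cols]
    } else { # swap (3, 4 partial, 11-14 full rows)
      cols <- if (category == 4)
        with_seed(seed, sort(sample(m, round(fraction * m)))) else seq_len(m)
      changes <- cell_changes(c(a, b), cols)
      tmp1 <- mat$a1[a, cols]; tmp2 <- mat$a2[a, cols]
      mat$a1[a, cols] <- mat$a1[b, cols]; mat$a2[a, cols] <- mat$a2[b, cols]
      mat$a1[b, cols] <- tmp1; mat$a2[b, cols] <- tmp2
    }
    result <- list(targets = c(a, b), changes = changes)
  } else if (category == 5) {
    if (is.null(targets)) {
      pool <- ind$id[vapply(ind$id, typed, TRUE) & (!is.na(ind$sire) | !is.na(ind$dam))]
      targets <- pick_one(pool, seed)
    }
    id <- targets[1L]
    cols <- with_seed(seed, sort(sample(m, round(fraction * m))))
    changes <- cell_changes(id, cols)
    sx <- ind$sex[match(id, ind$id)]
    with_seed(seed + 1L, {
      for (j in cols) {
        legal <- legal_genotypes(mat$markers$alleles[[j]],
                                 mat$markers$linkage[j], sx)
        g <- split_geno(legal[sample(length(legal), 1L)])
        mat$a1[id, j] <- g$a1; mat$a2[id, j] <- g$a2
      }
    })
    result <- list(targets = id, changes = changes)
  } else if (category %in% 6:9) {
    fams <- derive_families(ped)
    kids <- if (category == 6) {
      keys <- names(fams$families)
      if (is.null(targets)) targets <- pick_one(keys, seed)
      fams$families[[targets]]$children
    } else if (category == 7) {
      lits <- unlist(lapply(fams$families, function(f)
        stats::setNames(f$litters, paste0(f$key, "|", names(f$litters)))),
        recursive = FALSE)
      if (is.null(targets)) targets <- pick_one(names(lits), seed)
      lits[[targets]]
    } else if (category == 8) {
      if (is.null(targets)) targets <- pick_one(names(fams$sire_index), seed)
      fams$sire_index[[targets]]
    } else {
      pool <- ind$id[!is.na(ind$dam) & vapply(ind$id, typed, TRUE)]
      if (is.null(targets)) targets <- pick_one(pool, seed)
      targets[1L]
    }
    kids <- kids[!is.na(ind$dam[match(kids, ind$id)])]
    if (!length(kids)) stop("novel-father categories need children with a recorded dam")
    changes <- cell_changes(kids)
    # simulate a novel father's genotypes, then re-drop each child from
    # (novel father, recorded dam)
    with_seed(seed + 7L, {
      nf1 <- nf2 <- character(m)
      for (j in seq_len(m)) {
        al <- mat$markers$alleles[[j]]
        lk <- mat$markers$linkage[j]
        nf1[j] <- al[sample(length(al), 1L)]
        nf2[j] <- if (lk == "x_linked") NULL_ALLELE else al[sample(length(al), 1L)]
      }
      for (id in kids) {
        sx <- ind$sex[match(id, ind$id)]
        if (sx == "unknown") sx <- if (stats::runif(1) < 0.5) "male" else "female"
        dam <- ind$dam[match(id, ind$id)]
        d1 <- mat$a1[dam, ]; d2 <- mat$a2[dam, ]
        pat <- ifelse(stats::runif(m) < 0.5, nf1, nf2)
        mat_c <- ifelse(stats::runif(m) < 0.5, d1, d2)
        xl <- mat$markers$linkage == "x_linked"
        zl <- mat$markers$linkage == "z_linked"
        if (sx == "male") pat[xl] <- NULL_ALLELE else
          pat[xl] <- ifelse(nf1[xl] == NULL_ALLELE, nf2[xl], nf1[xl])
        if (sx == "female") mat_c[zl] <- NULL_ALLELE else
          mat_c[zl] <- ifelse(d1[zl] == NULL_ALLELE, d2[zl], d1[zl])
        # a missing dam call leaves the maternal slot unknown
        mat_c[mat_c == UNKNOWN_ALLELE] <- UNKNOWN_ALLELE
        p <- canon_pair(pat, mat_c)
        mat$a1[id, ] <- p$a1; mat$a2[id, ] <- p$a2
      }
    })
    result <- list(targets = kids, changes = changes)
  } else { # category 10: score a sex-linked marker as homozygous
    sl <- which(mat$markers$linkage != "autosomal")
    if (is.null(marker)) {
      if (!length(sl)) stop("no sex-linked marker in the dataset")
      marker <- mat$markers$name[sl[1L]]
    }
    j <- match(marker, mat$markers$name)
    if (is.na(j) || mat$markers$linkage[j] == "autosomal")
      stop("category 10 needs a sex-linked marker")
    hemi <- which(mat$a2[, j] == NULL_ALLELE)
    changes <- cell_changes(mat$ids[hemi], j)
    changes$old_linkage <- NA_character_
    changes <- rbind(changes,
                     data.frame(id = NA_character_, marker = marker,
                                old_a1 = NA_character_, old_a2 = NA_character_,
                                old_linkage = mat$markers$linkage[j],
                                stringsAsFactors = FALSE))
    mat$a2[hemi, j] <- mat$a1[hemi, j]
    mat$markers$linkage[j] <- "autosomal" # the sex-linkage goes unrecognized
    result <- list(targets = mat$ids[hemi], changes = changes)
  }

  truth <- list(kind = "genotype", category = as.integer(category),
                targets = result$targets,
                description = paste0("genotype category ", category, " on ",
                                     paste(utils::head(result$targets, 4L),
                                           collapse = ", "),
                                     if (length(result$targets) > 4L) ", ..."),
                changes = result$changes)
  list(genotypes = mat, truth = truth)
}

#' Revert an injected error
#'
#' Applies the inverse recorded in a ground-truth object, restoring the
#' pre-injection pedigree or genotype matrix exactly.
#'
#' @param x the corrupted [pedigree] or `genotypes` object.
#' @param truth the `truth` element returned by [inject_pedigree()] /
#'   [inject_genotype()].
#' @return the restored object.
#' @export
revert_injection <- function(x, truth) {
  if (truth$kind == "pedigree") {
    stopifnot(inherits(x, "pedigree"))
    ch <- truth$changes
    for (r in seq_len(nrow(ch)))
      x$ind[[ch$field[r]]][match(ch$id[r], x$ind$id)] <- ch$old[r]
    return(x)
  }
  stopifnot(inherits(x, "genotypes"))
  ch <- truth$changes
  if (!is.null(ch$old_linkage)) {
    for (r in which(!is.na(ch$old_linkage)))
      x$markers$linkage[match(ch$marker[r], x$markers$name)] <- ch$old_linkage[r]
    ch <- ch[is.na(ch$old_linkage), , drop = FALSE]
  }
  if (nrow(ch)) {
    idx <- cbind(match(ch$id, x$ids), match(ch$marker, x$markers$name))
    x$a1[idx] <- ch$old_a1
    x$a2[idx] <- ch$old_a2
  }
  x
}
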