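#' Legal genotypes for a sex at a marker
#'
#' Autosomal markers admit all unordered allele pairs in both sexes. At
#' `x_linked` markers males are hemizygous (`a/-`) and females carry two
#' real alleles; `z_linked` is the mirror image (hemizygous females). For
#' unknown sex the union of both sexes' sets is used, which avoids false
#' constraints on the many unsexed non-breeders found in real pedigrees.
#'
#' @param alleles character vector, the marker's allele alphabet.
#' @param linkage one of `"autosomal"`, `"x_linked"`, `"z_linked"`.
#' @param sex one of `"male"`, `"female"`, `"unknown"`.
#' @return character vector of canonical `"x/y"` genotype strings.
#' @examples
#' legal_genotypes(c("C", "T"), "x_linked", "male")   # "C/-" "T/-"
#' legal_genotypes(c("C", "T"), "autosomal", "female") # "C/C" "C/T" "T/T"
#' @export
legal_genotypes <- function(alleles, linkage = "autosomal", sex = "unknown") {
  stopifnot(linkage %in% LINKAGES, sex %in% SEXES)
  alleles <- sort(alleles)
  diploid <- function() {
    idx <- which(upper.tri(diag(length(alleles)), diag = TRUE), arr.ind = TRUE)
    geno_string(alleles[idx[, 1L]], alleles[idx[, 2L]])
  }
  hemi <- function() geno_string(alleles, rep(NULL_ALLELE, length(alleles)))
  out <- switch(linkage,
    autosomal = diploid(),
    x_linked = switch(sex, male = hemi(), female = diploid(),
                      unknown = c(diploid(), hemi())),
    z_linked = switch(sex, female = hemi(), male = diploid(),
                      unknown = c(diploid(), hemi())))
  unique(out)
}

# Alleles one candidate genotype may transmit in a given parental role to a
# child of a given sex. `g = "*"` stands for a wholly unconstrained (absent)
# parent. Hemizygous transmission: an x-linked sire passes "-" (the Y) to
# sons and his X allele(s) to daughters; a z-linked dam passes "-" (the W)
# to daughters and her Z allele(s) to sons.
trans_one <- function(g, alleles, linkage, role, child_sex) {
  if (child_sex == "unknown")
    return(unique(c(trans_one(g, alleles, linkage, role, "male"),
                    trans_one(g, alleles, linkage, role, "female"))))
  own <- if (identical(g, "*")) alleles else
    unlist(strsplit(g, "/", fixed = TRUE), use.names = FALSE)
  real <- setdiff(own, NULL_ALLELE)
  if (length(real) == 0L) real <- alleles # degenerate "-/-" fact: stay lenient
  hemi_side <- (linkage == "x_linked" && role == "sire") ||
    (linkage == "z_linked" && role == "dam")
  if (!hemi_side) return(unique(own))
  null_to <- if (linkage == "x_linked") "male" else "female"
  if (child_sex == null_to) NULL_ALLELE else unique(real)
}

#' Transmissible alleles of a candidate set
#'
#' Union over a parent's candidate genotypes of the alleles that parent may
#' pass to a child of the given sex, honoring the marker's linkage.
#'
#' @param genotypes character vector of candidate `"x/y"` genotype strings,
#'   or `"*"` for an absent/unconstrained parent.
#' @param alleles the marker's allele alphabet.
#' @param linkage marker linkage mode.
#' @param role `"sire"` or `"dam"`.
#' @param child_sex sex of the receiving child (`"unknown"` = union of both).
#' @return character vector of allele symbols (possibly including `"-"`).
#' @examples
#' transmissible_alleles("C/T", c("C", "T"), "autosomal", "sire", "female")
#' transmissible_alleles("C/-", c("C", "T"), "x_linked", "sire", "male") # "-"
#' @export
transmissible_alleles <- function(genotypes, alleles, linkage = "autosomal",
                                  role = c("sire", "dam"),
                                  child_sex = "unknown") {
  role <- match.arg(role)
  stopifnot(length(genotypes) >= 1L)
  unique(unlist(lapply(genotypes, trans_one, alleles = alleles,
                       linkage = linkage, role = role,
                       child_sex = child_sex), use.names = FALSE))
}

# child genotype gc compatible with parent candidates (gs, gd)?
# For unknown-sex children, compatibility holds if it holds under either sex.
compatible_child <- function(gc, gs, gd, alleles, linkage, child_sex) {
  if (child_sex == "unknown")
    return(compatible_child(gc, gs, gd, alleles, linkage, "male") ||
           compatible_child(gc, gs, gd, alleles, linkage, "female"))
  ts <- trans_one(gs, alleles, linkage, "sire", child_sex)
  td <- trans_one(gd, alleles, linkage, "dam", child_sex)
  p <- strsplit(gc, "/", fixed = TRUE)[[1L]]
  (p[1L] %in% ts && p[2L] %in% td) || (p[2L] %in% ts && p[1L] %in% td)
}

# Initial candidate set for one individual at one marker:
#   fully observed call -> singleton fact (kept even if illegal for the sex);
#   partial call (one known allele) -> legal genotypes containing it;
#   missing -> all legal genotypes for the recorded sex.
init_candidates <- function(x1, x2, alleles, linkage, sex) {
  known <- setdiff(c(x1, x2), UNKNOWN_ALLELE)
  if (length(known) == 2L || (length(known) == 1L && x1 == x2))
    return(geno_string(x1, x2))
  legal <- legal_genotypes(alleles, linkage, sex)
  if (length(known) == 1L) {
    keep <- vapply(legal, function(g) known %in%
                     strsplit(g, "/", fixed = TRUE)[[1L]], TRUE)
    out <- legal[keep]
    if (length(out)) return(out)
    # observed allele outside every legal genotype: keep it as a partial fact
    return(geno_string(known, UNKNOWN_ALLELE))
  }
  legal
}

#' Per-marker genotype elimination to fixpoint
#'
#' Implements nuclear-family constraint propagation: every individual starts
#' from its observed call (an immutable singleton fact), the legal genotypes
#' compatible with a partial call, or the full legal set for its sex when the
#' call is missing. Families are then swept in sorted (sire, dam) key order;
#' within each family, any member's candidate that participates in no jointly
#' consistent (sire, dam, child) assignment with the other members' current
#' sets is deleted. Sweeps repeat until a full pass deletes nothing.
#'
#' Inference is bidirectional: observed children constrain ungenotyped
#' parents just as parents constrain children. Observed genotypes are never
#' deleted, even when erroneous, so errors propagate through inferred
#' relatives exactly as contradictory facts should.
#'
#' If a non-observed individual's set empties (the surrounding facts are
#' contradictory), the individual is marked `conflicted`, its set is reset to
#' the subset of its initial set compatible with its own parents' current
#' candidate sets (falling back to the initial set when even that is empty),
#' and it is exempted from further deletion. Anchoring the reset to the
#' parental side pushes the contradiction down the pedigree: the observed
#' descendants, not the silent intermediate, end up carrying the error flags.
#'
#' @param ped a validated [pedigree].
#' @param mat a `genotypes` object covering `marker`.
#' @param marker marker name.
#' @return list with `candidates` (named list id -> character vector of
#'   genotype strings), `conflicted` (named logical) and `pass_count`.
#' @export
propagate_marker <- function(ped, mat, marker) {
  stopifnot(inherits(ped, "pedigree"), inherits(mat, "genotypes"))
  j <- match(marker, mat$markers$name)
  if (is.na(j)) stop("unknown marker: ", marker)
  alleles <- mat$markers$alleles[[j]]
  linkage <- mat$markers$linkage[j]
  ind <- ped$ind
  ids <- ind$id
  sex <- stats::setNames(ind$sex, ids)
  x1 <- mat$a1[ids, j]; x2 <- mat$a2[ids, j]
  observed <- x1 != UNKNOWN_ALLELE & x2 != UNKNOWN_ALLELE
  names(observed) <- ids

  cand <- stats::setNames(vector("list", length(ids)), ids)
  init <- cand
  for (i in seq_along(ids)) {
    init[[i]] <- init_candidates(x1[i], x2[i], alleles, linkage, sex[i])
    cand[[i]] <- init[[i]]
  }
  conflicted <- stats::setNames(rep(FALSE, length(ids)), ids)
  exempt <- conflicted

  fam <- derive_families(ped)$families
  sire_of <- stats::setNames(ind$sire, ids)
  dam_of <- stats::setNames(ind$dam, ids)

  parent_derived <- function(id) {
    cs <- if (is.na(sire_of[id])) "*" else cand[[sire_of[id]]]
    cd <- if (is.na(dam_of[id])) "*" else cand[[dam_of[id]]]
    keep <- vapply(init[[id]], function(g) {
      for (gs in cs) for (gd in cd)
        if (compatible_child(g, gs, gd, alleles, linkage, sex[id]))
          return(TRUE)
      FALSE
    }, TRUE)
    out <- init[[id]][keep]
    if (length(out)) out else init[[id]]
  }

  pass_count <- 0L
  repeat {
    changed <- FALSE
    pass_count <- pass_count + 1L
    for (f in fam) {
      s <- f$sire; d <- f$dam
      cs <- if (is.na(s)) "*" else cand[[s]]
      cd <- if (is.na(d)) "*" else cand[[d]]
      kids <- f$children
      ckids <- lapply(kids, function(k) cand[[k]])
      saved_s <- logical(length(cs))
      saved_d <- logical(length(cd))
      saved_k <- lapply(ckids, function(x) logical(length(x)))
      for (si in seq_along(cs)) {
        for (di in seq_along(cd)) {
          ok <- TRUE
          compat <- vector("list", length(kids))
          for (ki in seq_along(kids)) {
            cc <- vapply(ckids[[ki]], compatible_child, TRUE,
                         gs = cs[si], gd = cd[di], alleles = alleles,
                         linkage = linkage, child_sex = sex[kids[ki]])
            if (!any(cc)) { ok <- FALSE; break }
            compat[[ki]] <- cc
          }
          if (ok) {
            saved_s[si] <- TRUE
            saved_d[di] <- TRUE
            for (ki in seq_along(kids))
              saved_k[[ki]] <- saved_k[[ki]] | compat[[ki]]
          }
        }
      }
      update <- function(id, keep) {
        if (is.na(id) || observed[id] || exempt[id]) return()
        new <- cand[[id]][keep]
        if (length(new) == 0L) {
          conflicted[id] <<- TRUE
          exempt[id] <<- TRUE
          cand[[id]] <<- parent_derived(id)
          changed <<- TRUE
        } else if (length(new) < length(cand[[id]])) {
          cand[[id]] <<- new
          changed <<- TRUE
        }
      }
      update(s, saved_s)
      update(d, saved_d)
      for (ki in seq_along(kids)) update(kids[ki], saved_k[[ki]])
    }
    if (!changed) break
  }
  list(candidates = cand, conflicted = conflicted, pass_count = pass_count)
}

#' Render a candidate set as a partially resolved genotype label
#'
#' Projects a candidate set onto two per-slot allele unions and prints the
#' most resolved label they admit: a single candidate prints as `X/Y`; one
#' resolved slot prints as `X/?` at bi-allelic markers or `X/[A or B]` at
#' multi-allelic ones; two unresolved slots print as `?/?` or the bracketed
#' set form. The smaller slot is printed first.
#'
#' @param candidates character vector of genotype strings (nonempty).
#' @param alleles the marker's allele alphabet.
#' @return a single character label.
#' @examples
#' render_partial(c("T/T", "C/T"), c("C", "T")) # "T/?"
#' @export
render_partial <- function(candidates, alleles) {
  stopifnot(length(candidates) >= 1L)
  candidates <- unique(candidates)
  if (length(candidates) == 1L) return(candidates)
  pairs <- lapply(strsplit(candidates, "/", fixed = TRUE), identity)
  symbols <- sort(unique(c(unlist(pairs), alleles)))
  # smallest (|S1|, |S2|) slot cover: every candidate {x,y} fits S1 x S2
  subsets <- unlist(lapply(seq_along(symbols), function(k)
    utils::combn(symbols, k, simplify = FALSE)), recursive = FALSE)
  best <- NULL
  for (s1 in subsets) for (s2 in subsets) {
    okall <- all(vapply(pairs, function(p)
      (p[1L] %in% s1 && p[2L] %in% s2) || (p[2L] %in% s1 && p[1L] %in% s2),
      TRUE))
    if (okall) {
      score <- length(s1) + length(s2)
      key <- paste(paste(s1, collapse = ""), paste(s2, collapse = ""))
      if (is.null(best) || score < best$score ||
          (score == best$score && key < best$key))
        best <- list(s1 = s1, s2 = s2, score = score, key = key)
    }
  }
  slots <- list(best$s1, best$s2)
  slots <- slots[order(lengths(slots))]
  full <- sort(unique(alleles))
  wholly_unresolved <- setequal(slots[[1L]], full) && setequal(slots[[2L]], full)
  lab <- function(s) {
    if (length(s) == 1L) return(s)
    if (length(full) <= 2L || wholly_unresolved) return(UNKNOWN_ALLELE)
    paste0("[", paste(sort(s), collapse = " or "), "]")
  }
  paste0(lab(slots[[1L]]), "/", lab(slots[[2L]]))
}
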