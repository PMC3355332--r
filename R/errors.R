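#' Classify one observed genotype against parental transmissible sets
#'
#' The three inheritance-inconsistency categories:
#' \describe{
#'   \item{nil_from_sire}{no child allele is in the sire's transmissible set.}
#'   \item{nil_from_dam}{no child allele is in the dam's transmissible set.}
#'   \item{novel_allele}{some child allele is in neither parent's set.}
#' }
#' The combination "nil from both parents but no novel allele" is logically
#' impossible: if no allele matches either side, every allele is novel.
#'
#' @param child_alleles character vector, the observed unordered allele pair
#'   (duplicates allowed).
#' @param t_sire,t_dam nonempty character vectors of transmissible alleles
#'   (see [transmissible_alleles()]; unconstrained parents give full sets).
#' @return named logical vector `c(nil_from_sire, nil_from_dam, novel_allele)`.
#' @examples
#' classify_call(c("C", "T"), t_sire = "C", t_dam = "T") # no flags
#' classify_call(c("A", "A"), t_sire = c("C", "T"), t_dam = "C") # all three
#' @export
classify_call <- function(child_alleles, t_sire, t_dam) {
  if (length(t_sire) == 0L || length(t_dam) == 0L)
    stop("transmissible sets must be nonempty")
  ca <- unique(child_alleles)
  c(nil_from_sire = !any(ca %in% t_sire),
    nil_from_dam = !any(ca %in% t_dam),
    novel_allele = any(!ca %in% c(t_sire, t_dam)))
}

#' Four-level severity binning
#'
#' Level 0 iff the count is zero; positive counts are binned into thirds of
#' `(0, max_count]`: level 1 up to a third of the maximum, 2 up to two
#' thirds, 3 above. Any monotone four-level scheme would serve; this one is
#' normalized to the maximum count in the current view.
#'
#' @param count non-negative numeric vector.
#' @param max_count positive scalar (the view maximum); `0` is tolerated
#'   when all counts are zero.
#' @return integer vector of levels in `0:3`.
#' @export
severity_bin <- function(count, max_count) {
  stopifnot(all(count <= max_count + 1e-12))
  out <- integer(length(count))
  pos <- count > 0
  if (any(pos)) {
    frac <- count[pos] / max_count
    out[pos] <- ifelse(frac <= 1 / 3, 1L, ifelse(frac <= 2 / 3, 2L, 3L))
  }
  out
}

#' Check a genotyped pedigree for inheritance inconsistencies
#'
#' Runs per-marker genotype elimination ([propagate_marker()]) and then
#' classifies every fully observed call of every non-founder against the
#' transmissible allele sets of its parents' candidate sets (an absent
#' parent contributes the full legal set). Founders and cells that are
#' missing or only partially observed are never flagged: a genotype cannot
#' be both inferred and incorrect. Errors therefore surface as low down the
#' pedigree as the observed data allows.
#'
#' Markers are independent: each marker's result depends only on calls at
#' that marker, and fully observed markers take a vectorized path that
#' skips the (trivial) fixpoint iteration.
#'
#' @param ped a [pedigree]; must validate cleanly (checking refuses to run
#'   on a pedigree with validation issues).
#' @param mat a `genotypes` object over the same individuals.
#' @return object of class `error_report`: flag matrices (`nil_from_sire`,
#'   `nil_from_dam`, `novel_allele`, `inferred`, `conflicted`), aggregate
#'   tables (`individuals`, `markers`, `families`), and the inputs. Use
#'   [findings()] for the long per-cell form.
#' @export
check_dataset <- function(ped, mat) {
  stopifnot(inherits(ped, "pedigree"), inherits(mat, "genotypes"))
  issues <- validate_pedigree(ped)
  if (nrow(issues))
    stop("pedigree failed validation (", paste(unique(issues$code),
         collapse = ", "), "); fix the pedigree before checking")
  ids <- ped$ind$id
  if (!identical(sort(ids), sort(mat$ids)))
    stop("genotype matrix does not cover the pedigree's individuals")
  m <- nrow(mat$markers)
  n <- length(ids)
  ord <- match(ids, mat$ids)
  A1 <- mat$a1[ord, , drop = FALSE]
  A2 <- mat$a2[ord, , drop = FALSE]

  full <- A1 != UNKNOWN_ALLELE & A2 != UNKNOWN_ALLELE
  nil_s <- nil_d <- novel <- conflict <- matrix(FALSE, n, m,
                                                dimnames = list(ids, mat$markers$name))
  inferred <- !full

  col_full <- colSums(full) == n
  fast <- which(col_full)
  slow <- which(!col_full)

  sex <- ped$ind$sex
  si <- match(ped$ind$sire, ids) # NA when absent
  di <- match(ped$ind$dam, ids)
  nonf <- which(!is.na(si) | !is.na(di))

  if (length(fast)) {
    res <- classify_fast(A1, A2, fast, mat$markers, sex, si, di, nonf)
    nil_s[, fast] <- res$nil_s
    nil_d[, fast] <- res$nil_d
    novel[, fast] <- res$novel
  }

  for (j in slow) {
    mk <- mat$markers$name[j]
    pr <- propagate_marker(ped, mat, mk)
    conflict[, j] <- pr$conflicted[ids]
    alleles <- mat$markers$alleles[[j]]
    linkage <- mat$markers$linkage[j]
    for (i in nonf) {
      if (!full[i, j]) next
      ts <- transmissible_alleles(
        if (is.na(si[i])) "*" else pr$candidates[[ids[si[i]]]],
        alleles, linkage, "sire", sex[i])
      td <- transmissible_alleles(
        if (is.na(di[i])) "*" else pr$candidates[[ids[di[i]]]],
        alleles, linkage, "dam", sex[i])
      fl <- classify_call(c(A1[i, j], A2[i, j]), ts, td)
      nil_s[i, j] <- fl[["nil_from_sire"]]
      nil_d[i, j] <- fl[["nil_from_dam"]]
      novel[i, j] <- fl[["novel_allele"]]
    }
  }

  report <- structure(list(
    pedigree = ped, matrix = mat,
    nil_from_sire = nil_s, nil_from_dam = nil_d, novel_allele = novel,
    inferred = inferred, conflicted = conflict), class = "error_report")
  report <- add_aggregates(report)
  report
}

# Vectorized classification for fully observed marker columns.
# Transmissible membership is computed directly from the parents' observed
# calls (their candidate sets are singletons at such markers).
classify_fast <- function(A1, A2, cols, markers, sex, si, di, nonf) {
  n <- nrow(A1)
  k <- length(cols)
  linkage <- markers$linkage[cols]
  xl <- linkage == "x_linked"
  zl <- linkage == "z_linked"
  nil_s <- nil_d <- novel <- matrix(FALSE, n, k)

  # membership of child allele x in parent's transmissible set
  member <- function(x, p1, p2, role, child_sex, absent) {
    # default: parent's own alleles
    inset <- (x == p1) | (x == p2)
    hemi <- if (role == "sire") xl else zl
    if (any(hemi)) {
      nn1 <- ifelse(p1 == NULL_ALLELE, NA, p1) # non-null alleles of parent
      nn2 <- ifelse(p2 == NULL_ALLELE, NA, p2)
      real_match <- (!is.na(nn1) & x == nn1) | (!is.na(nn2) & x == nn2)
      hm <- switch(child_sex,
        male = if (role == "sire") x == NULL_ALLELE else real_match,
        female = if (role == "sire") real_match else x == NULL_ALLELE,
        unknown = real_match | x == NULL_ALLELE)
      # x_linked affects sire role; z_linked affects dam role
      inset[hemi] <- hm[hemi]
    }
    if (any(absent)) {
      # unconstrained parent: full legal transmissible set; every symbol of
      # the alphabet matches, and "-" matches where the linkage provides it
      alset <- x != NULL_ALLELE # alphabet symbols (alphabet is inferred/declared)
      hm <- switch(child_sex,
        male = if (role == "sire") ifelse(xl, x == NULL_ALLELE, alset) else
          ifelse(zl, alset, alset),
        female = if (role == "sire") alset else
          ifelse(zl, x == NULL_ALLELE, alset),
        unknown = alset | ((if (role == "sire") xl else zl) & x == NULL_ALLELE))
      base <- alset
      base[xl | zl] <- hm[xl | zl]
      inset[absent] <- base[absent]
    }
    inset
  }

  for (i in nonf) {
    x1 <- A1[i, cols]; x2 <- A2[i, cols]
    cs <- sex[i]
    s_abs <- rep(is.na(si[i]), k)
    d_abs <- rep(is.na(di[i]), k)
    p1s <- if (is.na(si[i])) rep(NA_character_, k) else A1[si[i], cols]
    p2s <- if (is.na(si[i])) rep(NA_character_, k) else A2[si[i], cols]
    p1d <- if (is.na(di[i])) rep(NA_character_, k) else A1[di[i], cols]
    p2d <- if (is.na(di[i])) rep(NA_character_, k) else A2[di[i], cols]
    in_s1 <- member(x1, p1s, p2s, "sire", cs, s_abs)
    in_s2 <- member(x2, p1s, p2s, "sire", cs, s_abs)
    in_d1 <- member(x1, p1d, p2d, "dam", cs, d_abs)
    in_d2 <- member(x2, p1d, p2d, "dam", cs, d_abs)
    nil_s[i, ] <- !(in_s1 | in_s2)
    nil_d[i, ] <- !(in_d1 | in_d2)
    novel[i, ] <- (!in_s1 & !in_d1) | (!in_s2 & !in_d2)
  }
  list(nil_s = nil_s, nil_d = nil_d, novel = novel)
}

add_aggregates <- function(report) {
  ped <- report$pedigree
  ids <- ped$ind$id
  nil_s <- report$nil_from_sire
  nil_d <- report$nil_from_dam
  novel <- report$novel_allele
  miss <- report$inferred

  ind_tab <- data.frame(
    id = ids,
    sex = ped$ind$sex,
    nil_from_sire = rowSums(nil_s),
    nil_from_dam = rowSums(nil_d),
    novel_allele = rowSums(novel),
    stringsAsFactors = FALSE)
  ind_tab$total <- ind_tab$nil_from_sire + ind_tab$nil_from_dam +
    ind_tab$novel_allele
  ind_tab$incompleteness <- rowMeans(miss)
  fams <- derive_families(ped)
  partners_s <- vapply(fams$families, function(f) f$sire %||% NA_character_, "")
  partners_d <- vapply(fams$families, function(f) f$dam %||% NA_character_, "")
  pc <- table(c(partners_s[!is.na(partners_s)], partners_d[!is.na(partners_d)]))
  ind_tab$partner_count <- as.integer(pc[ids])
  ind_tab$partner_count[is.na(ind_tab$partner_count)] <- 0L
  ind_tab$severity <- severity_bin(ind_tab$total, max(ind_tab$total, 0))

  mk_tab <- data.frame(
    marker = colnames(nil_s),
    linkage = report$matrix$markers$linkage[
      match(colnames(nil_s), report$matrix$markers$name)],
    nil_from_sire = colSums(nil_s),
    nil_from_dam = colSums(nil_d),
    novel_allele = colSums(novel),
    stringsAsFactors = FALSE, row.names = NULL)
  mk_tab$total <- mk_tab$nil_from_sire + mk_tab$nil_from_dam + mk_tab$novel_allele
  mk_tab$incompleteness <- colMeans(miss)
  mk_tab$severity <- severity_bin(mk_tab$total, max(mk_tab$total, 0))

  fam_rows <- lapply(fams$families, function(f) {
    rows <- match(f$children, ids)
    data.frame(
      key = f$key,
      sire = f$sire %||% NA_character_,
      dam = f$dam %||% NA_character_,
      n_children = length(f$children),
      nil_from_sire = sum(ind_tab$nil_from_sire[rows]),
      nil_from_dam = sum(ind_tab$nil_from_dam[rows]),
      novel_allele = sum(ind_tab$novel_allele[rows]),
      incompleteness = mean(ind_tab$incompleteness[rows]),
      stringsAsFactors = FALSE)
  })
  fam_tab <- if (length(fam_rows)) do.call(rbind, fam_rows) else
    data.frame(key = character(), sire = character(), dam = character(),
               n_children = integer(), nil_from_sire = numeric(),
               nil_from_dam = numeric(), novel_allele = numeric(),
               incompleteness = numeric())
  rownames(fam_tab) <- NULL
  if (nrow(fam_tab)) {
    fam_tab$total <- fam_tab$nil_from_sire + fam_tab$nil_from_dam +
      fam_tab$novel_allele
    fam_tab$severity <- severity_bin(fam_tab$total, max(fam_tab$total, 0))
  } else {
    fam_tab$total <- numeric()
    fam_tab$severity <- integer()
  }

  report$individuals <- ind_tab
  report$markers <- mk_tab
  report$families <- fam_tab
  report
}

#' Per-cell findings of an error report
#'
#' Long form of the flag matrices: one row per (individual, marker) cell
#' with the three error flags and the inferred indicator. Inferred cells
#' (missing or partial calls) never carry flags.
#'
#' @param report an `error_report` from [check_dataset()].
#' @param flagged_only keep only rows with at least one flag.
#' @return data.frame with columns `individual`, `marker`, `nil_from_sire`,
#'   `nil_from_dam`, `novel_allele`, `inferred`.
#' @export
findings <- function(report, flagged_only = FALSE) {
  stopifnot(inherits(report, "error_report"))
  ids <- rownames(report$nil_from_sire)
  mks <- colnames(report$nil_from_sire)
  keep <- if (flagged_only) {
    which(report$nil_from_sire | report$nil_from_dam | report$novel_allele)
  } else seq_along(report$nil_from_sire)
  n <- length(ids)
  out <- data.frame(
    individual = ids[(keep - 1L) %% n + 1L],
    marker = mks[(keep - 1L) %/% n + 1L],
    nil_from_sire = report$nil_from_sire[keep],
    nil_from_dam = report$nil_from_dam[keep],
    novel_allele = report$novel_allele[keep],
    inferred = report$inferred[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# ids of individuals carrying at least one flag
flagged_ids <- function(report) {
  tab <- report$individuals
  tab$id[tab$total > 0]
}

#' @export
print.error_report <- function(x, ...) {
  nf <- sum(x$nil_from_sire) + sum(x$nil_from_dam) + sum(x$novel_allele)
  cat("<error_report> ", nrow(x$nil_from_sire), " individuals x ",
      ncol(x$nil_from_sire), " markers\n", sep = "")
  cat("  flags: nil_from_sire=", sum(x$nil_from_sire),
      ", nil_from_dam=", sum(x$nil_from_dam),
      ", novel_allele=", sum(x$novel_allele),
      " (", length(flagged_ids(x)), " flagged individuals)\n", sep = "")
  cat("  incompleteness: ", sprintf("%.1f%%", 100 * mean(x$inferred)),
      " of cells inferred\n", sep = "")
  invisible(x)
}

#' @export
summary.error_report <- function(object, ...) {
  print(object)
  tab <- object$individuals
  tab <- tab[tab$total > 0, c("id", "sex", "nil_from_sire", "nil_from_dam",
                              "novel_allele", "total", "severity")]
  if (nrow(tab)) {
    cat("\nFlagged individuals:\n")
    print(utils::head(tab[order(-tab$total), ], 20L), row.names = FALSE)
  }
  invisible(object)
}

#' Serialize an error report to JSON
#'
#' @param report an `error_report`.
#' @param file optional path.
#' @return JSON string, invisibly.
#' @export
report_to_json <- function(report, file = NULL) {
  payload <- list(
    findings = findings(report, flagged_only = TRUE),
    individuals = report$individuals,
    markers = report$markers,
    families = report$families)
  txt <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                          digits = NA)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}
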