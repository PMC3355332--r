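#' Marker definitions
#'
#' A marker has a name, an allele alphabet (single-character symbols; the
#' null symbol `-` and the unknown symbol `?` are reserved and never part of
#' the alphabet) and a linkage mode. At `x_linked` markers males are
#' hemizygous (one allele plus `-`, the Y-null); at `z_linked` markers
#' females are hemizygous (W-null); `autosomal` markers are diploid in both
#' sexes.
#'
#' @param name character vector of marker names.
#' @param alleles list of character vectors (or a single vector recycled).
#' @param linkage character vector in `c("autosomal", "x_linked", "z_linked")`.
#' @return data.frame with columns `name`, `linkage` and list-column `alleles`.
#' @export
marker_def <- function(name, alleles, linkage = "autosomal") {
  if (!is.list(alleles)) alleles <- list(alleles)
  alleles <- rep_len(alleles, length(name))
  linkage <- rep_len(linkage, length(name))
  if (!all(linkage %in% LINKAGES))
    stop("linkage must be one of: ", paste(LINKAGES, collapse = ", "))
  for (a in alleles) {
    if (any(a %in% c(NULL_ALLELE, UNKNOWN_ALLELE)))
      stop("'-' and '?' are reserved symbols and cannot be marker alleles")
    if (any(nchar(a) != 1L)) stop("alleles must be single characters")
  }
  out <- data.frame(name = as.character(name), linkage = linkage,
                    stringsAsFactors = FALSE)
  out$alleles <- lapply(alleles, function(a) sort(unique(a)))
  out
}

#' Construct a genotype matrix
#'
#' Holds unordered diploid calls (`C/T`), hemizygous calls (`C/-`), partial
#' calls (`T/?`) and missing calls (`?/?`) for every (individual, marker)
#' cell of a declared grid. Calls are stored canonically: alleles sorted,
#' `-` last, `?` last of all. A call is `missing` iff both symbols are `?`.
#'
#' @param ids character vector of individual ids (rows).
#' @param markers a [marker_def()] data.frame (columns).
#' @param a1,a2 character matrices `length(ids) x nrow(markers)` of allele
#'   symbols (defaults: all missing).
#' @return object of class `genotypes`.
#' @export
genotype_matrix <- function(ids, markers, a1 = NULL, a2 = NULL) {
  n <- length(ids); m <- nrow(markers)
  if (is.null(a1)) a1 <- matrix(UNKNOWN_ALLELE, n, m)
  if (is.null(a2)) a2 <- matrix(UNKNOWN_ALLELE, n, m)
  stopifnot(identical(dim(a1), c(n, m)), identical(dim(a2), c(n, m)))
  p <- canon_pair(a1, a2)
  a1 <- matrix(p$a1, n, m); a2 <- matrix(p$a2, n, m)
  dimnames(a1) <- dimnames(a2) <- list(ids, markers$name)
  structure(list(ids = as.character(ids), markers = markers, a1 = a1, a2 = a2),
            class = "genotypes")
}

#' Read a genotype table
#'
#' The genotype TSV dialect has header `id<TAB>marker1<TAB>marker2...`;
#' cells are `X/Y` allele pairs, with `?/?` or an empty cell meaning missing.
#' Every id must be present in the accompanying pedigree; individuals absent
#' from the table receive all-missing rows so that the declared grid is
#' complete. Marker alphabets are inferred from the observed symbols
#' (linkage defaults to autosomal) unless a marker sidecar is supplied.
#'
#' @param file path or character lines (as for [read_pedigree()]).
#' @param ped a [pedigree]; the matrix covers exactly its individuals.
#' @param markers optional sidecar [marker_def()] data.frame giving explicit
#'   alphabets and linkage (see [read_marker_defs()]).
#' @return a `genotypes` object.
#' @export
read_genotypes <- function(file, ped, markers = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  lines <- read_text_lines(file)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty genotype input")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (tolower(header[1L]) != "id")
    stop("genotype header must start with 'id'")
  mnames <- header[-1L]
  rows <- fields[-1L]
  ids <- vapply(rows, `[`, "", 1L)
  bad_id <- setdiff(ids, ped$ind$id)
  if (length(bad_id))
    stop("genotyped id(s) not present in the pedigree: ",
         paste(utils::head(bad_id, 5L), collapse = ", "))
  n <- nrow(ped$ind); m <- length(mnames)
  a1 <- matrix(UNKNOWN_ALLELE, n, m, dimnames = list(ped$ind$id, mnames))
  a2 <- a1
  for (r in seq_along(rows)) {
    cells <- rows[[r]][-1L]
    length(cells) <- m
    cells[is.na(cells) | cells == ""] <- "?/?"
    parts <- split_geno(cells)
    bad <- is.na(parts$a1) | is.na(parts$a2) |
      nchar(parts$a1) != 1L | nchar(parts$a2) != 1L
    if (any(bad))
      stop("malformed genotype cell for individual ", ids[r],
           " at marker ", mnames[which(bad)[1L]])
    a1[ids[r], ] <- parts$a1
    a2[ids[r], ] <- parts$a2
  }
  if (is.null(markers)) {
    alphabet <- lapply(seq_len(m), function(j) {
      sort(setdiff(unique(c(a1[, j], a2[, j])), c(NULL_ALLELE, UNKNOWN_ALLELE)))
    })
    out_of_range <- unlist(alphabet)[!unlist(alphabet) %in% c("A", "C", "G", "T")]
    if (length(out_of_range))
      stop("allele symbol(s) outside {A,C,G,T,-,?}: ",
           paste(unique(out_of_range), collapse = ", "),
           " (supply a marker sidecar for multi-allelic alphabets)")
    markers <- marker_def(mnames, alphabet, "autosomal")
  } else {
    markers <- markers[match(mnames, markers$name), , drop = FALSE]
    if (any(is.na(markers$name)))
      stop("marker(s) missing from sidecar: ",
           paste(mnames[is.na(markers$name)], collapse = ", "))
    for (j in seq_len(m)) {
      seen <- setdiff(unique(c(a1[, j], a2[, j])), c(NULL_ALLELE, UNKNOWN_ALLELE))
      extra <- setdiff(seen, markers$alleles[[j]])
      if (length(extra))
        stop("allele symbol(s) outside the declared alphabet at marker ",
             mnames[j], ": ", paste(extra, collapse = ", "))
    }
  }
  genotype_matrix(ped$ind$id, markers, a1, a2)
}

#' Read PLINK PED genotype columns
#'
#' Consumes the genotype columns of a PLINK PED file (pairs of allele codes
#' per marker; `0 0` = missing). Marker names are `M1`, `M2`, ... unless
#' given; linkage defaults to autosomal on import.
#'
#' @param file path or character lines.
#' @param ped a [pedigree].
#' @param marker_names optional character vector of marker names.
#' @return a `genotypes` object.
#' @export
read_genotypes_plink <- function(file, ped, marker_names = NULL) {
  lines <- read_text_lines(file)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- unique(lengths(fields))
  if (length(nf) != 1L || nf < 6L || (nf - 6L) %% 2L != 0L)
    stop("PED rows must share one length of 6 + 2*n_markers fields")
  m <- (nf - 6L) / 2L
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(m))
  ids <- vapply(fields, `[`, "", 2L)
  bad_id <- setdiff(ids, ped$ind$id)
  if (length(bad_id))
    stop("genotyped id(s) not present in the pedigree: ",
         paste(utils::head(bad_id, 5L), collapse = ", "))
  n <- nrow(ped$ind)
  a1 <- matrix(UNKNOWN_ALLELE, n, m, dimnames = list(ped$ind$id, marker_names))
  a2 <- a1
  for (r in seq_along(fields)) {
    g <- fields[[r]][-(1:6)]
    x1 <- g[seq(1L, 2L * m, 2L)]
    x2 <- g[seq(2L, 2L * m, 2L)]
    x1[x1 == "0"] <- UNKNOWN_ALLELE
    x2[x2 == "0"] <- UNKNOWN_ALLELE
    a1[ids[r], ] <- x1
    a2[ids[r], ] <- x2
  }
  alphabet <- lapply(seq_len(m), function(j)
    sort(setdiff(unique(c(a1[, j], a2[, j])), c(NULL_ALLELE, UNKNOWN_ALLELE))))
  genotype_matrix(ped$ind$id, marker_def(marker_names, alphabet, "autosomal"),
                  a1, a2)
}

#' Read / write a marker sidecar table
#'
#' Sidecar TSV dialect: `marker<TAB>alleles<TAB>linkage`, alleles as a
#' comma-separated list, linkage one of `A`, `X`, `Z`.
#' @param file path or character lines.
#' @return a [marker_def()] data.frame.
#' @export
read_marker_defs <- function(file) {
  lines <- read_text_lines(file)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(fields[[1L]][1L]) == "marker") fields <- fields[-1L]
  name <- vapply(fields, `[`, "", 1L)
  alleles <- lapply(fields, function(f) strsplit(f[2L], ",", fixed = TRUE)[[1L]])
  linkage <- c(A = "autosomal", X = "x_linked", Z = "z_linked")[
    toupper(vapply(fields, `[`, "", 3L))]
  if (any(is.na(linkage))) stop("sidecar linkage codes must be A, X or Z")
  marker_def(name, alleles, unname(linkage))
}

#' @rdname read_marker_defs
#' @param markers a [marker_def()] data.frame.
#' @export
write_marker_defs <- function(markers, file = "") {
  code <- c(autosomal = "A", x_linked = "X", z_linked = "Z")[markers$linkage]
  txt <- c("marker\talleles\tlinkage",
           paste(markers$name,
                 vapply(markers$alleles, paste, "", collapse = ","),
                 code, sep = "\t"))
  if (nzchar(file)) writeLines(txt, file)
  invisible(paste(txt, collapse = "\n"))
}

#' Write a genotype table
#'
#' Serializes canonically: missing calls as `?/?`, hemizygous calls
#' allele-first (`C/-`, never `-/C`). `read_genotypes(write_genotypes(m))`
#' round-trips to an identical object (given the same sidecar).
#'
#' @param mat a `genotypes` object.
#' @param file path, or `""` to only return the text.
#' @return the TSV text, invisibly.
#' @export
write_genotypes <- function(mat, file = "") {
  stopifnot(inherits(mat, "genotypes"))
  cells <- matrix(paste0(mat$a1, "/", mat$a2), nrow(mat$a1), ncol(mat$a1))
  body <- vapply(seq_along(mat$ids), function(i)
    paste(c(mat$ids[i], cells[i, ]), collapse = "\t"), "")
  txt <- c(paste(c("id", mat$markers$name), collapse = "\t"), body)
  if (nzchar(file)) writeLines(txt, file)
  invisible(paste(txt, collapse = "\n"))
}

#' Missing-data fractions
#'
#' Fraction of missing-status cells (both symbols `?`) per individual and
#' per marker; exact rationals in `[0, 1]`.
#'
#' @param mat a `genotypes` object.
#' @return list with named numeric vectors `individual` and `marker`.
#' @export
completeness <- function(mat) {
  stopifnot(inherits(mat, "genotypes"))
  miss <- mat$a1 == UNKNOWN_ALLELE & mat$a2 == UNKNOWN_ALLELE
  list(individual = rowMeans(miss), marker = colMeans(miss))
}

#' @export
print.genotypes <- function(x, ...) {
  miss <- mean(x$a1 == UNKNOWN_ALLELE & x$a2 == UNKNOWN_ALLELE)
  cat("<genotypes> ", length(x$ids), " individuals x ", nrow(x$markers),
      " markers; ", sprintf("%.1f%%", 100 * miss), " missing\n", sep = "")
  lk <- table(x$markers$linkage)
  cat("  linkage: ", paste(names(lk), lk, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# set one cell (canonicalizes); internal
set_call <- function(mat, id, marker, a1, a2) {
  p <- canon_pair(a1, a2)
  mat$a1[id, marker] <- p$a1
  mat$a2[id, marker] <- p$a2
  mat
}

# observed = not missing; fully observed = no "?" in either slot
is_missing_call <- function(mat) {
  mat$a1 == UNKNOWN_ALLELE & mat$a2 == UNKNOWN_ALLELE
}
is_full_call <- function(mat) {
  mat$a1 != UNKNOWN_ALLELE & mat$a2 != UNKNOWN_ALLELE
}
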