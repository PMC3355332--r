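#' Construct a pedigree from vectors
#'
#' A pedigree records one row per individual with optional sire and dam links,
#' a recorded sex and an optional litter tag. Parent links are directed edges
#' of an acyclic graph; founders are individuals with no recorded parents and
#' may enter the breeding program at any generation.
#'
#' @param id character vector of unique, non-empty individual identifiers.
#' @param sire,dam character vectors of parent ids; `NA` (or `""`) = absent.
#' @param sex character vector, each element one of `"male"`, `"female"`,
#'   `"unknown"` (or the codes `M`, `F`, `U`, `1`, `2`, `0`, empty).
#' @param litter optional character vector of litter tags within a family;
#'   `NA` = untagged (the whole family is then one litter).
#' @return An object of class `pedigree`: a list with element `ind`, a
#'   data.frame with columns `id`, `sire`, `dam`, `sex`, `litter`.
#' @examples
#' trio <- pedigree(id = c("F", "M", "C"), sire = c(NA, NA, "F"),
#'                  dam = c(NA, NA, "M"), sex = c("M", "F", "U"))
#' validate_pedigree(trio)
#' @export
pedigree <- function(id, sire = NA, dam = NA, sex = "unknown", litter = NA) {
  n <- length(id)
  id <- as.character(id)
  if (any(is.na(id) | id == ""))
    stop("pedigree ids must be non-empty")
  blank <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & x == ""] <- NA_character_
    x
  }
  ind <- data.frame(
    id = id,
    sire = rep_len(blank(sire), n),
    dam = rep_len(blank(dam), n),
    sex = normalize_sex(rep_len(as.character(sex), n)),
    litter = rep_len(blank(litter), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ind$id))
    stop("duplicate individual id(s): ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "))
  structure(list(ind = ind), class = "pedigree")
}

normalize_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("M", "MALE", "1")] <- "male"
  out[x %in% c("F", "FEMALE", "2")] <- "female"
  bad <- !(x %in% c("M", "MALE", "1", "F", "FEMALE", "2",
                    "U", "UNKNOWN", "0", "", NA) | is.na(x))
  if (any(bad)) stop("unrecognized sex code(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  out
}

#' Read a pedigree table
#'
#' Two dialects are supported. The native dialect is a TSV with header
#' `id<TAB>sire<TAB>dam<TAB>sex[<TAB>litter]`; empty fields mean "absent",
#' sex codes are `M`/`F`/`U`/empty and `#` lines are comments. The
#' `plink_ped` dialect consumes the first five columns of a PLINK PED file
#' (FID, IID, PAT, MAT, SEX) with `0` meaning an absent parent and SEX codes
#' 1/2/0 for male/female/unknown; genotype columns are ignored here.
#'
#' @param file path to a file, or a character vector of lines (length > 1 or
#'   containing a newline).
#' @param dialect `"native"` or `"plink_ped"`.
#' @param create_missing_founders if `TRUE`, parents referenced but not listed
#'   are materialized as unsexed founders instead of being reported later as
#'   `UNKNOWN_PARENT` issues (real datasets commonly reference ungenotyped,
#'   unlisted parents).
#' @return A [pedigree] object (unvalidated; see [validate_pedigree()]).
#' @export
read_pedigree <- function(file, dialect = c("native", "plink_ped"),
                          create_missing_founders = FALSE) {
  dialect <- match.arg(dialect)
  lines <- read_text_lines(file)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty pedigree input")
  ped <- if (dialect == "native") {
    parse_pedigree_native(lines)
  } else {
    parse_pedigree_plink(lines)
  }
  if (create_missing_founders) {
    refs <- setdiff(unique(c(ped$ind$sire, ped$ind$dam)), c(ped$ind$id, NA))
    if (length(refs)) {
      extra <- data.frame(id = refs, sire = NA_character_, dam = NA_character_,
                          sex = "unknown", litter = NA_character_,
                          stringsAsFactors = FALSE)
      ped$ind <- rbind(ped$ind, extra)
    }
  }
  ped
}

read_text_lines <- function(file) {
  if (length(file) > 1L || any(grepl("\n", file, fixed = TRUE))) {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    readLines(file, warn = FALSE)
  }
}

parse_pedigree_native <- function(lines) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- tolower(trimws(fields[[1L]]))
  if (length(header) < 4L || !identical(header[1:4], c("id", "sire", "dam", "sex")))
    stop("pedigree header must be 'id\\tsire\\tdam\\tsex[\\tlitter]'")
  has_litter <- length(header) >= 5L && header[5L] == "litter"
  rows <- fields[-1L]
  nf <- lengths(rows)
  bad <- which(nf < 3L) # trailing empty fields are dropped by the splitter
  if (length(bad))
    stop("malformed pedigree row at line ", bad[1L] + 1L,
         ": expected at least 4 tab-separated fields")
  get <- function(i) vapply(rows, function(r) if (length(r) >= i) r[i] else "", "")
  pedigree(id = get(1L), sire = get(2L), dam = get(3L), sex = get(4L),
           litter = if (has_litter) get(5L) else NA)
}

parse_pedigree_plink <- function(lines) {
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 5L)
  if (length(bad))
    stop("malformed PED row at line ", bad[1L],
         ": expected at least 5 whitespace-separated fields")
  get <- function(i) vapply(fields, `[`, "", i)
  zero_na <- function(x) ifelse(x == "0", NA_character_, x)
  pedigree(id = get(2L), sire = zero_na(get(3L)), dam = zero_na(get(4L)),
           sex = get(5L))
}

#' Validate a pedigree
#'
#' Returns a data.frame of structural issues rather than throwing: an empty
#' result means the pedigree is accepted. Issue codes:
#' \describe{
#'   \item{DUPLICATE_ID}{the same id occurs on more than one row (also raised
#'     immediately at construction).}
#'   \item{UNKNOWN_PARENT}{a sire/dam id that is not listed as an individual.}
#'   \item{SEX_ROLE_CONFLICT}{an individual referenced as sire is recorded
#'     female, or referenced as dam is recorded male. Unsexed individuals may
#'     serve in either role without conflict.}
#'   \item{DUAL_ROLE}{an individual referenced both as a sire and as a dam.}
#'   \item{CYCLE}{an individual is its own ancestor (including self-parenting).}
#' }
#'
#' @param ped a [pedigree].
#' @return data.frame with columns `code`, `subject_id`, `detail`.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ind <- ped$ind
  issues <- list()
  add <- function(code, subject, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, subject_id = subject, detail = detail,
      stringsAsFactors = FALSE)
  }
  dup <- unique(ind$id[duplicated(ind$id)])
  for (d in dup) add("DUPLICATE_ID", d, "id listed more than once")

  known <- ind$id
  for (p in setdiff(unique(c(ind$sire, ind$dam)), c(known, NA))) {
    role <- c("sire"[p %in% ind$sire], "dam"[p %in% ind$dam])
    add("UNKNOWN_PARENT", p,
        paste0("referenced as ", paste(role, collapse = " and "),
               " but not listed"))
  }

  sires <- setdiff(unique(ind$sire), NA)
  dams <- setdiff(unique(ind$dam), NA)
  sex_of <- stats::setNames(ind$sex, ind$id)
  for (s in sires) {
    if (!is.na(sex_of[s]) && identical(unname(sex_of[s]), "female"))
      add("SEX_ROLE_CONFLICT", s, "recorded female but referenced as sire")
  }
  for (d in dams) {
    if (!is.na(sex_of[d]) && identical(unname(sex_of[d]), "male"))
      add("SEX_ROLE_CONFLICT", d, "recorded male but referenced as dam")
  }
  for (b in intersect(sires, dams))
    add("DUAL_ROLE", b, "referenced both as sire and as dam")

  for (cyc in find_cycle_members(ped))
    add("CYCLE", cyc, "individual is its own ancestor")

  if (length(issues) == 0L)
    return(data.frame(code = character(), subject_id = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

# ids participating in ancestry cycles (parent links restricted to known ids)
find_cycle_members <- function(ped) {
  ind <- ped$ind
  idx <- stats::setNames(seq_len(nrow(ind)), ind$id)
  p1 <- idx[ind$sire]; p2 <- idx[ind$dam]
  state <- integer(nrow(ind)) # 0 unseen, 1 in stack, 2 done
  in_cycle <- logical(nrow(ind))
  visit <- function(i) {
    stack <- list(c(i, 0L))
    path <- integer()
    while (length(stack)) {
      top <- stack[[length(stack)]]
      node <- top[1L]; stage <- top[2L]
      if (stage == 0L) {
        if (state[node] == 1L) { # back-edge: mark cycle along path
          k <- match(node, path)
          in_cycle[path[k:length(path)]] <<- TRUE
          stack[[length(stack)]] <- NULL
          next
        }
        if (state[node] == 2L) { stack[[length(stack)]] <- NULL; next }
        state[node] <<- 1L
        path <- c(path, node)
        stack[[length(stack)]] <- c(node, 1L)
        for (p in c(p1[node], p2[node]))
          if (!is.na(p)) stack[[length(stack) + 1L]] <- c(p, 0L)
      } else {
        state[node] <<- 2L
        path <- path[-length(path)]
        stack[[length(stack)]] <- NULL
      }
    }
  }
  for (i in seq_len(nrow(ind))) if (state[i] == 0L) visit(i)
  ind$id[in_cycle]
}

#' Assign display generations
#'
#' Generation 0 holds founders; every non-founder is placed one level below
#' its deepest present parent (`1 + max` over parents). Founders introduced
#' mid-program (mating into a later generation) are lifted to one level above
#' their earliest child so that every parent-offspring sandwich is
#' well-formed; children always sit strictly below each present parent.
#'
#' @param ped a [pedigree] that validates with no `CYCLE`/`UNKNOWN_PARENT`
#'   issues.
#' @return named integer vector, id -> generation (0-based; label with
#'   `paste0("F", gen)`).
#' @export
assign_generations <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ind <- ped$ind
  n <- nrow(ind)
  idx <- stats::setNames(seq_len(n), ind$id)
  p1 <- idx[ind$sire]; p2 <- idx[ind$dam]
  unknown_parent <- (!is.na(ind$sire) & is.na(p1)) | (!is.na(ind$dam) & is.na(p2))
  if (any(unknown_parent))
    stop("cannot assign generations: unknown parent id(s) for ",
         paste(utils::head(ind$id[unknown_parent], 3L), collapse = ", "))
  gen <- rep(NA_integer_, n)
  is_founder <- is.na(p1) & is.na(p2)
  gen[is_founder] <- 0L
  repeat {
    todo <- which(is.na(gen))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      ps <- c(p1[i], p2[i]); ps <- ps[!is.na(ps)]
      if (all(!is.na(gen[ps]))) {
        gen[i] <- 1L + max(gen[ps])
        progressed <- TRUE
      }
    }
    if (!progressed)
      stop("cannot assign generations: ancestry cycle detected")
  }
  # lift late founders to just above their earliest child
  children_of <- split(rep(seq_len(n), 2L), c(ind$sire, ind$dam))
  for (i in which(is_founder)) {
    kids <- children_of[[ind$id[i]]]
    if (length(kids))
      gen[i] <- max(0L, min(gen[kids]) - 1L)
  }
  stats::setNames(gen, ind$id)
}

#' Derive nuclear families and parent indexes
#'
#' Families are keyed by the (sire, dam) pair; every non-founder belongs to
#' exactly one family. Litters partition a family's children by their litter
#' tag; untagged children form a single litter.
#'
#' @param ped a validated [pedigree].
#' @return list with components:
#'   \item{families}{named list; each element has `key`, `sire`, `dam`,
#'     `children` (ordered ids) and `litters` (named list partitioning the
#'     children).}
#'   \item{sire_index}{named list, sire id -> all its offspring ids (sire-sib
#'     sets).}
#'   \item{dam_index}{named list, dam id -> all its offspring ids.}
#' @export
derive_families <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ind <- ped$ind
  nonf <- ind[!(is.na(ind$sire) & is.na(ind$dam)), , drop = FALSE]
  key <- paste(ifelse(is.na(nonf$sire), "", nonf$sire),
               ifelse(is.na(nonf$dam), "", nonf$dam), sep = "|")
  fams <- lapply(split(seq_len(nrow(nonf)), key), function(rows) {
    ch <- nonf$id[rows]
    tags <- nonf$litter[rows]
    tags[is.na(tags)] <- "."
    list(key = paste(ifelse(is.na(nonf$sire[rows[1L]]), "", nonf$sire[rows[1L]]),
                     ifelse(is.na(nonf$dam[rows[1L]]), "", nonf$dam[rows[1L]]),
                     sep = "|"),
         sire = nonf$sire[rows[1L]],
         dam = nonf$dam[rows[1L]],
         children = ch,
         litters = split(ch, tags))
  })
  fams <- fams[order(names(fams))]
  sire_index <- lapply(split(nonf$id, nonf$sire), identity)
  dam_index <- lapply(split(nonf$id, nonf$dam), identity)
  list(families = fams, sire_index = sire_index, dam_index = dam_index)
}

#' Transitive relatives of an individual
#'
#' @param ped a [pedigree].
#' @param id an individual id.
#' @param direction `"ancestors"` (transitive closure along parent links) or
#'   `"descendants"` (along child links). The individual itself is excluded.
#' @return character vector of ids.
#' @export
relatives <- function(ped, id, direction = c("ancestors", "descendants")) {
  stopifnot(inherits(ped, "pedigree"))
  direction <- match.arg(direction)
  ind <- ped$ind
  if (!id %in% ind$id) stop("unknown individual id: ", id)
  step <- if (direction == "ancestors") {
    par <- stats::setNames(Map(function(s, d) setdiff(c(s, d), NA),
                               ind$sire, ind$dam), ind$id)
    function(x) unique(unlist(par[x], use.names = FALSE))
  } else {
    kids <- split(rep(ind$id, 2L), c(ind$sire, ind$dam))
    function(x) unique(unlist(kids[x], use.names = FALSE))
  }
  seen <- character()
  frontier <- id
  repeat {
    nxt <- setdiff(step(frontier), c(seen, id))
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

#' @export
print.pedigree <- function(x, ...) {
  ind <- x$ind
  nf <- sum(is.na(ind$sire) & is.na(ind$dam))
  cat("<pedigree> ", nrow(ind), " individuals (", nf, " founders); sexes: ",
      paste(names(table(ind$sex)), table(ind$sex), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  gen <- assign_generations(object)
  tab <- table(generation = paste0("F", gen[object$ind$id]), sex = object$ind$sex)
  print(object)
  print(tab)
  invisible(tab)
}

#' Write a pedigree in the native TSV dialect
#'
#' @param ped a [pedigree].
#' @param file path, or `""` to return the text invisibly.
#' @return the TSV text, invisibly.
#' @export
write_pedigree <- function(ped, file = "") {
  ind <- ped$ind
  has_litter <- any(!is.na(ind$litter))
  sex_code <- c(male = "M", female = "F", unknown = "U")[ind$sex]
  cols <- list(ind$id, ifelse(is.na(ind$sire), "", ind$sire),
               ifelse(is.na(ind$dam), "", ind$dam), sex_code)
  header <- c("id", "sire", "dam", "sex")
  if (has_litter) {
    cols <- c(cols, list(ifelse(is.na(ind$litter), "", ind$litter)))
    header <- c(header, "litter")
  }
  txt <- c(paste(header, collapse = "\t"),
           do.call(paste, c(cols, sep = "\t")))
  if (nzchar(file)) writeLines(txt, file)
  invisible(paste(txt, collapse = "\n"))
}
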