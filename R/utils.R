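# Shared internal helpers: allele ordering, genotype string handling.

# Reserved symbols: "-" is the null allele carried by the heterogametic sex at
# sex-linked loci, "?" marks an unknown allele slot.
NULL_ALLELE <- "-"
UNKNOWN_ALLELE <- "?"

SEXES <- c("male", "female", "unknown")
LINKAGES <- c("autosomal", "x_linked", "z_linked")

# Canonical allele order: real alleles alphabetically, then "-", then "?".
# Rank classes; ties among real alleles are broken alphabetically in canon_pair.
allele_rank <- function(x) {
  ifelse(x == UNKNOWN_ALLELE, 2L, ifelse(x == NULL_ALLELE, 1L, 0L))
}

# Order a pair of allele vectors canonically (letters sorted, "-" last,
# "?" last of all). Vectorized; returns list(a1, a2).
canon_pair <- function(a1, a2) {
  r1 <- allele_rank(a1)
  r2 <- allele_rank(a2)
  swap <- (r1 > r2) | (r1 == r2 & a1 > a2)
  swap[is.na(swap)] <- FALSE
  t1 <- ifelse(swap, a2, a1)
  t2 <- ifelse(swap, a1, a2)
  list(a1 = t1, a2 = t2)
}

geno_string <- function(a1, a2) {
  p <- canon_pair(a1, a2)
  paste0(p$a1, "/", p$a2)
}

split_geno <- function(g) {
  parts <- strsplit(g, "/", fixed = TRUE)
  a1 <- vapply(parts, `[`, "", 1L)
  a2 <- vapply(parts, `[`, "", 2L)
  list(a1 = a1, a2 = a2)
}

geno_alleles <- function(g) {
  unique(unlist(strsplit(g, "/", fixed = TRUE), use.names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable deterministic RNG scope
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
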