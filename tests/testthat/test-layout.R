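layout_report <- function(seed = 1, erase = 0) {
  ped <- eval_pedigree()
  mat <- gene_drop(ped, copies = 2, seed = seed)
  inj <- inject_genotype(mat, ped, 3, seed = seed)
  mat <- inj$genotypes
  if (erase > 0) mat <- erase_generation(mat, ped, 1, erase, seed = seed)
  check_dataset(ped, mat)
}

offspring_cells <- function(doc) {
  unlist(lapply(doc$sandwiches, function(sw)
    unlist(sw$offspring_rows, recursive = FALSE)), recursive = FALSE)
}

test_that("a trio lays out as one sandwich with single-cell rows", {
  ped <- make_trio()
  mat <- trio_genotypes(ped, list(F = "C/C", M = "T/T", C = "C/T"))
  rep <- check_dataset(ped, mat)
  doc <- build_layout(rep)
  expect_length(doc$sandwiches, 1L)
  sw <- doc$sandwiches[[1L]]
  expect_equal(sw$sire_row[[1L]]$ids, "F")
  expect_equal(sw$dam_row[[1L]]$ids, "M")
  expect_equal(offspring_cells(doc)[[1L]]$ids, "C")
  expect_length(sw$arcs, 0L)
})

test_that("child cells are conserved and sit in their generation's sandwich", {
  rep <- layout_report(seed = 2)
  doc <- build_layout(rep)
  ped <- rep$pedigree
  nonf <- sum(!(is.na(ped$ind$sire) & is.na(ped$ind$dam)))
  cells <- offspring_cells(doc)
  expect_equal(sum(lengths(lapply(cells, `[[`, "ids"))), nonf)
  gen <- assign_generations(ped)
  for (sw in doc$sandwiches) {
    g <- sw$generation_pair[2L]
    for (row in sw$offspring_rows) for (cell in row)
      expect_true(all(gen[cell$ids] == g))
  }
})

test_that("duplicated parents appear once per family joined by arcs", {
  rep <- layout_report(seed = 2)
  doc <- build_layout(rep)
  for (sw in doc$sandwiches) {
    for (row_name in c("sire_row", "dam_row")) {
      ids <- vapply(sw[[row_name]], function(c)
        if (length(c$ids)) c$ids[1L] else NA_character_, "")
      role <- sub("_row", "", row_name)
      for (id in unique(stats::na.omit(ids))) {
        k <- sum(ids == id, na.rm = TRUE)
        n_arcs <- sum(vapply(sw$arcs, function(a)
          a$parent == id && a$role == role, TRUE))
        expect_equal(n_arcs, k - 1L)
      }
    }
  }
  # A3 sires two families in the F1-F2 sandwich: exactly one arc
  sw2 <- doc$sandwiches[[2L]]
  a3_arcs <- sum(vapply(sw2$arcs, function(a) a$parent == "A3", TRUE))
  expect_equal(a3_arcs, 1L)
})

test_that("glyph levels agree with independently recomputed severity bins", {
  rep <- layout_report(seed = 3)
  doc <- build_layout(rep)
  tab <- rep$individuals
  max_s <- max(tab$nil_from_sire)
  for (cell in offspring_cells(doc)) {
    row <- tab[match(cell$ids, tab$id), ]
    expect_equal(cell$glyph$sire_tip,
                 severity_bin(row$nil_from_sire, max(max_s, 1)))
  }
})

test_that("family overview collapses each family to one aggregated cell", {
  rep <- layout_report(seed = 3)
  doc <- build_layout(rep, mode = "family_overview")
  n_fams <- nrow(rep$families)
  expect_equal(length(offspring_cells(doc)), n_fams)
})

test_that("sex split yields three sub-rows with unknowns in the middle", {
  rep <- layout_report(seed = 3)
  doc <- build_layout(rep, split_by_sex = TRUE)
  sw <- doc$sandwiches[[1L]]
  expect_equal(names(sw$offspring_rows), c("male", "unknown", "female"))
  ped <- rep$pedigree
  for (rname in names(sw$offspring_rows)) {
    for (cell in sw$offspring_rows[[rname]])
      expect_equal(unname(ped$ind$sex[match(cell$ids, ped$ind$id)]), rname)
  }
})

test_that("marker focus attaches exclusive states and genotype labels", {
  rep <- layout_report(seed = 4, erase = 0.5)
  mk <- rep$matrix$markers$name[1L]
  doc <- build_layout(rep, marker_focus = mk)
  for (cell in offspring_cells(doc)) {
    expect_true(cell$state %in% c("error", "inferred", "clean"))
    expect_true(nzchar(cell$label))
  }
})

test_that("sorting orders families deterministically with id tie-breaks", {
  rep <- layout_report(seed = 5)
  expect_error(build_layout(rep, sort_key = "bogus"), "sort key")
  doc <- build_layout(rep, sort_key = "error_total")
  fam_tab <- rep$families
  for (sw in doc$sandwiches) {
    keys <- vapply(sw$sire_row, `[[`, "", "family")
    tot <- fam_tab$total[match(keys, fam_tab$key)]
    expect_true(all(diff(tot) <= 0)) # most errors leftmost
    ties <- which(diff(tot) == 0)
    expect_true(all(keys[ties] < keys[ties + 1L])) # ties break by key
  }
})

test_that("detail view renders every child of a large family", {
  ped <- sim_pedigree(2, 1, offspring_per_family = 300, seed = 6)
  mat <- gene_drop(ped, copies = 1, seed = 6)
  rep <- check_dataset(ped, mat)
  key <- rep$families$key[1L]
  doc <- detail_view(rep, key)
  expect_equal(length(offspring_cells(doc)), 300L)
  # clean family: all glyph levels zero
  for (cell in offspring_cells(doc))
    expect_equal(unlist(cell$glyph, use.names = FALSE), rep(0L, 3L))
  expect_error(detail_view(rep, "no|family"), "unknown family")
})

test_that("JSON export round-trips and SVG export is deterministic", {
  rep <- layout_report(seed = 7)
  doc <- build_layout(rep, sort_key = "error_total")
  js <- export_layout(doc, "json")
  doc2 <- layout_from_json(js)
  expect_identical(as.character(export_layout(doc2, "json")), as.character(js))
  svg1 <- export_layout(doc, "svg")
  svg2 <- export_layout(build_layout(rep, sort_key = "error_total"), "svg")
  expect_identical(svg1, svg2)
  expect_match(svg1, "^<svg")
})

test_that("narrow cells in wide generations are label-suppressed", {
  ped <- sim_pedigree(2, 25, offspring_per_family = 10, seed = 8)
  mat <- gene_drop(ped, copies = 1, seed = 8)
  rep <- check_dataset(ped, mat)
  doc <- build_layout(rep, width = 1200)
  cells <- offspring_cells(doc)
  expect_true(all(vapply(cells, `[[`, TRUE, "label_suppressed")))
  wide <- build_layout(rep, width = 120000)
  expect_false(any(vapply(offspring_cells(wide), `[[`, TRUE,
                          "label_suppressed")))
})
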