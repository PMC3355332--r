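# Sandwich-view layout model: a structural document (rows, cells, glyph
# states, duplication arcs) for a checked pedigree, serializable to JSON and
# renderable to deterministic static SVG. Interactivity is out of scope; all
# display semantics are carried by the structure itself.

LAYOUT_SORT_KEYS <- c("name", "partner_count", "error_total", "sire_errors",
                      "dam_errors", "novel_errors", "error_ratio",
                      "incompleteness")

sort_value <- function(tab, key) {
  switch(key,
    name = tab$id %||% tab$key,
    partner_count = -(tab$partner_count %||% 0),
    error_total = -tab$total,
    sire_errors = -tab$nil_from_sire,
    dam_errors = -tab$nil_from_dam,
    novel_errors = -tab$novel_allele,
    error_ratio = -(tab$total / pmax(1, tab$n_children %||% 1)),
    incompleteness = -tab$incompleteness)
}

#' Build a sandwich layout document
#'
#' Lays the pedigree out as one "sandwich" per consecutive generation pair:
#' sires across the top row, dams across the bottom, offspring in between,
#' families read vertically so children sit directly below their sire and
#' above their dam. A parent with several families in one sandwich appears
#' once per family, its cells joined by arcs. Offspring cells carry a
#' hexagon glyph state: the sire-pointing tip is leveled by nil-from-sire
#' counts, the dam-pointing tip by nil-from-dam counts and the mid-stripe by
#' novel-allele counts (four severity levels, normalized to the view
#' maximum); a second, contrasting level encodes data incompleteness
#' (absolute thirds of `[0, 1]`).
#'
#' @param report an `error_report` from [check_dataset()].
#' @param mode `"individuals"` (one cell per child) or `"family_overview"`
#'   (one aggregated cell per family).
#' @param split_by_sex lay offspring out in three sub-rows
#'   (male / unknown / female, the "club sandwich").
#' @param sort_key orders families left-to-right and children within
#'   families; one of `r paste(LAYOUT_SORT_KEYS, collapse = ", ")`. Ties
#'   break by id.
#' @param marker_focus optional marker name; cells then carry rendered
#'   genotype labels and a mutually exclusive state in
#'   `{"error", "inferred", "clean"}`.
#' @param width canvas width in pixels; cells narrower than
#'   `label_threshold` are marked `label_suppressed`.
#' @param label_threshold minimum cell width (px) for labels.
#' @return object of class `layout_document`.
#' @export
build_layout <- function(report, mode = c("individuals", "family_overview"),
                         split_by_sex = FALSE, sort_key = "name",
                         marker_focus = NULL, width = 1200,
                         label_threshold = 18) {
  stopifnot(inherits(report, "error_report"))
  mode <- match.arg(mode)
  if (!sort_key %in% LAYOUT_SORT_KEYS)
    stop("unknown sort key: ", sort_key, " (use one of ",
         paste(LAYOUT_SORT_KEYS, collapse = ", "), ")")
  ped <- report$pedigree
  gen <- assign_generations(ped)
  fams <- derive_families(ped)$families
  ind_tab <- report$individuals
  fam_tab <- report$families
  focus <- NULL
  if (!is.null(marker_focus)) {
    if (!marker_focus %in% report$matrix$markers$name)
      stop("unknown marker: ", marker_focus)
    focus <- marker_state(report, marker_focus)
  }

  max_counts <- list(
    sire = max(ind_tab$nil_from_sire, 0),
    dam = max(ind_tab$nil_from_dam, 0),
    novel = max(ind_tab$novel_allele, 0),
    fam_sire = max(fam_tab$nil_from_sire, 0),
    fam_dam = max(fam_tab$nil_from_dam, 0),
    fam_novel = max(fam_tab$novel_allele, 0),
    parent_total = max(ind_tab$total, 0))

  sandwiches <- list()
  for (g in sort(unique(gen[gen > 0]))) {
    child_ids <- names(gen)[gen == g]
    fg <- Filter(function(f) any(f$children %in% child_ids), fams)
    fg <- lapply(fg, function(f) {
      f$children <- intersect(f$children, child_ids)
      f
    })
    if (!length(fg)) next
    # order families by sort key, ties by key
    fr <- fam_tab[match(vapply(fg, `[[`, "", "key"), fam_tab$key), ,
                  drop = FALSE]
    ofam <- order(sort_value(fr, sort_key), fr$key)
    fg <- fg[ofam]
    sandwiches[[length(sandwiches) + 1L]] <-
      build_sandwich(g, fg, report, gen, mode, split_by_sex, sort_key,
                     max_counts, focus, width, label_threshold)
  }
  structure(list(mode = mode, split_by_sex = split_by_sex,
                 sort_key = sort_key, marker_focus = marker_focus,
                 width = width, label_threshold = label_threshold,
                 sandwiches = sandwiches),
            class = "layout_document")
}

# per-marker binary states and labels for marker-focus mode
marker_state <- function(report, marker) {
  ids <- rownames(report$nil_from_sire)
  err <- report$nil_from_sire[, marker] | report$nil_from_dam[, marker] |
    report$novel_allele[, marker]
  inf <- report$inferred[, marker]
  pr <- propagate_marker(report$pedigree, report$matrix, marker)
  j <- match(marker, report$matrix$markers$name)
  labels <- vapply(ids, function(id)
    render_partial(pr$candidates[[id]], report$matrix$markers$alleles[[j]]), "")
  state <- ifelse(err, "error", ifelse(inf, "inferred", "clean"))
  list(state = stats::setNames(state, ids), label = stats::setNames(labels, ids))
}

incomplete_level <- function(frac) {
  ifelse(frac <= 0, 0L, ifelse(frac <= 1 / 3, 1L, ifelse(frac <= 2 / 3, 2L, 3L)))
}

child_cell <- function(id, ind_tab, max_counts, focus) {
  row <- ind_tab[match(id, ind_tab$id), ]
  cell <- list(
    ids = id, role = "offspring",
    glyph = list(
      sire_tip = severity_bin(row$nil_from_sire, max(max_counts$sire, 1)),
      dam_tip = severity_bin(row$nil_from_dam, max(max_counts$dam, 1)),
      mid_stripe = severity_bin(row$novel_allele, max(max_counts$novel, 1))),
    incomplete = incomplete_level(row$incompleteness))
  if (!is.null(focus)) {
    cell$state <- unname(focus$state[id])
    cell$label <- unname(focus$label[id])
  }
  cell
}

parent_cell <- function(id, role, ind_tab, max_counts, focus) {
  if (is.na(id))
    return(list(ids = character(), role = role, severity = 0L,
                incomplete = 0L))
  row <- ind_tab[match(id, ind_tab$id), ]
  cell <- list(ids = id, role = role,
               severity = severity_bin(row$total, max(max_counts$parent_total, 1)),
               incomplete = incomplete_level(row$incompleteness))
  if (!is.null(focus)) {
    cell$state <- unname(focus$state[id])
    cell$label <- unname(focus$label[id])
  }
  cell
}

build_sandwich <- function(g, fg, report, gen, mode, split_by_sex, sort_key,
                           max_counts, focus, width, label_threshold) {
  ind_tab <- report$individuals
  fam_tab <- report$families
  ped <- report$pedigree

  n_units <- vapply(fg, function(f)
    if (mode == "family_overview") 1L else length(f$children), 0L)
  unit_w <- width / max(1L, sum(n_units))

  sire_row <- list(); dam_row <- list()
  off_rows <- if (split_by_sex && mode == "individuals")
    list(male = list(), unknown = list(), female = list()) else
    list(all = list())
  x <- 0
  for (f in fg) {
    fw <- unit_w * (if (mode == "family_overview") 1L else length(f$children))
    sc <- parent_cell(f$sire %||% NA_character_, "sire", ind_tab, max_counts,
                      focus)
    dc <- parent_cell(f$dam %||% NA_character_, "dam", ind_tab, max_counts,
                      focus)
    sc$x <- x; sc$width <- fw; dc$x <- x; dc$width <- fw
    sc$label_suppressed <- fw < label_threshold
    dc$label_suppressed <- fw < label_threshold
    sc$family <- f$key; dc$family <- f$key
    sire_row[[length(sire_row) + 1L]] <- sc
    dam_row[[length(dam_row) + 1L]] <- dc

    if (mode == "family_overview") {
      fr <- fam_tab[match(f$key, fam_tab$key), ]
      cell <- list(
        ids = f$children, role = "family",
        glyph = list(
          sire_tip = severity_bin(fr$nil_from_sire, max(max_counts$fam_sire, 1)),
          dam_tip = severity_bin(fr$nil_from_dam, max(max_counts$fam_dam, 1)),
          mid_stripe = severity_bin(fr$novel_allele, max(max_counts$fam_novel, 1))),
        incomplete = incomplete_level(fr$incompleteness),
        x = x, width = fw, family = f$key,
        label_suppressed = fw < label_threshold)
      off_rows[[1L]][[length(off_rows[[1L]]) + 1L]] <- cell
    } else {
      kids <- ind_tab[match(f$children, ind_tab$id), , drop = FALSE]
      okid <- order(sort_value(kids, sort_key), kids$id)
      kids_sorted <- f$children[okid]
      cx <- x
      for (id in kids_sorted) {
        cell <- child_cell(id, ind_tab, max_counts, focus)
        cell$x <- cx; cell$width <- unit_w; cell$family <- f$key
        cell$label_suppressed <- unit_w < label_threshold
        sx <- ped$ind$sex[match(id, ped$ind$id)]
        rkey <- if (split_by_sex) sx else "all"
        off_rows[[rkey]][[length(off_rows[[rkey]]) + 1L]] <- cell
        cx <- cx + unit_w
      }
    }
    x <- x + fw
  }
  arcs <- parent_arcs(sire_row, "sire")
  arcs <- c(arcs, parent_arcs(dam_row, "dam"))
  list(generation_pair = c(g - 1L, g), sire_row = sire_row,
       offspring_rows = off_rows, dam_row = dam_row, arcs = arcs)
}

# arcs join consecutive cells of a parent duplicated across families
parent_arcs <- function(row, role) {
  ids <- vapply(row, function(c) if (length(c$ids)) c$ids[1L] else NA_character_, "")
  arcs <- list()
  for (id in unique(stats::na.omit(ids))) {
    at <- which(!is.na(ids) & ids == id)
    if (length(at) > 1L) {
      for (k in seq_len(length(at) - 1L)) {
        a <- row[[at[k]]]; b <- row[[at[k + 1L]]]
        arcs[[length(arcs) + 1L]] <- list(
          parent = id, role = role,
          from_x = a$x + a$width / 2, to_x = b$x + b$width / 2)
      }
    }
  }
  arcs
}

#' Single-family detail view
#'
#' A one-sandwich document holding every individual of one family
#' regardless of size, with the same glyph and state semantics as
#' [build_layout()].
#'
#' @param report an `error_report`.
#' @param family_key a `"sire|dam"` family key (see the report's `families`
#'   table).
#' @param marker_focus optional marker name.
#' @param width canvas width in pixels.
#' @return a `layout_document`.
#' @export
detail_view <- function(report, family_key, marker_focus = NULL,
                        width = 1200) {
  stopifnot(inherits(report, "error_report"))
  ped <- report$pedigree
  fams <- derive_families(ped)$families
  f <- fams[[family_key]]
  if (is.null(f)) stop("unknown family: ", family_key)
  gen <- assign_generations(ped)
  g <- max(gen[f$children])
  focus <- if (is.null(marker_focus)) NULL else
    marker_state(report, marker_focus)
  max_counts <- list(
    sire = max(report$individuals$nil_from_sire, 0),
    dam = max(report$individuals$nil_from_dam, 0),
    novel = max(report$individuals$novel_allele, 0),
    fam_sire = 1, fam_dam = 1, fam_novel = 1,
    parent_total = max(report$individuals$total, 0))
  sw <- build_sandwich(g, list(f), report, gen, "individuals", FALSE, "name",
                       max_counts, focus, width, 18)
  structure(list(mode = "detail", split_by_sex = FALSE, sort_key = "name",
                 marker_focus = marker_focus, width = width,
                 label_threshold = 18, sandwiches = list(sw)),
            class = "layout_document")
}

#' Export a layout document
#'
#' JSON export round-trips structurally ([layout_from_json()]); SVG export
#' is a deterministic static rendering: white plus three darkening error
#' shades fill the glyph parts, and outline intensity encodes
#' incompleteness.
#'
#' @param doc a `layout_document`.
#' @param format `"json"` or `"svg"`.
#' @param file optional output path.
#' @return the serialized text, invisibly.
#' @export
export_layout <- function(doc, format = c("json", "svg"), file = NULL) {
  stopifnot(inherits(doc, "layout_document"))
  format <- match.arg(format)
  txt <- if (format == "json") {
    jsonlite::toJSON(unclass(doc), auto_unbox = TRUE, digits = 6,
                     null = "null", pretty = FALSE)
  } else {
    layout_svg(doc)
  }
  if (!is.null(file)) writeLines(txt, file)
  invisible(as.character(txt))
}

#' @rdname export_layout
#' @param json JSON text produced by `export_layout(..., "json")`.
#' @export
layout_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  structure(doc, class = "layout_document")
}

ERROR_SHADES <- c("#ffffff", "#fdbea6", "#f06b4b", "#b51d14")
INCOMPLETE_SHADES <- c("#bbbbbb", "#a8c6e8", "#5b8fd4", "#1f4e9c")

layout_svg <- function(doc) {
  row_h <- 28; off_h <- 40; pad <- 6
  lines <- character()
  add <- function(...) lines[[length(lines) + 1L]] <<- paste0(...)
  y <- 0
  body <- character()
  num <- function(x) formatC(x, format = "f", digits = 2)
  rect <- function(x, y, w, h, fill, stroke) {
    paste0('<rect x="', num(x), '" y="', num(y), '" width="', num(w),
           '" height="', num(h), '" fill="', fill, '" stroke="', stroke,
           '" stroke-width="1"/>')
  }
  hexagon <- function(x, y, w, h, g, stroke) {
    tip <- h / 4
    top <- paste0('<polygon points="',
                  num(x), ",", num(y + tip), " ", num(x + w / 2), ",", num(y),
                  " ", num(x + w), ",", num(y + tip), " ", num(x + w), ",",
                  num(y + h / 2), " ", num(x), ",", num(y + h / 2),
                  '" fill="', ERROR_SHADES[g$sire_tip + 1L],
                  '" stroke="', stroke, '"/>')
    bot <- paste0('<polygon points="',
                  num(x), ",", num(y + h / 2), " ", num(x + w), ",",
                  num(y + h / 2), " ", num(x + w), ",", num(y + h - tip), " ",
                  num(x + w / 2), ",", num(y + h), " ", num(x), ",",
                  num(y + h - tip),
                  '" fill="', ERROR_SHADES[g$dam_tip + 1L],
                  '" stroke="', stroke, '"/>')
    mid <- paste0('<rect x="', num(x), '" y="', num(y + h / 2 - h / 10),
                  '" width="', num(w), '" height="', num(h / 5),
                  '" fill="', ERROR_SHADES[g$mid_stripe + 1L],
                  '" stroke="none"/>')
    paste0(top, bot, mid)
  }
  for (sw in doc$sandwiches) {
    # sire row
    for (c in sw$sire_row)
      body <- c(body, rect(c$x, y, c$width, row_h,
                           ERROR_SHADES[(c$severity %||% 0L) + 1L],
                           INCOMPLETE_SHADES[(c$incomplete %||% 0L) + 1L]))
    yy <- y + row_h + pad
    for (rname in names(sw$offspring_rows)) {
      row <- sw$offspring_rows[[rname]]
      for (c in row) {
        stroke <- INCOMPLETE_SHADES[(c$incomplete %||% 0L) + 1L]
        body <- c(body, hexagon(c$x, yy, c$width, off_h, c$glyph, stroke))
      }
      yy <- yy + off_h + pad
    }
    for (c in sw$dam_row)
      body <- c(body, rect(c$x, yy, c$width, row_h,
                           ERROR_SHADES[(c$severity %||% 0L) + 1L],
                           INCOMPLETE_SHADES[(c$incomplete %||% 0L) + 1L]))
    yy <- yy + row_h
    for (a in sw$arcs) {
      ay <- if (a$role == "dam") yy + 4 else y - 4
      body <- c(body, paste0('<path d="M ', num(a$from_x), " ", num(ay),
                             " Q ", num((a$from_x + a$to_x) / 2), " ",
                             num(ay + if (a$role == "dam") 10 else -10), " ",
                             num(a$to_x), " ", num(ay),
                             '" fill="none" stroke="#444444"/>'))
    }
    y <- yy + 24
  }
  height <- max(y, 1)
  paste0('<svg xmlns="http://www.w3.org/2000/svg" width="', doc$width,
         '" height="', num(height), '">\n',
         paste(body, collapse = "\n"), "\n</svg>")
}

#' @export
print.layout_document <- function(x, ...) {
  n_cells <- sum(vapply(x$sandwiches, function(sw)
    sum(vapply(sw$offspring_rows, length, 0L)), 0L))
  cat("<layout_document> mode=", x$mode, ", ", length(x$sandwiches),
      " sandwich(es), ", n_cells, " offspring cell(s)",
      if (!is.null(x$marker_focus)) paste0(", marker=", x$marker_focus),
      "\n", sep = "")
  invisible(x)
}
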