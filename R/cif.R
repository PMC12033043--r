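# Minimal CIF 1.1 reader covering the items needed for kinematical
# prediction: cell lengths/angles, symmetry operators, atom sites.
# Symmetry operators are applied to expand the asymmetric unit to P1.

#' Parse a crystal structure from CIF text
#'
#' Reads the cell (`_cell_length_*`, `_cell_angle_*`), the symmetry
#' operators (`_symmetry_equiv_pos_as_xyz` or
#' `_space_group_symop_operation_xyz`, if present) and the atom site loop
#' (`_atom_site_fract_*`, `_atom_site_occupancy`,
#' `_atom_site_B_iso_or_equiv` / `_atom_site_U_iso_or_equiv`,
#' `_atom_site_type_symbol` / `_atom_site_label`).
#'
#' Symmetry operators are applied to every site and duplicates closer
#' than `dedup_tol` (fractional, default 1e-4) are removed, yielding a
#' P1-expanded site list.  When only U_iso is given it is converted via
#' `B = 8 pi^2 U`.
#'
#' @param cif Either a file path or CIF text (character vector of lines or
#'   a single string).
#' @param dedup_tol Positional tolerance (fractional coordinates) for
#'   deduplicating symmetry-generated sites.
#' @return A `crystal_structure`: list with `cell` ([unit_cell()]),
#'   `sites` (data.frame: label, symbol, x, y, z, occupancy, b_iso) and
#'   `symops` (operator strings retained for provenance).
#' @export
parse_cif <- function(cif, dedup_tol = 1e-4) {
  lines <- if (length(cif) == 1L && file.exists(cif)) readLines(cif, warn = FALSE)
           else unlist(strsplit(cif, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  getnum <- function(tag) {
    hit <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (!length(hit)) return(NA_real_)
    val <- trimws(sub(paste0("^", tag), "", hit[[1]]))
    .cif_number(val)
  }
  cl <- c(a = getnum("_cell_length_a"), b = getnum("_cell_length_b"),
          c = getnum("_cell_length_c"))
  ang <- c(alpha = getnum("_cell_angle_alpha"), beta = getnum("_cell_angle_beta"),
           gamma = getnum("_cell_angle_gamma"))
  if (any(is.na(cl)))
    stop("CIF parse error: missing cell block (_cell_length_a/b/c)")
  if (any(is.na(ang))) ang[is.na(ang)] <- 90
  cell <- unit_cell(cl[["a"]], cl[["b"]], cl[["c"]],
                    ang[["alpha"]], ang[["beta"]], ang[["gamma"]])

  loops <- .cif_loops(lines)
  symops <- "x,y,z"
  for (lp in loops) {
    if (any(grepl("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
                  lp$tags))) {
      col <- grep("as_xyz|operation_xyz", lp$tags)[[1]]
      symops <- tolower(gsub("['\"]", "", lp$rows[, col]))
    }
  }

  site_lp <- NULL
  for (lp in loops)
    if (any(grepl("^_atom_site_fract_x$", lp$tags))) site_lp <- lp
  if (is.null(site_lp)) stop("CIF parse error: no atom site loop found")
  tg <- site_lp$tags; rows <- site_lp$rows
  pick <- function(tag) {
    i <- match(tolower(tag), tg)         # loop tags are stored lowercased
    if (is.na(i)) NULL else rows[, i]
  }
  label <- pick("_atom_site_label")
  symbol <- pick("_atom_site_type_symbol")
  if (is.null(symbol)) {
    if (is.null(label)) stop("CIF parse error: atom sites lack both label and type symbol")
    symbol <- sub("^([A-Za-z]+?)[0-9'].*$", "\\1", label)
  }
  if (is.null(label)) label <- symbol
  x <- vapply(pick("_atom_site_fract_x"), .cif_number, numeric(1))
  y <- vapply(pick("_atom_site_fract_y"), .cif_number, numeric(1))
  z <- vapply(pick("_atom_site_fract_z"), .cif_number, numeric(1))
  occ <- pick("_atom_site_occupancy")
  occ <- if (is.null(occ)) rep(1, length(x)) else vapply(occ, .cif_number, numeric(1))
  biso <- pick("_atom_site_B_iso_or_equiv")
  if (is.null(biso)) {
    uiso <- pick("_atom_site_U_iso_or_equiv")
    biso <- if (is.null(uiso)) rep(0, length(x))
            else 8 * pi^2 * vapply(uiso, .cif_number, numeric(1))
  } else biso <- vapply(biso, .cif_number, numeric(1))
  occ[is.na(occ)] <- 1; biso[is.na(biso)] <- 0
  # normalize element capitalization ("FE" -> "Fe") but keep ion charges
  symbol <- vapply(symbol, function(s) {
    core <- regmatches(s, regexpr("^[A-Za-z]+", s))
    rest <- sub("^[A-Za-z]+", "", s)
    paste0(toupper(substr(core, 1, 1)), tolower(substring(core, 2)), rest)
  }, character(1), USE.NAMES = FALSE)
  for (sym in unique(symbol)) .lookup_scattering(sym)  # fail early on unknowns

  asu <- data.frame(label = label, symbol = symbol, x = x, y = y, z = z,
                    occupancy = occ, b_iso = biso, stringsAsFactors = FALSE)
  sites <- .expand_symmetry(asu, symops, dedup_tol)
  structure(list(cell = cell, sites = sites, symops = symops),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("crystal structure: %d sites (P1-expanded, %d symop%s)\n",
              nrow(x$sites), length(x$symops), if (length(x$symops) == 1) "" else "s"))
  print(x$cell)
  invisible(x)
}

# strip esd parentheses: "1.234(5)" -> 1.234
.cif_number <- function(txt) {
  v <- suppressWarnings(as.numeric(sub("\\(.*\\)", "", txt)))
  if (is.na(v)) stop(sprintf("CIF parse error: expected a number, got '%s'", txt))
  v
}

# split lines into loop_ blocks: list of (tags, rows matrix)
.cif_loops <- function(lines) {
  loops <- list()
  i <- 1
  while (i <= length(lines)) {
    if (tolower(lines[i]) == "loop_") {
      j <- i + 1
      tags <- character(0)
      while (j <= length(lines) && startsWith(lines[j], "_")) {
        tags <- c(tags, strsplit(lines[j], "[ \t]+")[[1]][1])
        j <- j + 1
      }
      vals <- character(0)
      while (j <= length(lines) && !startsWith(lines[j], "_") &&
             tolower(lines[j]) != "loop_" && !startsWith(lines[j], "data_")) {
        vals <- c(vals, .cif_tokens(lines[j]))
        j <- j + 1
      }
      if (length(tags) && length(vals) %% length(tags) == 0 && length(vals)) {
        rows <- matrix(vals, ncol = length(tags), byrow = TRUE)
        loops[[length(loops) + 1]] <- list(tags = tolower(tags), rows = rows)
      }
      i <- j
    } else i <- i + 1
  }
  loops
}

# tokenize one CIF data line, honoring single/double quotes
.cif_tokens <- function(line) {
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|[^ \t]+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

# apply "x,y,z"-style operators, deduplicate within tolerance
.expand_symmetry <- function(asu, symops, tol) {
  out <- list()
  for (op in symops) {
    M <- .parse_symop(op)
    xyz <- as.matrix(asu[, c("x", "y", "z")]) %*% t(M$rot) +
      matrix(M$tr, nrow(asu), 3, byrow = TRUE)
    xyz <- xyz - floor(xyz)                       # wrap into [0,1)
    blk <- asu
    blk$x <- xyz[, 1]; blk$y <- xyz[, 2]; blk$z <- xyz[, 3]
    out[[length(out) + 1]] <- blk
  }
  all <- do.call(rbind, out)
  keep <- rep(TRUE, nrow(all))
  pos <- as.matrix(all[, c("x", "y", "z")])
  for (i in seq_len(nrow(all))[-1]) {
    if (!any(keep[1:(i - 1)])) next
    prev <- pos[1:(i - 1), , drop = FALSE][keep[1:(i - 1)], , drop = FALSE]
    dd <- abs(sweep(prev, 2, pos[i, ]))
    dd <- pmin(dd, 1 - dd)                         # periodic distance
    if (any(rowSums(dd^2) < tol^2)) keep[i] <- FALSE
  }
  res <- all[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# "−x, y+1/2, -z" -> rotation matrix + translation
.parse_symop <- function(op) {
  parts <- strsplit(gsub(" ", "", tolower(op)), ",")[[1]]
  if (length(parts) != 3) stop(sprintf("bad symmetry operator '%s'", op))
  rot <- matrix(0, 3, 3); tr <- numeric(3)
  for (r in 1:3) {
    expr <- parts[r]
    # coefficients of x, y, z
    for (ax in 1:3) {
      v <- c("x", "y", "z")[ax]
      if (grepl(paste0("-", v), expr, fixed = TRUE)) rot[r, ax] <- -1
      else if (grepl(v, expr, fixed = TRUE)) rot[r, ax] <- 1
      expr <- gsub(paste0("[+-]?", v), "", expr)
    }
    if (nzchar(expr)) {
      if (grepl("/", expr, fixed = TRUE)) {
        nd <- as.numeric(strsplit(sub("^\\+", "", expr), "/")[[1]])
        tr[r] <- nd[1] / nd[2]
      } else tr[r] <- as.numeric(expr)
    }
  }
  list(rot = rot, tr = tr)
}
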