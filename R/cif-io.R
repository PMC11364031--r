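#' @include cell-symmetry.R
NULL

# ---- minimal small-molecule CIF parser ----------------------------------

.cifTokenize <- function(lines) {
  toks <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^;", ln)) {            # multi-line text field
      buf <- character()
      i <- i + 1
      while (i <= length(lines) && !grepl("^;", lines[i])) {
        buf <- c(buf, lines[i]); i <- i + 1
      }
      toks[[length(toks) + 1]] <- paste(buf, collapse = "\n")
      i <- i + 1
      next
    }
    ln <- sub("(^|\\s)#.*$", "", ln)
    while (nzchar(trimws(ln))) {
      ln <- sub("^\\s+", "", ln)
      if (grepl("^'", ln)) {
        m <- regexpr("^'([^']*)'", ln)
        toks[[length(toks) + 1]] <- gsub("^'|'$", "", regmatches(ln, m))
        ln <- substr(ln, attr(m, "match.length") + 1, nchar(ln))
      } else if (grepl('^"', ln)) {
        m <- regexpr('^"([^"]*)"', ln)
        toks[[length(toks) + 1]] <- gsub('^"|"$', "", regmatches(ln, m))
        ln <- substr(ln, attr(m, "match.length") + 1, nchar(ln))
      } else {
        m <- regexpr("^\\S+", ln)
        toks[[length(toks) + 1]] <- regmatches(ln, m)
        ln <- substr(ln, attr(m, "match.length") + 1, nchar(ln))
      }
    }
    i <- i + 1
  }
  unlist(toks)
}

# parse tokens into named items and loop tables, split by data block
.cifParse <- function(tokens) {
  blocks <- list()
  cur <- NULL; curName <- NULL
  i <- 1
  flush <- function() if (!is.null(cur)) blocks[[curName]] <<- cur
  while (i <= length(tokens)) {
    tk <- tokens[i]
    if (grepl("^data_", tk, ignore.case = TRUE)) {
      flush()
      curName <- sub("^data_", "", tk, ignore.case = TRUE)
      cur <- list(items = list(), loops = list())
      i <- i + 1
    } else if (tolower(tk) == "loop_") {
      hdr <- character()
      i <- i + 1
      while (i <= length(tokens) && grepl("^_", tokens[i])) {
        hdr <- c(hdr, tolower(tokens[i])); i <- i + 1
      }
      vals <- character()
      while (i <= length(tokens) && !grepl("^_", tokens[i]) &&
             !tolower(tokens[i]) %in% "loop_" &&
             !grepl("^data_", tokens[i], ignore.case = TRUE)) {
        vals <- c(vals, tokens[i]); i <- i + 1
      }
      if (length(vals) %% length(hdr) != 0)
        stop("CIF loop with ragged rows: ", paste(hdr[1], "..."))
      tab <- as.data.frame(matrix(vals, ncol = length(hdr), byrow = TRUE),
                           stringsAsFactors = FALSE)
      colnames(tab) <- hdr
      cur$loops[[length(cur$loops) + 1]] <- tab
    } else if (grepl("^_", tk)) {
      cur$items[[tolower(tk)]] <- tokens[i + 1]
      i <- i + 2
    } else i <- i + 1
  }
  flush()
  blocks
}

.cifNum <- function(x) as.numeric(sub("\\(.*\\)", "", x))

.findLoop <- function(block, tag) {
  for (tab in block$loops) if (tag %in% colnames(tab)) return(tab)
  NULL
}

.firstItem <- function(block, tags) {
  for (tg in tags) if (!is.null(block$items[[tg]])) return(block$items[[tg]])
  NULL
}

#' Read a small-molecule CIF file
#'
#' Parses cell, symmetry operations, atom sites with isotropic or
#' anisotropic displacement parameters, and (when present) an F-squared
#' reflection loop.
#'
#' @param path File path.
#' @param block Data-block name (default: first block).
#' @return List with elements \code{structure} (a \code{CrystalStructure})
#'   and \code{reflections} (a \code{ReflectionSet} or NULL).
#' @export
readCif <- function(path, block = NULL) {
  blocks <- .cifParse(.cifTokenize(readLines(path)))
  if (length(blocks) == 0) stop("no data block in ", path)
  bl <- if (is.null(block)) blocks[[1]]
        else blocks[[block]]
  if (is.null(bl)) stop("data block '", block, "' not found; available: ",
                        paste(names(blocks), collapse = ", "))
  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c")
  missing <- need[!need %in% names(bl$items)]
  if (length(missing))
    stop("CIF is missing mandatory item(s): ", paste(missing, collapse = ", "))
  cell <- unitCell(.cifNum(bl$items[["_cell_length_a"]]),
                   .cifNum(bl$items[["_cell_length_b"]]),
                   .cifNum(bl$items[["_cell_length_c"]]),
                   .cifNum(.firstItem(bl, "_cell_angle_alpha") %||% "90"),
                   .cifNum(.firstItem(bl, "_cell_angle_beta") %||% "90"),
                   .cifNum(.firstItem(bl, "_cell_angle_gamma") %||% "90"))
  symbol <- .firstItem(bl, c("_space_group_name_h-m_alt",
                             "_symmetry_space_group_name_h-m")) %||% "P1"
  symbol <- gsub(" ", "", symbol)
  symTab <- .findLoop(bl, "_space_group_symop_operation_xyz") %||%
    .findLoop(bl, "_symmetry_equiv_pos_as_xyz")
  sg <- if (!is.null(symTab)) {
    col <- intersect(c("_space_group_symop_operation_xyz",
                       "_symmetry_equiv_pos_as_xyz"), colnames(symTab))[1]
    spaceGroup(symbol, symTab[[col]])
  } else spaceGroup(symbol)
  at <- .findLoop(bl, "_atom_site_label")
  if (is.null(at)) stop("CIF has no atom_site loop")
  sites <- data.frame(
    label = at[["_atom_site_label"]],
    element = at[["_atom_site_type_symbol"]] %||%
      sub("[0-9]+[A-Za-z]*$", "", at[["_atom_site_label"]]),
    x = .cifNum(at[["_atom_site_fract_x"]]),
    y = .cifNum(at[["_atom_site_fract_y"]]),
    z = .cifNum(at[["_atom_site_fract_z"]]),
    occ = if (!is.null(at[["_atom_site_occupancy"]]))
      .cifNum(at[["_atom_site_occupancy"]]) else 1,
    adpType = if (!is.null(at[["_atom_site_adp_type"]]))
      ifelse(tolower(at[["_atom_site_adp_type"]]) %in% c("uani", "aniso"),
             "aniso", "iso") else "iso",
    uiso = if (!is.null(at[["_atom_site_u_iso_or_equiv"]]))
      .cifNum(at[["_atom_site_u_iso_or_equiv"]]) else 0,
    partId = if (!is.null(at[["_atom_site_disorder_group"]]))
      suppressWarnings(as.integer(at[["_atom_site_disorder_group"]])) else 1L,
    stringsAsFactors = FALSE)
  sites$partId[is.na(sites$partId)] <- 1L
  an <- .findLoop(bl, "_atom_site_aniso_label")
  for (cn in c("u11", "u22", "u33", "u12", "u13", "u23"))
    sites[[cn]] <- NA_real_
  if (!is.null(an)) {
    idx <- match(an[["_atom_site_aniso_label"]], sites$label)
    map <- c(u11 = "_atom_site_aniso_u_11", u22 = "_atom_site_aniso_u_22",
             u33 = "_atom_site_aniso_u_33", u12 = "_atom_site_aniso_u_12",
             u13 = "_atom_site_aniso_u_13", u23 = "_atom_site_aniso_u_23")
    for (cn in names(map)) sites[[cn]][idx] <- .cifNum(an[[map[[cn]]]])
    sites$adpType[idx] <- "aniso"
  }
  structure <- crystalStructure(cell, sg, sites)
  refl <- NULL
  rf <- .findLoop(bl, "_refln_index_h")
  if (!is.null(rf) && !is.null(rf[["_refln_f_squared_meas"]])) {
    refl <- reflectionSet(
      cbind(as.integer(rf[["_refln_index_h"]]),
            as.integer(rf[["_refln_index_k"]]),
            as.integer(rf[["_refln_index_l"]])),
      .cifNum(rf[["_refln_f_squared_meas"]]),
      .cifNum(rf[["_refln_f_squared_sigma"]]), cell)
  }
  list(structure = structure, reflections = refl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a small-molecule CIF file
#'
#' @param structure A \code{CrystalStructure}.
#' @param path Output path.
#' @param block Data-block name.
#' @param reflections Optional \code{ReflectionSet} written as a refln
#'   loop.
#' @return Invisibly, the path.
#' @export
writeCif <- function(structure, path, block = "structure",
                     reflections = NULL) {
  cell <- structure@cell; st <- structure@sites
  sg <- structure@spaceGroup
  p <- cellParameters(cell)
  out <- c(
    paste0("data_", block),
    sprintf("_space_group_name_H-M_alt         '%s'", sg@symbol),
    sprintf("_cell_length_a                    %.6f", p[1]),
    sprintf("_cell_length_b                    %.6f", p[2]),
    sprintf("_cell_length_c                    %.6f", p[3]),
    sprintf("_cell_angle_alpha                 %.4f", p[4]),
    sprintf("_cell_angle_beta                  %.4f", p[5]),
    sprintf("_cell_angle_gamma                 %.4f", p[6]),
    "loop_", "_space_group_symop_operation_xyz",
    vapply(seq_along(sg@rotations), function(i)
      sprintf("  '%s'", .symopString(sg@rotations[[i]], sg@translations[[i]])),
      character(1)),
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "_atom_site_occupancy", "_atom_site_adp_type",
    "_atom_site_U_iso_or_equiv", "_atom_site_disorder_group",
    sprintf("%-6s %-2s %10.6f %10.6f %10.6f %8.4f %-5s %9.6f %d",
            st$label, st$element, st$x, st$y, st$z, st$occ,
            ifelse(st$adpType == "aniso", "Uani", "Uiso"),
            ifelse(st$adpType == "aniso",
                   (st$u11 + st$u22 + st$u33) / 3, st$uiso),
            st$partId))
  an <- st[st$adpType == "aniso", ]
  if (nrow(an) > 0) {
    out <- c(out, "loop_", "_atom_site_aniso_label",
             "_atom_site_aniso_U_11", "_atom_site_aniso_U_22",
             "_atom_site_aniso_U_33", "_atom_site_aniso_U_12",
             "_atom_site_aniso_U_13", "_atom_site_aniso_U_23",
             sprintf("%-6s %9.6f %9.6f %9.6f %9.6f %9.6f %9.6f", an$label,
                     an$u11, an$u22, an$u33, an$u12, an$u13, an$u23))
  }
  if (!is.null(reflections)) {
    out <- c(out, "loop_", "_refln_index_h", "_refln_index_k",
             "_refln_index_l", "_refln_F_squared_meas",
             "_refln_F_squared_sigma",
             sprintf("%4d %4d %4d %12.4f %12.4f", reflections@hkl[, 1],
                     reflections@hkl[, 2], reflections@hkl[, 3],
                     reflections@fobs2, reflections@sigma))
  }
  writeLines(out, path)
  invisible(path)
}
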