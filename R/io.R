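# CIF and (extended-)XYZ readers/writers. The CIF subset covers cell
# parameters, P1 or operator-expanded atom sites; unknown tags are ignored.

#' Read a crystal structure from CIF text or file
#'
#' Supports symmetry-expanded (P1) files and files carrying an operator loop
#' (`_symmetry_equiv_pos_as_xyz` / `_space_group_symop_operation_xyz`), in
#' which case sites are expanded to the full P1 set and coincident duplicates
#' merged.
#'
#' @param x Path to a `.cif` file, or a character vector/scalar of CIF text.
#' @param merge_tol Fractional distance below which operator-generated images
#'   of a site are merged (default 1e-4, in Angstrom via the cell).
#' @return A `csp_crystal` (P1 site list).
#' @export
read_cif <- function(x, merge_tol = 1e-3) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(paste(x, collapse = "\n"), "\n"))
  }
  lines <- trimws(lines)
  lines <- lines[!grepl("^#", lines)]

  numtag <- function(tag) {
    hit <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (length(hit) == 0) return(NA_real_)
    val <- sub(paste0("^", tag, "\\s+"), "", hit[1])
    as.numeric(sub("\\(.*\\)", "", val))      # strip esd parentheses
  }
  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
            "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  vals <- vapply(need, numtag, 0)
  if (any(is.na(vals))) {
    stop("CIF missing cell tag(s): ", paste(need[is.na(vals)], collapse = ", "))
  }
  lat <- lattice_from_params(vals)

  # parse loops
  loops <- list()
  i <- 1
  while (i <= length(lines)) {
    if (identical(lines[i], "loop_")) {
      hdr <- character(0); i <- i + 1
      while (i <= length(lines) && grepl("^_", lines[i])) {
        hdr <- c(hdr, strsplit(lines[i], "\\s+")[[1]][1]); i <- i + 1
      }
      rows <- list()
      while (i <= length(lines) && nzchar(lines[i]) &&
             !grepl("^(_|loop_|data_)", lines[i])) {
        rows[[length(rows) + 1]] <- scan(text = lines[i], what = "character",
                                         quiet = TRUE)
        i <- i + 1
      }
      loops[[length(loops) + 1]] <- list(header = hdr, rows = rows)
    } else i <- i + 1
  }

  find_loop <- function(tag) {
    for (lp in loops) if (any(grepl(tag, lp$header))) return(lp)
    NULL
  }
  sites <- find_loop("_atom_site_fract_x")
  if (is.null(sites)) stop("CIF missing _atom_site loop")
  h <- sites$header
  col <- function(tag) which(h == tag)[1]
  ix <- col("_atom_site_fract_x"); iy <- col("_atom_site_fract_y")
  iz <- col("_atom_site_fract_z")
  isym <- col("_atom_site_type_symbol")
  if (is.na(isym)) isym <- col("_atom_site_label")
  rows <- sites$rows
  species <- vapply(rows, function(r) sub("[0-9+\\-].*$", "", r[isym]), "")
  stripnum <- function(s) as.numeric(sub("\\(.*\\)", "", s))
  fr <- t(vapply(rows, function(r) c(stripnum(r[ix]), stripnum(r[iy]),
                                     stripnum(r[iz])), numeric(3)))

  ops_loop <- find_loop("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz")
  if (!is.null(ops_loop)) {
    oph <- ops_loop$header
    k <- grep("as_xyz|operation_xyz", oph)[1]
    opstr <- vapply(ops_loop$rows, function(r) {
      s <- paste(r[k:length(r)], collapse = "")
      gsub("'|\"", "", s)
    }, "")
    ops <- lapply(opstr, parse_symop)
    exp_sp <- character(0); exp_fr <- NULL
    for (s in seq_len(nrow(fr))) {
      for (op in ops) {
        p <- (op$W %*% fr[s, ] + op$w) %% 1
        if (!is.null(exp_fr)) {
          d <- vapply(seq_len(nrow(exp_fr)), function(q) {
            if (exp_sp[q] != species[s]) return(Inf)
            min_image_distance(lat, exp_fr[q, ], p)
          }, 0)
          if (any(d < merge_tol)) next
        }
        exp_sp <- c(exp_sp, species[s])
        exp_fr <- rbind(exp_fr, as.numeric(p))
      }
    }
    species <- exp_sp; fr <- exp_fr
  }
  crystal_structure(lat, species, fr)
}

#' Write a crystal structure as a P1 CIF
#'
#' @param crystal A `csp_crystal`.
#' @param path Output path; if `NULL`, the CIF text is returned invisibly.
#' @param name Data block name.
#' @return The CIF text, invisibly.
#' @export
write_cif <- function(crystal, path = NULL, name = "cspkit") {
  p <- lattice_params(crystal$lattice)
  txt <- c(
    paste0("data_", name),
    sprintf("_cell_length_a    %.10f", p[1]),
    sprintf("_cell_length_b    %.10f", p[2]),
    sprintf("_cell_length_c    %.10f", p[3]),
    sprintf("_cell_angle_alpha %.10f", p[4]),
    sprintf("_cell_angle_beta  %.10f", p[5]),
    sprintf("_cell_angle_gamma %.10f", p[6]),
    "_symmetry_space_group_name_H-M 'P 1'",
    "_symmetry_Int_Tables_number 1",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    vapply(seq_along(crystal$species), function(i) {
      sprintf("%s%d %s %.10f %.10f %.10f",
              crystal$species[i], i, crystal$species[i],
              crystal$frac_coords[i, 1], crystal$frac_coords[i, 2],
              crystal$frac_coords[i, 3])
    }, "")
  )
  if (!is.null(path)) writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}

#' Read / write (extended-)XYZ
#'
#' `read_xyz()` returns a `csp_molecule` for plain XYZ and a `csp_crystal`
#' when the comment line carries a `Lattice="..."` header. `write_xyz()`
#' accepts molecules, n-mers and crystals (crystals get a Lattice header).
#'
#' @param x Path or character vector of XYZ text.
#' @param frame For multi-frame files, which frame to read (default 1).
#' @return See description.
#' @export
read_xyz <- function(x, frame = 1) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else unlist(strsplit(paste(x, collapse = "\n"), "\n"))
  i <- 1; f <- 0
  while (i <= length(lines)) {
    nat <- as.integer(trimws(lines[i]))
    if (is.na(nat)) stop("malformed XYZ: expected atom count at line ", i)
    f <- f + 1
    if (f == frame) {
      comment <- lines[i + 1]
      body <- lines[(i + 2):(i + 1 + nat)]
      toks <- lapply(body, function(s) scan(text = s, what = "character", quiet = TRUE))
      sym <- vapply(toks, `[`, "", 1)
      pos <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
      m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
      if (length(m) == 1) {
        nums <- as.numeric(scan(text = gsub('Lattice="|"', "", m), what = "character",
                                quiet = TRUE))
        cell <- matrix(nums, 3, 3, byrow = TRUE)
        lat <- lattice(cell)
        return(crystal_structure(lat, sym,
                                 coords_convert(lat, pos, "cart_to_frac")))
      }
      return(molecule(sym, pos))
    }
    i <- i + 2 + nat
  }
  stop("frame ", frame, " not present")
}

#' @rdname read_xyz
#' @param geom A `csp_molecule`, `csp_nmer` or `csp_crystal`.
#' @param path Output path (`NULL` to return text).
#' @param comment Extra comment-line metadata.
#' @param append Append as an additional frame.
#' @export
write_xyz <- function(geom, path = NULL, comment = "", append = FALSE) {
  at <- as_atoms(geom)
  head2 <- comment
  if (inherits(geom, "csp_crystal")) {
    cell <- as.matrix(geom$lattice)
    head2 <- paste0('Lattice="', paste(sprintf("%.10f", t(cell)), collapse = " "),
                    '" Properties=species:S:1:pos:R:3 ', comment)
  }
  txt <- c(length(at$symbols), head2,
           vapply(seq_along(at$symbols), function(i) {
             sprintf("%s %.10f %.10f %.10f", at$symbols[i],
                     at$positions[i, 1], at$positions[i, 2], at$positions[i, 3])
           }, ""))
  if (!is.null(path)) {
    if (append) cat(paste(txt, collapse = "\n"), "\n", sep = "", file = path,
                    append = TRUE)
    else writeLines(txt, path)
  }
  invisible(paste(txt, collapse = "\n"))
}
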