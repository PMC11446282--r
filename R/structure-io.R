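#' Read a predicted complex structure into an atom tibble
#'
#' Parses a PDB or mmCIF file (optionally gzipped) into a tidy atom table:
#' one row per atom with chain id, author residue number, residue name, atom
#' name, element, coordinates and the B-factor column (which structure
#' prediction servers reuse for per-residue pLDDT). Chain roles are assigned
#' at read time: the chain named by `receptor_chain` (default: the first
#' chain in the file) becomes the receptor, all remaining chains the binder
#' side. Screening expects exactly one receptor and one binder chain.
#'
#' @param path path to a `.pdb`, `.cif` or gzipped variant.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param receptor_chain chain id to mark as receptor; `NULL` takes the first
#'   chain in file order.
#' @return a tibble of class `hs_structure` with columns `chain`, `role`,
#'   `resid` (author numbering), `resname`, `atom`, `element`, `x`, `y`, `z`,
#'   `b`, `het` (logical, HETATM record).
#' @details Insertion codes are rejected with an error (prediction outputs do
#'   not use them); only the first alternate location is kept. Multi-model
#'   files keep the first model (bio3d behaviour).
#' @seealso [write_structure()], [read_confidence()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           receptor_chain = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("structure file does not exist: ", path, call. = FALSE)
  }
  real <- path
  if (grepl("\\.gz$", path, ignore.case = TRUE)) {
    real <- tempfile(fileext = sub("\\.gz$", "", basename(path)))
    writeLines(readLines(gzfile(path)), real)
    on.exit(unlink(real), add = TRUE)
  }
  if (format == "auto") {
    base <- sub("\\.gz$", "", path, ignore.case = TRUE)
    format <- if (grepl("\\.(cif|mmcif)$", base, ignore.case = TRUE)) {
      "mmcif"
    } else {
      "pdb"
    }
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(real, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(real, verbose = FALSE)),
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no atoms in structure: ", path, call. = FALSE)
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported (found in ", path, ")",
         call. = FALSE)
  }
  # first altloc only
  keep_alt <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep_alt, , drop = FALSE]
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  tbl <- tibble::tibble(
    chain = chain,
    resid = as.integer(at$resno),
    resname = at$resid,
    atom = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(gsub("[0-9']", "", at$elety), 1, 1), at$elesy),
    x = at$x, y = at$y, z = at$z,
    b = ifelse(is.na(at$b), 0, at$b),
    het = at$type == "HETATM"
  )
  polymer <- !tbl$het | !(tbl$resname %in% c("HOH", "WAT", "DOD"))
  tbl <- tbl[polymer, , drop = FALSE]
  if (nrow(tbl) == 0L) stop("no polymer chains in structure: ", path,
                            call. = FALSE)
  if (anyNA(tbl$x) || anyNA(tbl$y) || anyNA(tbl$z)) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  new_structure(tbl, receptor_chain = receptor_chain)
}

#' Construct / validate a structure tibble
#'
#' @param atoms data frame with at least `chain`, `resid`, `resname`, `atom`,
#'   `x`, `y`, `z`; missing `element`, `b`, `het`, `role` columns are filled.
#' @param receptor_chain chain id to mark as receptor (`NULL`: first chain).
#' @return `hs_structure` tibble.
#' @export
new_structure <- function(atoms, receptor_chain = NULL) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("chain", "resid", "resname", "atom", "x", "y", "z")
  missing <- setdiff(need, names(atoms))
  if (length(missing)) {
    stop("structure table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) == 0L) stop("empty structure", call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (!"element" %in% names(atoms)) {
    atoms$element <- substr(gsub("[0-9']", "", atoms$atom), 1, 1)
  }
  if (!"b" %in% names(atoms)) atoms$b <- 0
  if (!"het" %in% names(atoms)) atoms$het <- FALSE
  atoms$resid <- as.integer(atoms$resid)
  # residue ids unique within chain (same resid must be contiguous)
  dup <- atoms |>
    dplyr::distinct(.data$chain, .data$resid) |>
    dplyr::count(.data$chain, .data$resid) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) stop("duplicated residue ids within a chain", call. = FALSE)
  atoms <- set_chain_roles(atoms, receptor_chain)
  cols <- c("chain", "role", "resid", "resname", "atom", "element",
            "x", "y", "z", "b", "het")
  atoms <- atoms[, cols]
  class(atoms) <- c("hs_structure", class(tibble::tibble()))
  atoms
}

#' Assign receptor / binder roles to chains
#'
#' @param model structure tibble.
#' @param receptor_chain chain id of the receptor; `NULL` keeps an existing
#'   assignment or defaults to the first chain in file order.
#' @return structure tibble with a `role` column (`receptor`, `binder`, or
#'   `unassigned` for chains beyond the first two).
#' @export
set_chain_roles <- function(model, receptor_chain = NULL) {
  chains <- unique(model$chain)
  if (is.null(receptor_chain)) {
    if ("role" %in% names(model) && any(model$role == "receptor")) {
      return(model)
    }
    receptor_chain <- chains[1]
  }
  if (!receptor_chain %in% chains) {
    stop("receptor chain '", receptor_chain, "' not present; chains: ",
         paste(chains, collapse = ", "), call. = FALSE)
  }
  others <- setdiff(chains, receptor_chain)
  model$role <- dplyr::case_when(
    model$chain == receptor_chain ~ "receptor",
    model$chain %in% others[seq_len(min(1, length(others)))] ~ "binder",
    TRUE ~ "unassigned"
  )
  model
}

chain_of_role <- function(model, role) {
  ch <- unique(model$chain[model$role == role])
  if (length(ch) != 1L) {
    stop("model must have exactly one ", role, " chain (found ",
         length(ch), ")", call. = FALSE)
  }
  ch
}

#' Write a structure tibble to PDB or mmCIF
#'
#' PDB output goes through `bio3d::write.pdb()`; mmCIF output writes a
#' minimal `atom_site` loop readable by standard mmCIF parsers. Coordinates
#' survive a PDB round trip to the format's 1e-3 Angstrom column precision.
#'
#' @param model structure tibble.
#' @param path output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
      "mmcif"
    } else {
      "pdb"
    }
  }
  if (nrow(model) == 0L) stop("refusing to write an empty model",
                              call. = FALSE)
  if (!all(is.finite(model$x) & is.finite(model$y) & is.finite(model$z))) {
    stop("refusing to write non-finite coordinates", call. = FALSE)
  }
  if (format == "pdb") {
    xyz <- as.numeric(t(as.matrix(model[, c("x", "y", "z")])))
    bio3d::write.pdb(
      file = path, xyz = xyz,
      type = ifelse(model$het, "HETATM", "ATOM"),
      resno = model$resid, resid = model$resname,
      eleno = seq_len(nrow(model)), elety = model$atom,
      chain = model$chain, o = rep(1, nrow(model)), b = model$b,
      elesy = model$element, end = TRUE
    )
  } else {
    write_mmcif(model, path)
  }
  invisible(path)
}

# Minimal mmCIF atom_site writer in the canonical PDBx column order (no
# installed R package writes mmCIF).
write_mmcif <- function(model, path) {
  header <- c(
    "data_helixscreen",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  seq_in_chain <- stats::ave(model$resid, model$chain,
                             FUN = function(r) match(r, unique(r)))
  lines <- sprintf(
    paste("%-6s %d %s %-4s . %-3s %s 1 %d ? %.3f %.3f %.3f 1.00 %.2f",
          "? %d %-3s %s %-4s 1"),
    ifelse(model$het, "HETATM", "ATOM"), seq_len(nrow(model)),
    model$element, model$atom, model$resname, model$chain, seq_in_chain,
    model$x, model$y, model$z, model$b,
    model$resid, model$resname, model$chain, model$atom
  )
  writeLines(c(header, lines, "#"), path)
  invisible(path)
}

residue_table <- function(model) {
  model |>
    dplyr::distinct(.data$chain, .data$role, .data$resid, .data$resname)
}
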