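#' Backbone dihedral angles of a chain
#'
#' Computes phi/psi per residue from N, CA, C atoms. Residues missing any
#' backbone atom get NA angles with a warning (never silently helical).
#'
#' @param model structure tibble.
#' @param chain chain id.
#' @return tibble `resid`, `resname`, `phi`, `psi` (degrees; NA at termini
#'   and wherever a neighbour's backbone is missing).
#' @export
backbone_dihedrals <- function(model, chain) {
  at <- model[model$chain == chain & !model$het, ]
  if (nrow(at) == 0L) stop("no atoms in chain ", chain, call. = FALSE)
  resids <- unique(at$resid)
  bb <- function(resid, name) {
    row <- at[at$resid == resid & at$atom == name, ]
    if (nrow(row) == 0L) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  n <- length(resids)
  phi <- psi <- rep(NA_real_, n)
  missing_bb <- logical(n)
  coords <- lapply(resids, function(r) {
    list(N = bb(r, "N"), CA = bb(r, "CA"), C = bb(r, "C"))
  })
  for (i in seq_len(n)) {
    this <- coords[[i]]
    if (is.null(this$N) || is.null(this$CA) || is.null(this$C)) {
      missing_bb[i] <- TRUE
      next
    }
    # phi needs previous C; psi needs next N; require sequential numbering
    if (i > 1 && resids[i - 1] == resids[i] - 1 &&
        !is.null(coords[[i - 1]]$C)) {
      phi[i] <- dihedral(coords[[i - 1]]$C, this$N, this$CA, this$C)
    }
    if (i < n && resids[i + 1] == resids[i] + 1 &&
        !is.null(coords[[i + 1]]$N)) {
      psi[i] <- dihedral(this$N, this$CA, this$C, coords[[i + 1]]$N)
    }
  }
  if (any(missing_bb)) {
    warning("skipped ", sum(missing_bb), " residue(s) with missing ",
            "backbone atoms in chain ", chain, call. = FALSE)
  }
  resnames <- vapply(resids, function(r) at$resname[at$resid == r][1], "")
  tibble::tibble(resid = resids, resname = resnames, phi = phi, psi = psi)
}

#' Assign alpha-helical segments from backbone dihedrals
#'
#' A residue is helical iff both its phi and psi exist and fall inside the
#' alpha-helical window (`phi` in (-100, -30), `psi` in (-80, -5) degrees);
#' helices are maximal runs of at least `min_length` helical residues. The
#' window is deliberately backbone-only and deterministic (no hydrogen-bond
#' energy model) and can be widened or narrowed by the caller.
#'
#' @param model structure tibble.
#' @param chain chain id (default: the binder chain).
#' @param phi_range,psi_range open intervals in degrees.
#' @param min_length minimum run length counted as a helix.
#' @return tibble of class `helix_segments`: `chain`, `start`, `end`
#'   (author ids, inclusive), `length`.
#' @export
assign_helices <- function(model, chain = NULL,
                           phi_range = c(-100, -30),
                           psi_range = c(-80, -5),
                           min_length = 4) {
  if (is.null(chain)) chain <- chain_of_role(model, "binder")
  dh <- backbone_dihedrals(model, chain)
  helical <- !is.na(dh$phi) & !is.na(dh$psi) &
    dh$phi > phi_range[1] & dh$phi < phi_range[2] &
    dh$psi > psi_range[1] & dh$psi < psi_range[2]
  runs <- rle(helical)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_length
  seg <- tibble::tibble(
    chain = chain,
    start = dh$resid[starts[keep]],
    end = dh$resid[ends[keep]]
  ) |>
    dplyr::mutate(length = .data$end - .data$start + 1L)
  class(seg) <- c("helix_segments", class(tibble::tibble()))
  seg
}

#' Label binder interface residues by the receptor patch they contact
#'
#' A binder residue is labelled with a patch iff it has at least one
#' interface pair whose receptor residue belongs to that patch; multiple
#' labels per residue are allowed.
#'
#' @param iface `interface_map` computed against the same site.
#' @param site [binding_site()] definition.
#' @return tibble `binder_chain`, `binder_resid`, `patch` (long form, one
#'   row per residue-patch label).
#' @export
classify_patch_contacts <- function(iface, site) {
  if (nrow(iface) == 0L) {
    return(tibble::tibble(binder_chain = character(),
                          binder_resid = integer(), patch = character()))
  }
  stray <- setdiff(unique(iface$receptor_resid), site$site)
  if (length(stray)) {
    stop("interface receptor residues outside the binding site: ",
         paste(stray, collapse = ", "),
         " - was the map computed against this site?", call. = FALSE)
  }
  iface |>
    tibble::as_tibble() |>
    dplyr::mutate(patch = patch_of(site, .data$receptor_resid)) |>
    dplyr::filter(!is.na(.data$patch)) |>
    dplyr::distinct(.data$binder_chain, .data$binder_resid, .data$patch) |>
    dplyr::arrange(.data$binder_resid, .data$patch)
}

#' Assign the helix binding register
#'
#' Picks the binding helix and anchors the register. The binding helix is
#' the segment containing the most patch-1-labelled residues (ties broken by
#' total interface residues in the helix, then by the most N-terminal
#' start). The anchor i is the most N-terminal helix residue r such that
#' both r and r+4 carry patch 1; if no such i/i+4 pair exists, the anchor is
#' the patch-1 residue with the most atom-level contacts to patch-1 receptor
#' residues. Offsets 0, 1, 2, 4, 5 relative to the anchor are then read off
#' the patch labels; contacts at other offsets or outside the binding helix
#' are reported as unassigned, never folded into the register.
#'
#' @param helices [assign_helices()] output (must be non-empty).
#' @param patch_contacts [classify_patch_contacts()] output.
#' @param iface the `interface_map` the labels came from.
#' @return object of class `register_assignment`: tibble with one row per
#'   register offset present (`offset`, `resid`, `resname`, `patches`
#'   comma-joined) and attributes `anchor`, `helix` (one-row segment),
#'   `unassigned_contacts` (tibble), `chain`.
#' @param model structure tibble (for residue names).
#' @export
assign_register <- function(helices, patch_contacts, iface, model) {
  if (nrow(helices) == 0L) stop("no helices assigned", call. = FALSE)
  p1 <- patch_contacts |> dplyr::filter(.data$patch == "patch1")
  if (nrow(p1) == 0L) {
    stop("no patch-1 contacts: non-canonical binder (register undefined)",
         call. = FALSE)
  }
  chain <- helices$chain[1]
  n_iface_in <- function(s, e) {
    sum(binder_iface(iface) >= s & binder_iface(iface) <= e)
  }
  scored <- helices |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_p1 = sum(p1$binder_resid >= .data$start & p1$binder_resid <= .data$end),
      n_if = n_iface_in(.data$start, .data$end)
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$n_p1), dplyr::desc(.data$n_if),
                   .data$start)
  if (scored$n_p1[1] == 0L) {
    stop("no patch-1 contacts inside any helix: non-canonical binder",
         call. = FALSE)
  }
  bh <- scored[1, c("chain", "start", "end", "length")]
  p1_in <- sort(p1$binder_resid[p1$binder_resid >= bh$start &
                                  p1$binder_resid <= bh$end])
  anchor <- NA_integer_
  for (r in p1_in) {
    if ((r + 4) %in% p1_in && r + 4 <= bh$end) { anchor <- r; break }
  }
  if (is.na(anchor)) {
    # fallback: patch-1 residue with the most atom contacts to patch-1
    contacts <- iface |>
      tibble::as_tibble() |>
      dplyr::filter(.data$binder_resid %in% p1_in) |>
      dplyr::group_by(.data$binder_resid) |>
      dplyr::summarise(n = sum(.data$n_atom_contacts), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$n), .data$binder_resid)
    anchor <- contacts$binder_resid[1]
  }
  offsets <- c(0L, 1L, 2L, 4L, 5L)
  labs <- patch_contacts |>
    dplyr::group_by(.data$binder_resid) |>
    dplyr::summarise(patches = paste(sort(unique(.data$patch)),
                                     collapse = ","), .groups = "drop")
  res_tbl <- residue_table(model) |> dplyr::filter(.data$chain == !!chain)
  reg <- tibble::tibble(offset = offsets, resid = anchor + offsets) |>
    dplyr::filter(.data$resid <= bh$end, .data$resid >= bh$start) |>
    dplyr::left_join(labs, by = c(resid = "binder_resid")) |>
    dplyr::left_join(res_tbl[, c("resid", "resname")], by = "resid") |>
    dplyr::filter(!is.na(.data$patches) | .data$offset == 0L)
  unassigned <- labs |>
    dplyr::filter(!.data$binder_resid %in% reg$resid) |>
    dplyr::rename(resid = "binder_resid")
  out <- reg
  attr(out, "anchor") <- anchor
  attr(out, "helix") <- bh
  attr(out, "chain") <- chain
  attr(out, "unassigned_contacts") <- unassigned
  class(out) <- c("register_assignment", class(tibble::tibble()))
  out
}

#' Anchor / binding helix / unassigned contacts of a register assignment
#' @param assignment a `register_assignment`.
#' @return `register_anchor()`: the anchor author id; `binding_helix()`: a
#'   one-row helix segment tibble; `unassigned_contacts()`: tibble of
#'   labelled residues outside the register offsets.
#' @export
register_anchor <- function(assignment) attr(assignment, "anchor")

#' @rdname register_anchor
#' @export
binding_helix <- function(assignment) attr(assignment, "helix")

#' @rdname register_anchor
#' @export
unassigned_contacts <- function(assignment) {
  attr(assignment, "unassigned_contacts")
}

aa_three_to_one <- function(resname) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  out <- unname(map[resname])
  out[is.na(out)] <- "X"
  out
}

#' Plain-text motif report for a register assignment
#'
#' Renders the binding helix plus five residues of flank on each side as a
#' one-letter sequence line, a helix-extent line (`H` under helix
#' residues), a patch line (`1`/`2`/`3`/`f` under contacting residues, `*`
#' where a residue touches more than one patch) and an anchor line (`i`
#' under the anchor). Output is deterministic and invariant to rigid-body
#' transformation of the model.
#'
#' @param assignment a `register_assignment`.
#' @param model structure tibble.
#' @param patch_contacts [classify_patch_contacts()] output (for labels
#'   outside the register offsets); defaults to register labels only.
#' @return character vector of report lines (also printed invisibly-friendly
#'   via `cat(x, sep = "\n")`).
#' @export
motif_report <- function(assignment, model, patch_contacts = NULL) {
  chain <- attr(assignment, "chain")
  bh <- binding_helix(assignment)
  anchor <- register_anchor(assignment)
  res_tbl <- residue_table(model) |>
    dplyr::filter(.data$chain == !!chain) |>
    dplyr::arrange(.data$resid)
  lo <- max(min(res_tbl$resid), bh$start - 5L)
  hi <- min(max(res_tbl$resid), bh$end + 5L)
  span <- res_tbl |> dplyr::filter(.data$resid >= lo, .data$resid <= hi)
  labs <- if (is.null(patch_contacts)) {
    assignment |>
      dplyr::filter(!is.na(.data$patches)) |>
      dplyr::select("resid", "patches")
  } else {
    patch_contacts |>
      dplyr::group_by(.data$binder_resid) |>
      dplyr::summarise(patches = paste(sort(unique(.data$patch)),
                                       collapse = ","), .groups = "drop") |>
      dplyr::rename(resid = "binder_resid")
  }
  sym <- function(patches) {
    if (is.na(patches)) return(".")
    ps <- strsplit(patches, ",")[[1]]
    if (length(ps) > 1) return("*")
    switch(ps, patch1 = "1", patch2 = "2", patch3 = "3", flank = "f", "?")
  }
  span <- span |> dplyr::left_join(labs, by = "resid")
  seq_line <- paste(aa_three_to_one(span$resname), collapse = "")
  helix_line <- paste(ifelse(span$resid >= bh$start & span$resid <= bh$end,
                             "H", "."), collapse = "")
  patch_line <- paste(vapply(span$patches, sym, ""), collapse = "")
  anchor_line <- paste(ifelse(span$resid == anchor, "i", "."),
                       collapse = "")
  c(sprintf("chain %s residues %d-%d  binding helix %d-%d  anchor i = %d",
            chain, lo, hi, bh$start, bh$end, anchor),
    paste0("seq    : ", seq_line),
    paste0("helix  : ", helix_line),
    paste0("patches: ", patch_line),
    paste0("anchor : ", anchor_line))
}

#' Register assignment as a machine-readable table
#' @param assignment a `register_assignment`.
#' @return tibble `offset`, `resid`, `resname`, `patches`.
#' @export
register_table <- function(assignment) {
  tibble::as_tibble(assignment)[, c("offset", "resid", "resname", "patches")]
}
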