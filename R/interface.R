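#' Representative coordinate of a residue (C-beta rule)
#'
#' The coarse prefilter measures distances between side-chain-proximal
#' points: the C-beta atom where present, the C-alpha atom for glycine, and
#' (when `fallback` is allowed) the residue's first atom otherwise.
#'
#' @param residue atom tibble of a single residue.
#' @param fallback allow falling back to the first atom when neither CB nor
#'   a glycine CA exists.
#' @return numeric length-3 position (Angstrom).
#' @export
representative_coordinate <- function(residue, fallback = TRUE) {
  if (nrow(residue) == 0L) stop("residue has no atoms", call. = FALSE)
  cb <- residue[residue$atom == "CB", ]
  if (nrow(cb)) return(c(cb$x[1], cb$y[1], cb$z[1]))
  if (residue$resname[1] == "GLY") {
    ca <- residue[residue$atom == "CA", ]
    if (nrow(ca)) return(c(ca$x[1], ca$y[1], ca$z[1]))
  }
  if (!fallback) {
    stop("no representative atom (CB / glycine CA) for residue ",
         residue$resid[1], call. = FALSE)
  }
  c(residue$x[1], residue$y[1], residue$z[1])
}

# Table of representative coordinates, one row per residue.
representative_coordinates <- function(atoms, fallback = TRUE) {
  atoms |>
    dplyr::group_by(.data$chain, .data$resid) |>
    dplyr::group_modify(function(df, key) {
      p <- representative_coordinate(
        dplyr::mutate(df, chain = key$chain, resid = key$resid), fallback)
      tibble::tibble(rx = p[1], ry = p[2], rz = p[3])
    }) |>
    dplyr::ungroup()
}

# Cross-chain residue pair table with min atom-atom distance and atom contact
# counts, for the given candidate residue pairs (or all pairs when NULL).
residue_pair_distances <- function(bat, rat, candidates = NULL,
                                   cutoff = Inf) {
  bxyz <- as.matrix(bat[, c("x", "y", "z")])
  rxyz <- as.matrix(rat[, c("x", "y", "z")])
  d2 <- outer(rowSums(bxyz^2), rowSums(rxyz^2), `+`) -
    2 * bxyz %*% t(rxyz)
  d2[d2 < 0] <- 0
  key_b <- bat$resid
  key_r <- rat$resid
  df <- tibble::tibble(
    binder_resid = rep(key_b, times = length(key_r)),
    receptor_resid = rep(key_r, each = length(key_b)),
    d = sqrt(as.vector(d2))
  )
  if (!is.null(candidates)) {
    df <- dplyr::semi_join(df, candidates,
                           by = c("binder_resid", "receptor_resid"))
  }
  df |>
    dplyr::group_by(.data$binder_resid, .data$receptor_resid) |>
    dplyr::summarise(min_atom_distance = min(.data$d),
                     n_atom_contacts = sum(.data$d <= cutoff),
                     .groups = "drop")
}

interface_map_result <- function(pairs, bchain, rchain, excluded, params) {
  pairs <- pairs |>
    dplyr::transmute(
      binder_chain = bchain, binder_resid = .data$binder_resid,
      receptor_chain = rchain, receptor_resid = .data$receptor_resid,
      min_atom_distance = .data$min_atom_distance,
      n_atom_contacts = .data$n_atom_contacts
    ) |>
    dplyr::arrange(.data$binder_resid, .data$receptor_resid)
  attr(pairs, "excluded_low_plddt") <- excluded
  attr(pairs, "params") <- params
  class(pairs) <- c("interface_map", class(tibble::tibble()))
  pairs
}

#' Two-stage interface-residue detection
#'
#' Detects interacting residue pairs between the binder and receptor chains
#' of a predicted complex with the screening procedure: stage 1 keeps
#' residue pairs whose representative (C-beta) coordinates lie within
#' `prefilter_cutoff` (inclusive); stage 2 keeps, of those, pairs with any
#' atom-atom distance at or below `atomic_cutoff` (all atoms present in the
#' file, hydrogens included if any). When a [binding_site()] is supplied the
#' receptor side is restricted to site members before stage 1. When
#' confidence data is supplied, residues with pLDDT below `plddt_min` are
#' removed from the resulting pairs (both chains) and reported in the
#' `excluded_low_plddt` attribute.
#'
#' @param model structure tibble with one receptor and one binder chain.
#' @param conf optional [confidence_data()]; enables the pLDDT exclusion.
#' @param site optional [binding_site()]; restricts the receptor side.
#' @param prefilter_cutoff stage-1 representative-atom cutoff, Angstrom.
#' @param atomic_cutoff stage-2 all-atom cutoff, Angstrom.
#' @param plddt_min residues below this pLDDT are discarded.
#' @param exclude_receptor_plddt also apply the pLDDT exclusion to receptor
#'   residues (default TRUE).
#' @return an `interface_map`: tibble of pairs (`binder_chain`,
#'   `binder_resid`, `receptor_chain`, `receptor_resid`,
#'   `min_atom_distance`, `n_atom_contacts`) with attributes
#'   `excluded_low_plddt` (tibble of removed residues) and `params`.
#'   Project with [binder_iface()] / [receptor_iface()].
#' @seealso [interface_residues_exhaustive()] for the prefilter-free oracle.
#' @export
interface_residues <- function(model, conf = NULL, site = NULL,
                               prefilter_cutoff = 8.0, atomic_cutoff = 4.0,
                               plddt_min = 50,
                               exclude_receptor_plddt = TRUE) {
  pre <- iface_prep(model, site)
  cand <- NULL
  if (nrow(pre$bat) && nrow(pre$rat)) {
    brep <- representative_coordinates(pre$bat)
    rrep <- representative_coordinates(pre$rat)
    d2 <- outer(rowSums(as.matrix(brep[, 3:5])^2),
                rowSums(as.matrix(rrep[, 3:5])^2), `+`) -
      2 * as.matrix(brep[, 3:5]) %*% t(as.matrix(rrep[, 3:5]))
    hit <- which(d2 <= prefilter_cutoff^2 + 1e-12, arr.ind = TRUE)
    cand <- tibble::tibble(binder_resid = brep$resid[hit[, 1]],
                           receptor_resid = rrep$resid[hit[, 2]])
  } else {
    cand <- tibble::tibble(binder_resid = integer(),
                           receptor_resid = integer())
  }
  finish_interface(pre, cand, conf, atomic_cutoff, plddt_min,
                   exclude_receptor_plddt,
                   params = list(prefilter_cutoff = prefilter_cutoff,
                                 atomic_cutoff = atomic_cutoff,
                                 plddt_min = plddt_min,
                                 site_restricted = !is.null(site)))
}

#' Exhaustive single-stage interface detection (oracle)
#'
#' Identical contract to [interface_residues()] but without the C-beta
#' prefilter: every cross-chain residue pair is tested at the all-atom
#' cutoff. Serves as the ground-truth reference; the two-stage result is
#' always a subset, with equality whenever no atom lies far from its
#' residue's representative coordinate.
#'
#' @inheritParams interface_residues
#' @return an `interface_map` (see [interface_residues()]).
#' @export
interface_residues_exhaustive <- function(model, conf = NULL, site = NULL,
                                          atomic_cutoff = 4.0,
                                          plddt_min = 50,
                                          exclude_receptor_plddt = TRUE) {
  pre <- iface_prep(model, site)
  finish_interface(pre, NULL, conf, atomic_cutoff, plddt_min,
                   exclude_receptor_plddt,
                   params = list(prefilter_cutoff = Inf,
                                 atomic_cutoff = atomic_cutoff,
                                 plddt_min = plddt_min,
                                 site_restricted = !is.null(site)))
}

iface_prep <- function(model, site) {
  bchain <- chain_of_role(model, "binder")
  rchain <- chain_of_role(model, "receptor")
  keep <- !model$het   # waters/heteroatoms never enter either stage
  bat <- model[keep & model$chain == bchain, ]
  rat <- model[keep & model$chain == rchain, ]
  if (!is.null(site)) {
    if (length(site$site) == 0L) stop("empty binding site", call. = FALSE)
    rat <- rat[rat$resid %in% site$site, ]
  }
  list(bat = bat, rat = rat, bchain = bchain, rchain = rchain)
}

finish_interface <- function(pre, candidates, conf, atomic_cutoff,
                             plddt_min, exclude_receptor_plddt, params) {
  empty <- tibble::tibble(binder_resid = integer(),
                          receptor_resid = integer(),
                          min_atom_distance = numeric(),
                          n_atom_contacts = integer())
  pairs <- if (nrow(pre$bat) && nrow(pre$rat) &&
               (is.null(candidates) || nrow(candidates))) {
    residue_pair_distances(pre$bat, pre$rat, candidates,
                           cutoff = atomic_cutoff) |>
      dplyr::filter(.data$min_atom_distance <= atomic_cutoff + 1e-12)
  } else {
    empty
  }
  excluded <- tibble::tibble(chain = character(), resid = integer(),
                             plddt = numeric())
  if (!is.null(conf) && nrow(pairs)) {
    bp <- plddt_of(conf, pre$bchain, pairs$binder_resid)
    rp <- plddt_of(conf, pre$rchain, pairs$receptor_resid)
    low_b <- bp < plddt_min
    low_r <- if (exclude_receptor_plddt) rp < plddt_min else FALSE
    drop <- low_b | low_r
    if (any(drop)) {
      excluded <- dplyr::bind_rows(
        tibble::tibble(chain = pre$bchain,
                       resid = pairs$binder_resid[low_b],
                       plddt = bp[low_b]),
        tibble::tibble(chain = pre$rchain,
                       resid = pairs$receptor_resid[which(low_r)],
                       plddt = rp[which(low_r)])
      ) |> dplyr::distinct()
      pairs <- pairs[!drop, ]
    }
  }
  interface_map_result(pairs, pre$bchain, pre$rchain, excluded, params)
}

#' Binder-side / receptor-side projections of an interface map
#' @param iface an `interface_map` from [interface_residues()].
#' @return sorted integer vector of residue ids.
#' @export
binder_iface <- function(iface) sort(unique(iface$binder_resid))

#' @rdname binder_iface
#' @export
receptor_iface <- function(iface) sort(unique(iface$receptor_resid))

#' Write an interface map as a tab-separated pair list
#' @param iface an `interface_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interface_pairs <- function(iface, path) {
  readr::write_tsv(tibble::as_tibble(iface), path)
  invisible(path)
}
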