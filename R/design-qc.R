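#' Optimal rigid-body superposition RMSD between two models
#'
#' Atoms are matched by (mapped chain, author residue id, atom name) after
#' restricting to the requested atom subset, then superposed by the optimal
#' least-squares proper rotation + translation (no reflection) and the RMSD
#' of the matched atoms is reported.
#'
#' @param reference,mobile structure tibbles.
#' @param selection `"CA"` (default; refolded side chains are not
#'   comparable), `"backbone"` (N, CA, C, O) or `"all"`.
#' @param chain_map named character vector mapping mobile chain ids to
#'   reference chain ids (`NULL`: identity).
#' @param chains restrict the match to these (reference) chain ids.
#' @return one-row tibble of class `design_qc`: `rmsd` (Angstrom),
#'   `n_atoms_matched`, `selection`, `collinear` (degenerate reference
#'   flagged, still computed).
#' @export
superpose_rmsd <- function(reference, mobile, selection = c("CA", "backbone",
                                                            "all"),
                           chain_map = NULL, chains = NULL) {
  selection <- match.arg(selection)
  m <- matched_coords(reference, mobile, selection, chain_map, chains)
  if (nrow(m$ref) < 3) {
    stop("need at least 3 matched atoms for superposition (got ",
         nrow(m$ref), ")", call. = FALSE)
  }
  fit <- kabsch(m$ref, m$mob)
  moved <- apply_rigid(m$mob, fit$rotation, fit$translation)
  rmsd <- sqrt(mean(rowSums((moved - m$ref)^2)))
  sv <- svd(sweep(m$ref, 2, colMeans(m$ref)))$d
  collinear <- sv[2] < 1e-6 * max(sv[1], 1)
  out <- tibble::tibble(rmsd = rmsd, n_atoms_matched = nrow(m$ref),
                        selection = selection, collinear = collinear)
  class(out) <- c("design_qc", class(tibble::tibble()))
  out
}

matched_coords <- function(reference, mobile, selection, chain_map,
                           chains = NULL) {
  pick <- function(df) {
    df <- df[!df$het, ]
    switch(selection,
           CA = df[df$atom == "CA", ],
           backbone = df[df$atom %in% c("N", "CA", "C", "O"), ],
           all = df)
  }
  ref <- pick(reference)
  mob <- pick(mobile)
  if (!is.null(chain_map)) {
    mapped <- unname(chain_map[mob$chain])
    mob$chain <- ifelse(is.na(mapped), mob$chain, mapped)
  }
  if (!is.null(chains)) {
    ref <- ref[ref$chain %in% chains, ]
    mob <- mob[mob$chain %in% chains, ]
  }
  key <- c("chain", "resid", "atom")
  j <- dplyr::inner_join(
    ref |> dplyr::select(dplyr::all_of(key), rx = "x", ry = "y", rz = "z"),
    mob |> dplyr::select(dplyr::all_of(key), mx = "x", my = "y", mz = "z"),
    by = key)
  list(ref = as.matrix(j[, c("rx", "ry", "rz")]),
       mob = as.matrix(j[, c("mx", "my", "mz")]),
       key = j[key])
}

#' Quality-control metrics for a refolded designed binder
#'
#' Computes the design filter inputs: the mean pLDDT of the refolded
#' binder's residues and the pose-sensitive RMSD between template and
#' refolded binder. The two models are superposed on their receptor-chain
#' CA atoms, and the RMSD is then measured over the binder-chain CA atoms
#' without re-fitting, so it reflects both the binder fold and its pose on
#' the receptor. `mode = "fold"` instead superposes on the binder itself
#' (fold-only RMSD). A design passes iff its mean binder pLDDT strictly
#' exceeds `plddt_min`.
#'
#' @param refolded structure tibble of the refolded design (with receptor).
#' @param conf [confidence_data()] for the refolded model.
#' @param template structure tibble of the design template.
#' @param binder_chain binder chain id (default: role lookup).
#' @param plddt_min pass threshold on mean binder pLDDT (strict `>`).
#' @param mode `"pose"` (default) or `"fold"`.
#' @return one-row tibble of class `design_qc`: `rmsd`, `n_atoms_matched`,
#'   `binder_mean_plddt`, `passed`, `selection`, `mode`.
#' @export
design_metrics <- function(refolded, conf, template, binder_chain = NULL,
                           plddt_min = 90, mode = c("pose", "fold")) {
  mode <- match.arg(mode)
  if (is.null(conf)) stop("confidence data required", call. = FALSE)
  if (is.null(binder_chain)) binder_chain <- chain_of_role(refolded, "binder")
  receptor_chain <- chain_of_role(refolded, "receptor")
  bres <- residue_table(refolded) |>
    dplyr::filter(.data$chain == binder_chain)
  plddt <- mean(plddt_of(conf, binder_chain, bres$resid))
  if (mode == "fold") {
    qc <- superpose_rmsd(template, refolded, selection = "CA",
                         chains = binder_chain)
    rmsd <- qc$rmsd
    n <- qc$n_atoms_matched
  } else {
    # fit on receptor CAs, measure on binder CAs without re-fitting
    rec <- matched_coords(template, refolded, "CA", NULL, receptor_chain)
    if (nrow(rec$ref) < 3) {
      stop("need at least 3 matched receptor CA atoms", call. = FALSE)
    }
    fit <- kabsch(rec$ref, rec$mob)
    bnd <- matched_coords(template, refolded, "CA", NULL, binder_chain)
    if (nrow(bnd$ref) == 0L) {
      stop("no matched binder CA atoms", call. = FALSE)
    }
    moved <- apply_rigid(bnd$mob, fit$rotation, fit$translation)
    rmsd <- sqrt(mean(rowSums((moved - bnd$ref)^2)))
    n <- nrow(bnd$ref)
  }
  out <- tibble::tibble(
    rmsd = rmsd, n_atoms_matched = n, binder_mean_plddt = plddt,
    passed = plddt > plddt_min, selection = "CA", mode = mode,
    plddt_min = plddt_min
  )
  class(out) <- c("design_qc", class(tibble::tibble()))
  out
}
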