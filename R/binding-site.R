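#' Define a receptor binding site partitioned into patches
#'
#' The conserved helix-binding surface of the receptor is described as four
#' disjoint residue sets: two hydrophobic patches, one electrostatic patch
#' and an aromatic flank, plus optional extra site residues. Residues are
#' author sequence numbers on the receptor chain.
#'
#' @param patch1,patch2,patch3,flank integer vectors of receptor residue ids;
#'   pairwise disjoint.
#' @param extra additional site residues outside the named patches.
#' @return object of class `binding_site`: list with the four patch sets and
#'   `site`, their union plus `extra`.
#' @export
binding_site <- function(patch1, patch2, patch3, flank = integer(),
                         extra = integer()) {
  sets <- list(patch1 = as.integer(patch1), patch2 = as.integer(patch2),
               patch3 = as.integer(patch3), flank = as.integer(flank))
  all_ids <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("patch sets must be pairwise disjoint", call. = FALSE)
  }
  sets$site <- sort(unique(c(all_ids, as.integer(extra))))
  structure(sets, class = "binding_site")
}

#' @export
print.binding_site <- function(x, ...) {
  cat("<binding_site>\n")
  for (p in c("patch1", "patch2", "patch3", "flank")) {
    cat(sprintf("  %-6s: %s\n", p, paste(x[[p]], collapse = ", ")))
  }
  cat("  site  :", length(x$site), "residues\n")
  invisible(x)
}

#' Default B55-alpha binding-site definition
#'
#' The conserved substrate-binding surface of the B55-alpha regulatory
#' subunit of PP2A: patch 1 (hydrophobic pocket) Y178, D197, M222, L225,
#' V228; patch 2 I284, S287; patch 3 (electrostatic) centred on D340; and
#' the aromatic flank Y337, F343. Fully overridable via [binding_site()].
#'
#' @param extra additional site residues to include beyond the patches.
#' @return a [binding_site()] object in B55-alpha author numbering.
#' @export
b55_site <- function(extra = integer()) {
  binding_site(patch1 = c(178, 197, 222, 225, 228),
               patch2 = c(284, 287),
               patch3 = 340,
               flank = c(337, 343),
               extra = extra)
}

#' Which patch does a receptor residue belong to?
#' @param site [binding_site()] object.
#' @param resid receptor residue id(s).
#' @return character vector: `"patch1"`, `"patch2"`, `"patch3"`, `"flank"`,
#'   or `NA` for site residues outside all patches.
#' @export
patch_of <- function(site, resid) {
  out <- rep(NA_character_, length(resid))
  for (p in c("patch1", "patch2", "patch3", "flank")) {
    out[resid %in% site[[p]]] <- p
  }
  out
}
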