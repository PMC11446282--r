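#' Construct per-residue confidence data
#'
#' Bundles a per-residue pLDDT vector, an optional N x N predicted aligned
#' error (PAE) matrix and the residue index map that ties matrix rows/columns
#' to `(chain, resid)` pairs of a structure.
#'
#' @param plddt numeric vector in `[0, 100]`, one value per residue, in index
#'   map order.
#' @param pae square numeric matrix (Angstrom, all entries >= 0) or `NULL`
#'   when only pLDDT is available.
#' @param index_map tibble with columns `chain`, `resid`, `index`
#'   (1-based row/column of each residue in `pae` and position in `plddt`).
#' @return object of class `confidence_data`: a list with elements `plddt`,
#'   `pae`, `index_map`.
#' @export
confidence_data <- function(plddt, pae, index_map) {
  index_map <- tibble::as_tibble(index_map)
  stopifnot(all(c("chain", "resid", "index") %in% names(index_map)))
  n <- nrow(index_map)
  if (!setequal(index_map$index, seq_len(n))) {
    stop("index_map must be a bijection onto 1..N", call. = FALSE)
  }
  if (length(plddt) != n) {
    stop("plddt length (", length(plddt), ") != number of residues (", n,
         ")", call. = FALSE)
  }
  if (any(plddt < 0 | plddt > 100)) {
    stop("pLDDT values must lie in [0, 100]", call. = FALSE)
  }
  if (!is.null(pae)) {
    pae <- as.matrix(pae)
    if (nrow(pae) != ncol(pae)) {
      stop("PAE matrix must be square (got ", nrow(pae), " x ", ncol(pae),
           ")", call. = FALSE)
    }
    if (nrow(pae) != n) {
      stop("PAE side (", nrow(pae), ") != number of residues (", n, ")",
           call. = FALSE)
    }
    if (any(pae < 0)) stop("PAE entries must be >= 0", call. = FALSE)
  }
  structure(list(plddt = as.numeric(plddt), pae = pae,
                 index_map = index_map),
            class = "confidence_data")
}

#' @export
print.confidence_data <- function(x, ...) {
  cat("<confidence_data> ", nrow(x$index_map), " residues; PAE ",
      if (is.null(x$pae)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Read model confidence (pLDDT / PAE)
#'
#' Two dialects are supported. `scores_json` reads the JSON emitted by
#' common structure-prediction servers: a per-residue `plddt` array plus a
#' square PAE matrix under either the key `predicted_aligned_error` or the
#' legacy nested `pae` key. `bfactor_plddt` takes pLDDT from the structure's
#' B-factor column (value of the first atom of each residue); the PAE matrix
#' is then absent and PAE-dependent operations error.
#'
#' The index map follows the structure's own chain order (receptor residues
#' first when the file lists the receptor chain first), so confidence rows
#' align with file residue order.
#'
#' @param source path to a scores JSON file (may be gzipped), or the
#'   structure tibble itself for the `bfactor_plddt` dialect.
#' @param model structure tibble the confidence belongs to (required for
#'   `scores_json`; ignored for `bfactor_plddt` when `source` is a model).
#' @param dialect `"scores_json"` or `"bfactor_plddt"`.
#' @return [confidence_data()] object.
#' @export
read_confidence <- function(source, model = NULL,
                            dialect = c("scores_json", "bfactor_plddt")) {
  dialect <- match.arg(dialect)
  if (dialect == "bfactor_plddt") {
    if (is.character(source)) source <- read_structure(source)
    res <- source |>
      dplyr::group_by(.data$chain, .data$resid) |>
      dplyr::summarise(plddt = dplyr::first(.data$b), .groups = "drop")
    # keep file residue order
    ord <- residue_table(source)
    res <- dplyr::left_join(ord[, c("chain", "resid")], res,
                            by = c("chain", "resid"))
    if (any(res$plddt < 0 | res$plddt > 100)) {
      stop("B-factor column does not look like pLDDT (outside [0, 100])",
           call. = FALSE)
    }
    imap <- tibble::tibble(chain = res$chain, resid = res$resid,
                           index = seq_len(nrow(res)))
    return(confidence_data(res$plddt, NULL, imap))
  }
  if (is.null(model)) {
    stop("scores_json dialect needs the structure to build the index map",
         call. = FALSE)
  }
  js <- jsonlite::fromJSON(source, simplifyVector = TRUE)
  if (is.null(js$plddt)) stop("no 'plddt' array in ", source, call. = FALSE)
  plddt <- as.numeric(js$plddt)
  pae <- js$predicted_aligned_error
  if (is.null(pae)) pae <- js$pae
  if (is.null(pae)) stop("no PAE matrix ('predicted_aligned_error' or ",
                         "'pae') in ", source, call. = FALSE)
  pae <- as.matrix(pae)
  ord <- residue_table(model)
  imap <- tibble::tibble(chain = ord$chain, resid = ord$resid,
                         index = seq_len(nrow(ord)))
  confidence_data(plddt, pae, imap)
}

# Look up confidence indices for (chain, resid) pairs; error on misses.
conf_index <- function(conf, chain, resid) {
  key <- paste(chain, resid)
  map <- stats::setNames(conf$index_map$index,
                         paste(conf$index_map$chain, conf$index_map$resid))
  idx <- unname(map[key])
  if (anyNA(idx)) {
    stop("residues absent from confidence index map: ",
         paste(unique(key[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

plddt_of <- function(conf, chain, resid) {
  conf$plddt[conf_index(conf, chain, resid)]
}

#' Write a confidence object as scores JSON
#'
#' Emits the `plddt` + `predicted_aligned_error` dialect understood by
#' [read_confidence()].
#'
#' @param conf [confidence_data()] object (PAE required).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confidence <- function(conf, path) {
  if (is.null(conf$pae)) stop("cannot write scores JSON without PAE",
                              call. = FALSE)
  jsonlite::write_json(
    list(plddt = conf$plddt,
         predicted_aligned_error = conf$pae),
    path, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}
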