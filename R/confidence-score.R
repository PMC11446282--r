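#' Score a model's interface confidence (ipLDDT, iPAE)
#'
#' Computes the two screening metrics over an interface map: the arithmetic
#' mean pLDDT of the binder's interface residues (ipLDDT) and the median PAE
#' over the binder-rows x receptor-columns submatrix of the PAE matrix
#' (iPAE). Both metrics require strictly more than `min_iface` binder-side
#' interface residues (after any low-pLDDT exclusion); otherwise a sentinel
#' report is returned with ipLDDT 0 and iPAE 30, which can never pass the
#' screen.
#'
#' @param iface an `interface_map` from [interface_residues()].
#' @param conf [confidence_data()] with a PAE matrix.
#' @param min_iface minimum binder interface size; the metrics are computed
#'   only when `n_binder_iface > min_iface` (strict).
#' @param symmetrize also include the receptor-rows x binder-columns block
#'   in the iPAE median (off by default; the screen uses the single
#'   binder-rows orientation).
#' @return one-row tibble of class `confidence_report`: `n_binder_iface`,
#'   `iplddt`, `ipae_median`, `sentinel`, `passed` (NA until
#'   [apply_screen()]), plus the `min_iface` used.
#' @export
score_model <- function(iface, conf, min_iface = 7, symmetrize = FALSE) {
  if (is.null(conf$pae)) {
    stop("PAE matrix absent: interface scoring needs a scores_json ",
         "confidence source", call. = FALSE)
  }
  b <- binder_iface(iface)
  r <- receptor_iface(iface)
  n <- length(b)
  if (n > min_iface) {
    bchain <- iface$binder_chain[1]
    rchain <- iface$receptor_chain[1]
    bi <- conf_index(conf, bchain, b)
    ri <- conf_index(conf, rchain, r)
    vals <- as.vector(conf$pae[bi, ri, drop = FALSE])
    if (symmetrize) {
      vals <- c(vals, as.vector(conf$pae[ri, bi, drop = FALSE]))
    }
    iplddt <- mean(conf$plddt[bi])
    ipae <- stats::median(vals)
    sentinel <- FALSE
  } else {
    iplddt <- 0
    ipae <- 30
    sentinel <- TRUE
  }
  rep_ <- tibble::tibble(
    n_binder_iface = n, iplddt = iplddt, ipae_median = ipae,
    sentinel = sentinel, passed = NA, min_iface = min_iface
  )
  class(rep_) <- c("confidence_report", class(tibble::tibble()))
  rep_
}

#' Apply the published screen thresholds to a confidence report
#'
#' A model passes iff `ipae_median < ipae_max` and `iplddt > iplddt_min`,
#' both strict, and the report is not a sentinel.
#'
#' @param report one or more rows of [score_model()] output (any data frame
#'   with `iplddt`, `ipae_median`, `sentinel` columns).
#' @param ipae_max iPAE upper threshold (strict `<`), Angstrom.
#' @param iplddt_min ipLDDT lower threshold (strict `>`).
#' @return the report with `passed` set and thresholds recorded.
#' @export
apply_screen <- function(report, ipae_max = 10, iplddt_min = 70) {
  report |>
    dplyr::mutate(
      passed = .data$ipae_median < ipae_max & .data$iplddt > iplddt_min &
        !.data$sentinel,
      ipae_max = ipae_max, iplddt_min = iplddt_min
    )
}

#' Count passing models in a per-model metrics table
#'
#' Applies the screen to an already-computed metrics table (for example a
#' published supplementary table of per-model ipLDDT/iPAE values) and counts
#' the models that pass.
#'
#' @param metrics data frame with columns `iplddt` and `ipae_median` (a
#'   `sentinel` column is honoured if present; otherwise sentinel rows are
#'   recognised by the (0, 30) value pair).
#' @inheritParams apply_screen
#' @return integer count of passing models.
#' @export
screen_count <- function(metrics, ipae_max = 10, iplddt_min = 70) {
  metrics <- tibble::as_tibble(metrics)
  if (!"sentinel" %in% names(metrics)) {
    metrics$sentinel <- metrics$iplddt == 0 & metrics$ipae_median == 30
  }
  sum(apply_screen(metrics, ipae_max, iplddt_min)$passed)
}
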