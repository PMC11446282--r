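#' Screening run configuration
#'
#' Collects every numeric threshold of the pipeline with its default:
#' the 8 A representative-atom prefilter, 4 A all-atom contact cutoff,
#' pLDDT 50 residue exclusion, > 7 interface-residue requirement, the
#' iPAE < 10 / ipLDDT > 70 screen, and the mean binder pLDDT > 90 design
#' filter, plus the binding-site definition, chain roles and seed.
#'
#' @param prefilter_cutoff,atomic_cutoff interface detection cutoffs, A.
#' @param plddt_min low-confidence residue exclusion threshold.
#' @param min_iface metrics need strictly more binder interface residues.
#' @param ipae_max,iplddt_min screen thresholds (strict inequalities).
#' @param design_plddt_min design QC pass threshold on mean binder pLDDT.
#' @param site [binding_site()] definition (default [b55_site()]).
#' @param receptor_chain receptor chain id (`NULL`: first chain in file).
#' @param seed integer seed for any stochastic step.
#' @return a `screen_config` list.
#' @export
screen_config <- function(prefilter_cutoff = 8.0, atomic_cutoff = 4.0,
                          plddt_min = 50, min_iface = 7, ipae_max = 10,
                          iplddt_min = 70, design_plddt_min = 90,
                          site = b55_site(), receptor_chain = NULL,
                          seed = 1L) {
  thresholds <- c(prefilter_cutoff, atomic_cutoff, plddt_min, min_iface,
                  ipae_max, iplddt_min, design_plddt_min)
  if (any(thresholds <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  structure(list(prefilter_cutoff = prefilter_cutoff,
                 atomic_cutoff = atomic_cutoff, plddt_min = plddt_min,
                 min_iface = min_iface, ipae_max = ipae_max,
                 iplddt_min = iplddt_min,
                 design_plddt_min = design_plddt_min, site = site,
                 receptor_chain = receptor_chain, seed = as.integer(seed)),
            class = "screen_config")
}

#' Read a screening configuration from YAML
#'
#' Any omitted field keeps its [screen_config()] default; patch sets are
#' given as `site: {patch1: [...], patch2: [...], patch3: [...],
#' flank: [...]}`.
#'
#' @param path YAML file path.
#' @return a `screen_config`.
#' @export
read_screen_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files",
         call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  site <- if (!is.null(y$site)) {
    binding_site(patch1 = y$site$patch1 %||% integer(),
                 patch2 = y$site$patch2 %||% integer(),
                 patch3 = y$site$patch3 %||% integer(),
                 flank = y$site$flank %||% integer(),
                 extra = y$site$extra %||% integer())
  } else {
    b55_site()
  }
  defaults <- screen_config()
  num <- function(name) y[[name]] %||% defaults[[name]]
  screen_config(prefilter_cutoff = num("prefilter_cutoff"),
                atomic_cutoff = num("atomic_cutoff"),
                plddt_min = num("plddt_min"), min_iface = num("min_iface"),
                ipae_max = num("ipae_max"),
                iplddt_min = num("iplddt_min"),
                design_plddt_min = num("design_plddt_min"), site = site,
                receptor_chain = y$receptor_chain %||% NULL,
                seed = num("seed"))
}

#' Screen a batch of predicted complex models
#'
#' Runs the full pipeline (read structure + confidence, interface
#' detection restricted to the binding site, pLDDT exclusion, ipLDDT/iPAE
#' scoring with sentinels, screen thresholds) over a manifest and returns
#' one row per model. Unreadable rows are marked errored and the run
#' continues; the result is fully determined by the manifest and config.
#'
#' @param manifest data frame or CSV path with columns `model_path`,
#'   `confidence_path` and optionally `receptor_chain`.
#' @param config a [screen_config()].
#' @param quiet suppress per-model log messages.
#' @return tibble: one row per manifest entry with `model`, the
#'   [score_model()] fields, `passed` and `error` (NA when the row ran).
#' @export
run_screen <- function(manifest, config = screen_config(), quiet = FALSE) {
  if (is.character(manifest)) {
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  manifest <- tibble::as_tibble(manifest)
  if (nrow(manifest) == 0L) {
    warning("empty manifest: nothing to screen", call. = FALSE)
    return(tibble::tibble(model = character(), n_binder_iface = integer(),
                          iplddt = numeric(), ipae_median = numeric(),
                          sentinel = logical(), passed = logical(),
                          error = character()))
  }
  rows <- purrr::pmap(manifest, function(model_path, confidence_path,
                                         receptor_chain = NULL, ...) {
    res <- tryCatch({
      rc <- receptor_chain %||% config$receptor_chain
      model <- read_structure(model_path, receptor_chain = rc)
      conf <- read_confidence(confidence_path, model = model)
      iface <- interface_residues(
        model, conf = conf, site = config$site,
        prefilter_cutoff = config$prefilter_cutoff,
        atomic_cutoff = config$atomic_cutoff,
        plddt_min = config$plddt_min)
      rep_ <- score_model(iface, conf, min_iface = config$min_iface) |>
        apply_screen(ipae_max = config$ipae_max,
                     iplddt_min = config$iplddt_min)
      dplyr::mutate(rep_[, c("n_binder_iface", "iplddt", "ipae_median",
                             "sentinel", "passed")],
                    error = NA_character_)
    }, error = function(e) {
      tibble::tibble(n_binder_iface = NA_integer_, iplddt = NA_real_,
                     ipae_median = NA_real_, sentinel = NA,
                     passed = NA, error = conditionMessage(e))
    })
    out <- dplyr::bind_cols(tibble::tibble(model = model_path), res)
    if (!quiet) {
      message(sprintf(
        "[screen] %s: %s", basename(model_path),
        if (!is.na(out$error)) paste("ERROR -", out$error)
        else sprintf("n_iface=%d iplddt=%.1f ipae=%.2f passed=%s",
                     out$n_binder_iface, out$iplddt, out$ipae_median,
                     out$passed)))
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  if (all(!is.na(res$error))) {
    warning("all manifest rows errored", call. = FALSE)
  }
  res
}

#' Materialise a standard synthetic fixture directory
#'
#' Writes three structure + confidence fixture pairs (one passing the
#' screen, one too small an interface hence a sentinel, one failing the
#' thresholds) plus a `manifest.csv` pointing at them, for end-to-end
#' tests of [run_screen()].
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for fixture geometry jitter.
#' @return path to the manifest CSV, invisibly.
#' @export
make_fixture_suite <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  register <- c("0" = "patch1", "1" = "patch2", "2" = "patch3",
                "4" = "patch1", "5" = "patch2")
  # 8 contacted binder residues > the 7-residue bar
  supplementary <- c("3" = "patch1", "6" = "patch1", "7" = "flank")
  cases <- list(
    pass = list(contacts = register, extra = supplementary,
                plddt = 90, interface = 5),
    sentinel = list(contacts = c("0" = "patch1", "4" = "patch1"),
                    extra = character(), plddt = 90, interface = 5),
    fail = list(contacts = register, extra = supplementary,
                plddt = 60, interface = 15)
  )
  manifest <- purrr::imap(cases, function(case, name) {
    spec <- helix_complex_spec(
      binder_length = 16, anchor_resid = 56, binder_start = 52,
      contacts = case$contacts, extra_contacts = case$extra,
      seed = seed + match(name, names(cases)))
    fx <- make_helix_complex(spec)
    pdb <- file.path(dir, paste0(name, ".pdb"))
    js <- file.path(dir, paste0(name, "_scores.json"))
    write_structure(fx$model, pdb)
    conf <- make_confidence(
      fx$model, binder_iface = unique(fx$truth$binder_resid),
      receptor_iface = unique(fx$truth$receptor_resid),
      plddt = case$plddt, interface_value = case$interface,
      background_value = max(25, case$interface))
    write_confidence(conf, js)
    tibble::tibble(model_path = pdb, confidence_path = js,
                   receptor_chain = "A")
  }) |> dplyr::bind_rows()
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, path)
  invisible(path)
}
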