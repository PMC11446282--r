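# Seeded generators for idealized helix-receptor complexes, block-valued
# confidence data and noisy saturation curves. All generators are pure
# functions of their arguments and seed.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Ideal alpha-helix backbone geometry (bond lengths A, angles deg).
.helix_geo <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  a_c_ca_cb = 110.1, d_n_c_ca_cb = 122.686,
  phi = -57, psi = -47, omega = 180
)

#' Build an ideal poly-alanine alpha-helix
#'
#' Backbone built residue-by-residue in the natural extension reference
#' frame with ideal bond lengths/angles and helical torsions (phi -57,
#' psi -47, omega 180 degrees); C-beta placed at the standard tetrahedral
#' position, carbonyl O in the peptide plane.
#'
#' @param n number of residues.
#' @param chain chain id.
#' @param start_resid author id of the first residue.
#' @param resnames 3-letter residue names (recycled; default `"ALA"`).
#' @return structure tibble (single chain, role unassigned until combined).
#' @export
ideal_helix <- function(n, chain = "B", start_resid = 1L,
                        resnames = "ALA") {
  g <- .helix_geo
  stopifnot(n >= 1)
  resnames <- rep_len(resnames, n)
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N; CB <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, g$psi)
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, g$omega)
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, g$phi)
    }
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, g$psi + 180)
    CB[i, ] <- nerf_place(N[i, ], C[i, ], CA[i, ],
                          g$b_ca_cb, g$a_c_ca_cb, g$d_n_c_ca_cb)
  }
  resid <- start_resid + seq_len(n) - 1L
  per_res <- function(xyz, name) {
    tibble::tibble(chain = chain, resid = resid, resname = resnames,
                   atom = name, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  atoms <- dplyr::bind_rows(
    per_res(N, "N"), per_res(CA, "CA"), per_res(C, "C"),
    per_res(O, "O"),
    per_res(CB, "CB")[resnames != "GLY", ]
  ) |>
    dplyr::arrange(.data$resid,
                   match(.data$atom, c("N", "CA", "C", "O", "CB")))
  atoms$element <- substr(atoms$atom, 1, 1)
  atoms$b <- 0
  atoms$het <- FALSE
  atoms
}

# Principal axis of a point cloud: list(point = centroid, dir = unit axis).
principal_axis <- function(xyz) {
  mu <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, mu))
  d <- s$v[, 1]
  # orient along increasing index order
  if (sum((xyz[nrow(xyz), ] - xyz[1, ]) * d) < 0) d <- -d
  list(point = mu, dir = unit(d))
}

# canonical residue names for the default receptor site
.b55_resnames <- c(`178` = "TYR", `197` = "ASP", `222` = "MET",
                   `225` = "LEU", `228` = "VAL", `284` = "ILE",
                   `287` = "SER", `340` = "ASP", `337` = "TYR",
                   `343` = "PHE")

#' Specify a synthetic helix-receptor fixture
#'
#' Describes the complex [make_helix_complex()] builds: an ideal binder
#' helix with prescribed register contacts to single-residue receptor
#' probes at an exact closest-approach distance, plus optional
#' non-contacting site probes placed far away.
#'
#' @param binder_length binder helix length, residues (>= 6).
#' @param anchor_resid author id of register position i on the binder.
#' @param binder_start author id of the binder's first residue.
#' @param contacts named character vector mapping register offsets (names,
#'   subset of `0,1,2,4,5`) to patch labels (`"patch1"`, `"patch2"`,
#'   `"patch3"`, `"flank"`), e.g. `c("0" = "patch1", "4" = "patch1")`.
#' @param extra_contacts like `contacts` but at arbitrary integer offsets
#'   outside the register set - supplementary contacts such as those the
#'   preceding helix of helix-loop-helix binders makes. Used to build
#'   fixtures whose interfaces exceed the > 7 residue screening bar.
#' @param approach prescribed minimum atom-atom distance for each contact,
#'   Angstrom (must be <= 4 to register at the default cutoff).
#' @param n_far_probes extra receptor site residues placed > 20 A away.
#' @param site [binding_site()] the probe residue ids are drawn from.
#' @param receptor_chain,binder_chain chain ids.
#' @param seed integer seed for the rigid-body placement jitter.
#' @return a `fixture_spec` list.
#' @export
helix_complex_spec <- function(binder_length = 14, anchor_resid = 56,
                               binder_start = anchor_resid - 4L,
                               contacts = c("0" = "patch1", "2" = "patch3",
                                            "4" = "patch1", "5" = "patch2"),
                               extra_contacts = character(),
                               approach = 3.5, n_far_probes = 0,
                               site = b55_site(),
                               receptor_chain = "A", binder_chain = "B",
                               seed = 1L) {
  offs <- as.integer(names(contacts))
  xoffs <- as.integer(names(extra_contacts))
  if (length(offs) == 0L && length(xoffs) == 0L && n_far_probes == 0L) {
    stop("fixture needs at least one probe", call. = FALSE)
  }
  if (length(offs) && (!all(offs %in% c(0L, 1L, 2L, 4L, 5L)) ||
                       anyDuplicated(offs))) {
    stop("contact offsets must be distinct members of {0,1,2,4,5}",
         call. = FALSE)
  }
  if (length(xoffs) && anyDuplicated(c(offs, xoffs))) {
    stop("extra_contacts offsets must not repeat register offsets",
         call. = FALSE)
  }
  if (!all(c(contacts, extra_contacts) %in%
           c("patch1", "patch2", "patch3", "flank"))) {
    stop("unknown patch label in contacts", call. = FALSE)
  }
  if (binder_length < 6) stop("binder_length must be >= 6", call. = FALSE)
  anchor_pos <- anchor_resid - binder_start + 1L
  all_offs <- c(offs, xoffs)
  if (anchor_pos < 1L ||
      (length(all_offs) &&
       (anchor_pos + max(all_offs) > binder_length ||
        anchor_pos + min(all_offs) < 1L))) {
    stop("anchor and offsets must fit inside the binder helix",
         call. = FALSE)
  }
  structure(list(binder_length = as.integer(binder_length),
                 anchor_resid = as.integer(anchor_resid),
                 binder_start = as.integer(binder_start),
                 contacts = contacts, extra_contacts = extra_contacts,
                 approach = approach,
                 n_far_probes = as.integer(n_far_probes), site = site,
                 receptor_chain = receptor_chain,
                 binder_chain = binder_chain, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Build a helix-receptor complex with prescribed contacts
#'
#' The binder is an ideal alpha-helix; each prescribed (offset, patch)
#' contact gets a single-residue receptor probe whose C-beta is placed
#' exactly `approach` Angstrom outward (radially from the helix axis) of
#' the contacted binder residue's C-beta, with the rest of the probe built
#' further out, so the minimum cross-chain atom distance of that residue
#' pair equals `approach` exactly. All other cross-chain residue pairs are
#' kept > 6 A apart (verified; violations raise an infeasibility error).
#' Non-contacting site probes are placed beyond 20 A. The whole complex is
#' then jittered by a seeded rigid-body transform, which leaves every
#' distance intact.
#'
#' @param spec a [helix_complex_spec()].
#' @return list with `model` (structure tibble, receptor chain first),
#'   `truth` (ground-truth `interface_map`-shaped tibble of the prescribed
#'   pairs), and `spec`.
#' @export
make_helix_complex <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  binder <- ideal_helix(spec$binder_length, chain = spec$binder_chain,
                        start_resid = spec$binder_start)
  ca <- as.matrix(binder[binder$atom == "CA", c("x", "y", "z")])
  axis <- principal_axis(ca)
  all_contacts <- c(spec$contacts, spec$extra_contacts)
  offs <- as.integer(names(all_contacts))
  # assign receptor residue ids per patch, in offset order, without reuse
  used <- integer()
  rec_ids <- integer(length(offs))
  for (k in seq_along(offs)) {
    pool <- setdiff(spec$site[[all_contacts[k]]], used)
    if (length(pool) == 0L) {
      stop("patch ", all_contacts[k], " has no unused residues left",
           call. = FALSE)
    }
    rec_ids[k] <- pool[1]
    used <- c(used, pool[1])
  }
  probe_at <- function(resid, target_cb, u, t) {
    # u: outward unit vector, t: unit tangent (for branch directions)
    cb <- target_cb
    ca_ <- cb + 1.52 * u
    w1 <- unit(u + 0.55 * t)
    w2 <- unit(u - 0.55 * t)
    n_ <- ca_ + 1.46 * w1
    c_ <- ca_ + 1.52 * w2
    o_ <- c_ + 1.23 * u
    name <- .b55_resnames[as.character(resid)]
    if (is.na(name)) name <- "ALA"
    tibble::tibble(
      chain = spec$receptor_chain, resid = as.integer(resid),
      resname = name,
      atom = c("N", "CA", "C", "O", "CB"),
      x = c(n_[1], ca_[1], c_[1], o_[1], cb[1]),
      y = c(n_[2], ca_[2], c_[2], o_[2], cb[2]),
      z = c(n_[3], ca_[3], c_[3], o_[3], cb[3]),
      element = c("N", "C", "C", "O", "C"), b = 0, het = FALSE)
  }
  probes <- list()
  truth <- tibble::tibble(binder_resid = integer(),
                          receptor_resid = integer())
  for (k in seq_along(offs)) {
    bres <- spec$anchor_resid + offs[k]
    cbrow <- binder[binder$resid == bres & binder$atom == "CB", ]
    cb_b <- c(cbrow$x, cbrow$y, cbrow$z)
    proj <- axis$point +
      sum((cb_b - axis$point) * axis$dir) * axis$dir
    u <- unit(cb_b - proj)
    t <- unit(cross3(axis$dir, u))
    probes[[k]] <- probe_at(rec_ids[k], cb_b + spec$approach * u, u, t)
    truth <- dplyr::bind_rows(truth,
                              tibble::tibble(binder_resid = bres,
                                             receptor_resid = rec_ids[k]))
  }
  # far, non-contacting site probes along the axis beyond the helix
  far_pool <- setdiff(spec$site$site, used)
  n_far <- min(spec$n_far_probes, length(far_pool))
  if (n_far > 0) {
    end_pt <- axis$point +
      (max((sweep(ca, 2, axis$point) %*% axis$dir)) + 25) * axis$dir
    t0 <- unit(cross3(axis$dir, if (abs(axis$dir[1]) < 0.9) c(1, 0, 0)
                      else c(0, 1, 0)))
    for (j in seq_len(n_far)) {
      p <- end_pt + (8 * j) * axis$dir
      probes[[length(probes) + 1L]] <-
        probe_at(far_pool[j], p, t0, unit(cross3(axis$dir, t0)))
    }
  }
  receptor <- dplyr::bind_rows(probes) |> dplyr::arrange(.data$resid)
  model <- new_structure(dplyr::bind_rows(receptor, binder),
                         receptor_chain = spec$receptor_chain)
  # seeded rigid-body jitter (distance-preserving)
  model <- with_seed(spec$seed, {
    tr <- random_rigid(max_shift = 15)
    transform_structure(model, tr$rotation, tr$translation)
  })
  verify_fixture(model, truth, spec)
  truth <- truth |>
    dplyr::transmute(binder_chain = spec$binder_chain,
                     binder_resid = .data$binder_resid,
                     receptor_chain = spec$receptor_chain,
                     receptor_resid = .data$receptor_resid,
                     min_atom_distance = spec$approach) |>
    dplyr::arrange(.data$binder_resid, .data$receptor_resid)
  list(model = model, truth = truth, spec = spec)
}

verify_fixture <- function(model, truth, spec) {
  bat <- model[model$chain == spec$binder_chain, ]
  rat <- model[model$chain == spec$receptor_chain, ]
  if (nrow(rat) == 0L) return(invisible(TRUE))
  d <- residue_pair_distances(bat, rat, NULL, cutoff = 4)
  key <- paste(d$binder_resid, d$receptor_resid)
  tkey <- paste(truth$binder_resid, truth$receptor_resid)
  on_target <- d[key %in% tkey, ]
  off_target <- d[!key %in% tkey, ]
  if (nrow(truth) &&
      (nrow(on_target) != nrow(truth) ||
       any(abs(on_target$min_atom_distance - spec$approach) > 1e-6))) {
    stop("infeasible geometry: prescribed contact distances not realised",
         call. = FALSE)
  }
  if (nrow(off_target) && any(off_target$min_atom_distance <= 6)) {
    stop("infeasible geometry: unintended cross-chain approach <= 6 A ",
         "(patches demanded beyond reach of distinct helix faces)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Random fixture specification (for property tests)
#'
#' Draws a seeded random [helix_complex_spec()]: binder length 8-20,
#' 1-5 register contacts over random patches, approach 3.0-3.9 A, and
#' enough far probes for 3-8 receptor residues in total. Candidate specs
#' whose contact pattern is geometrically infeasible (probes demanded
#' within the 6 A exclusion margin of a non-contact residue) are redrawn
#' deterministically, so the returned spec always builds.
#'
#' @param seed integer seed.
#' @return a `fixture_spec`.
#' @export
random_complex_spec <- function(seed) {
  with_seed(seed, {
    for (attempt in 1:25) {
      len <- sample(8:20, 1)
      n_contact <- sample(1:5, 1)
      offs <- sort(sample(c(0L, 1L, 2L, 4L, 5L), n_contact))
      # keep contacts inside the helix
      anchor_pos <- sample(seq_len(max(1L, len - max(offs))), 1)
      start <- sample(1:200, 1)
      patches <- sample(c("patch1", "patch1", "patch2", "patch3", "flank"),
                        n_contact, replace = TRUE)
      # a patch can back at most its set size of distinct probes
      cap <- c(patch1 = 5, patch2 = 2, patch3 = 1, flank = 2)
      for (p in names(cap)) {
        idx <- which(patches == p)
        if (length(idx) > cap[[p]]) {
          patches[idx[-seq_len(cap[[p]])]] <- "patch1"
        }
      }
      n_total <- sample(3:8, 1)
      spec <- helix_complex_spec(
        binder_length = len, binder_start = start,
        anchor_resid = start + anchor_pos - 1L,
        contacts = stats::setNames(patches, offs),
        approach = stats::runif(1, 3.0, 3.9),
        n_far_probes = max(0L, n_total - n_contact),
        seed = seed
      )
      ok <- tryCatch({make_helix_complex(spec); TRUE},
                     error = function(e) FALSE)
      if (ok) return(spec)
    }
    stop("no feasible fixture after 25 attempts (seed ", seed, ")",
         call. = FALSE)
  })
}

#' Block-valued PAE matrix with a prescribed interface median
#'
#' Fills an (n_receptor + n_binder)-square matrix with `background_value`
#' and sets the binder-rows x receptor-columns entries of the given
#' interface residues to `interface_value` (plus the transposed block when
#' `symmetrize` is on). Receptor residues occupy the leading indices, as
#' when the receptor chain is listed first in the structure.
#'
#' @param n_binder,n_receptor residue counts.
#' @param binder_iface,receptor_iface 1-based residue positions within each
#'   chain forming the interface block.
#' @param interface_value,background_value PAE values, Angstrom (>= 0);
#'   `interface_value` at or below `background_value`.
#' @param symmetrize also set the transposed block.
#' @return square numeric matrix.
#' @export
make_pae <- function(n_binder, n_receptor, binder_iface = integer(),
                     receptor_iface = integer(), interface_value = 5,
                     background_value = 25, symmetrize = FALSE) {
  if (interface_value < 0 || background_value < 0) {
    stop("PAE values must be >= 0", call. = FALSE)
  }
  if (interface_value > background_value) {
    stop("interface PAE must not exceed the background value",
         call. = FALSE)
  }
  n <- n_binder + n_receptor
  if (length(binder_iface) && (min(binder_iface) < 1 ||
                               max(binder_iface) > n_binder)) {
    stop("binder_iface index out of range", call. = FALSE)
  }
  if (length(receptor_iface) && (min(receptor_iface) < 1 ||
                                 max(receptor_iface) > n_receptor)) {
    stop("receptor_iface index out of range", call. = FALSE)
  }
  pae <- matrix(background_value, n, n)
  rows <- n_receptor + binder_iface
  cols <- receptor_iface
  if (length(rows) && length(cols)) {
    pae[rows, cols] <- interface_value
    if (symmetrize) pae[cols, rows] <- interface_value
  }
  pae
}

#' Confidence data for a synthetic complex
#'
#' Builds a [confidence_data()] whose index map follows the model's residue
#' order, with a uniform (or per-residue overridden) pLDDT profile and a
#' block-valued PAE from [make_pae()] over the given interface residues.
#'
#' @param model structure tibble (receptor + binder chains).
#' @param binder_iface,receptor_iface author residue ids forming the
#'   interface block (defaults: none).
#' @param plddt default per-residue pLDDT (scalar), optionally overridden
#'   by `plddt_overrides`.
#' @param plddt_overrides tibble with `chain`, `resid`, `plddt` columns.
#' @param interface_value,background_value,symmetrize see [make_pae()].
#' @return a `confidence_data` object.
#' @export
make_confidence <- function(model, binder_iface = integer(),
                            receptor_iface = integer(), plddt = 90,
                            plddt_overrides = NULL, interface_value = 5,
                            background_value = 25, symmetrize = FALSE) {
  ord <- residue_table(model)
  imap <- tibble::tibble(chain = ord$chain, resid = ord$resid,
                         index = seq_len(nrow(ord)))
  pl <- rep(plddt, nrow(ord))
  if (!is.null(plddt_overrides)) {
    for (i in seq_len(nrow(plddt_overrides))) {
      hit <- imap$chain == plddt_overrides$chain[i] &
        imap$resid == plddt_overrides$resid[i]
      pl[hit] <- plddt_overrides$plddt[i]
    }
  }
  rch <- chain_of_role(model, "receptor")
  bch <- chain_of_role(model, "binder")
  rres <- ord$resid[ord$chain == rch]
  bres <- ord$resid[ord$chain == bch]
  n <- nrow(ord)
  pae <- matrix(background_value, n, n)
  if (length(binder_iface) && length(receptor_iface)) {
    rows <- imap$index[match(paste(bch, binder_iface),
                             paste(imap$chain, imap$resid))]
    cols <- imap$index[match(paste(rch, receptor_iface),
                             paste(imap$chain, imap$resid))]
    if (anyNA(rows) || anyNA(cols)) {
      stop("interface residues absent from model", call. = FALSE)
    }
    pae[rows, cols] <- interface_value
    if (symmetrize) pae[cols, rows] <- interface_value
  }
  confidence_data(pl, pae, imap)
}

#' Default fluorescence-polarization concentration series
#'
#' Three-fold titration ladder from `low` up, plus the top concentration:
#' 1.8, 5.4, 16.2, 48.6, 145.8, 437.4 and 500 nM by default, covering the
#' assayed 1.8-500 nM range.
#'
#' @param low,high range endpoints, nM.
#' @param fold dilution factor.
#' @return increasing numeric vector of concentrations, nM.
#' @export
fp_series <- function(low = 1.8, high = 500, fold = 3) {
  ladder <- low * fold^(0:floor(log(high / low) / log(fold)))
  sort(unique(c(ladder, high)))
}

#' Simulate a noisy saturation binding curve
#'
#' Responses on the one-site curve [predict_one_site()] plus iid Gaussian
#' noise. Identical seed gives an identical curve.
#'
#' @param kd,bmax true parameters (nM / response units, > 0).
#' @param concentrations nM series (default [fp_series()]).
#' @param noise_sd Gaussian noise SD in response units.
#' @param seed integer seed (NULL: use current RNG state).
#' @param replicate replicate id stored alongside.
#' @return tibble `concentration_nM`, `response`, `replicate`.
#' @export
make_binding_curve <- function(kd, bmax, concentrations = fp_series(),
                               noise_sd = 0, seed = NULL, replicate = 1L) {
  if (kd <= 0 || bmax <= 0) stop("kd and bmax must be positive",
                                 call. = FALSE)
  y0 <- predict_one_site(kd, bmax, concentrations)
  noise <- with_seed(seed, stats::rnorm(length(y0), 0, noise_sd))
  if (noise_sd == 0) noise <- rep(0, length(y0))
  tibble::tibble(concentration_nM = concentrations,
                 response = y0 + noise, replicate = replicate)
}
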