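test_that("representative coordinate follows the CB / glycine / fallback rules", {
  ala <- tibble::tibble(chain = "B", resid = 1L, resname = "ALA",
                        atom = c("N", "CA", "CB"),
                        x = c(9, 8, 1), y = c(9, 8, 2), z = c(9, 8, 3))
  expect_equal(representative_coordinate(ala), c(1, 2, 3))
  gly <- tibble::tibble(chain = "B", resid = 2L, resname = "GLY",
                        atom = c("N", "CA"),
                        x = c(9, 0), y = c(9, 0), z = c(9, 0))
  expect_equal(representative_coordinate(gly), c(0, 0, 0))
  bare <- tibble::tibble(chain = "B", resid = 3L, resname = "ALA",
                         atom = "N", x = 5, y = 5, z = 5)
  expect_equal(representative_coordinate(bare), c(5, 5, 5))
  expect_error(representative_coordinate(bare, fallback = FALSE),
               "representative")
  expect_error(representative_coordinate(bare[0, ]), "no atoms")
})

test_that("contacts appear at 3.5 A and vanish at 4.6 A separation", {
  near <- interface_residues(toy_pair(sep = 3.5))
  expect_equal(nrow(near), 1L)
  expect_equal(near$min_atom_distance, 3.5)
  far <- interface_residues(toy_pair(sep = 4.6))
  expect_equal(nrow(far), 0L)
})

test_that("cutoffs are inclusive at the boundary", {
  exact <- interface_residues(toy_pair(sep = 4.0))
  expect_equal(nrow(exact), 1L)
})

test_that("site restriction removes off-site receptor contacts", {
  model <- toy_pair(sep = 3.5)
  # receptor residue is 178 (in patch 1); restrict to a site without it
  site_without <- binding_site(patch1 = 222, patch2 = 284, patch3 = 340)
  off <- interface_residues(model, site = site_without)
  expect_equal(nrow(off), 0L)
  on <- interface_residues(model, site = b55_site())
  expect_equal(nrow(on), 1L)
  unrestricted <- interface_residues(model)
  expect_equal(nrow(unrestricted), 1L)
  expect_error(interface_residues(
    model, site = binding_site(integer(), integer(), integer())), "empty")
})

test_that("residues below the pLDDT floor are excluded and recorded", {
  sf <- scored_fixture(seed = 11)
  b <- unique(sf$fx$truth$binder_resid)
  victim <- b[1]
  conf_low <- make_confidence(
    sf$fx$model, binder_iface = b,
    receptor_iface = unique(sf$fx$truth$receptor_resid),
    plddt = 90,
    plddt_overrides = tibble::tibble(chain = "B", resid = victim,
                                     plddt = 49.9))
  iface <- interface_residues(sf$fx$model, conf = conf_low,
                              site = b55_site())
  excl <- attr(iface, "excluded_low_plddt")
  expect_true(victim %in% excl$resid[excl$chain == "B"])
  expect_false(victim %in% binder_iface(iface))
  # boundary: exactly 50 is kept ("below 50" is strict)
  conf_edge <- make_confidence(
    sf$fx$model, binder_iface = b,
    receptor_iface = unique(sf$fx$truth$receptor_resid), plddt = 90,
    plddt_overrides = tibble::tibble(chain = "B", resid = victim,
                                     plddt = 50))
  iface_edge <- interface_residues(sf$fx$model, conf = conf_edge,
                                   site = b55_site())
  expect_true(victim %in% binder_iface(iface_edge))
})

test_that("two-stage result is a subset of the exhaustive oracle, equal under CB coverage", {
  for (seed in 1:30) {
    fx <- make_helix_complex(random_complex_spec(seed))
    two <- interface_residues(fx$model)
    ex <- interface_residues_exhaustive(fx$model)
    key <- function(m) paste(m$binder_resid, m$receptor_resid)
    expect_true(all(key(two) %in% key(ex)))
    # poly-ALA probes: every atom within 4.47 A of the representative
    # coordinate, so the prefilter can hide nothing
    expect_identical(key(two), key(ex))
    # generator ground truth matches the exhaustive map
    expect_identical(key(ex), paste(fx$truth$binder_resid,
                                    fx$truth$receptor_resid))
  }
})

test_that("long side chains defeat the prefilter; exhaustive finds the pair", {
  model <- long_sidechain_counterexample()
  two <- interface_residues(model)
  ex <- interface_residues_exhaustive(model)
  expect_equal(nrow(two), 0L)
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$min_atom_distance, 3.5, tolerance = 1e-9)
})

test_that("well-separated chains give an empty map", {
  model <- toy_pair(sep = 25)
  expect_equal(nrow(interface_residues(model)), 0L)
  expect_equal(nrow(interface_residues_exhaustive(model)), 0L)
})

test_that("enlarging the cutoff never removes pairs; shrinking the site never adds", {
  fx <- make_helix_complex(random_complex_spec(17))
  key <- function(m) paste(m$binder_resid, m$receptor_resid)
  small <- interface_residues(fx$model, atomic_cutoff = 3.2)
  big <- interface_residues(fx$model, atomic_cutoff = 4.5)
  expect_true(all(key(small) %in% key(big)))
  full_site <- interface_residues(fx$model, site = b55_site())
  p1_only <- binding_site(patch1 = b55_site()$patch1, patch2 = integer(),
                          patch3 = integer())
  shrunk <- interface_residues(fx$model, site = p1_only)
  expect_true(all(key(shrunk) %in% key(full_site)))
})

test_that("interface map is invariant under rigid-body transformation", {
  fx <- make_helix_complex(random_complex_spec(23))
  base <- interface_residues(fx$model)
  for (s in 1:5) {
    set.seed(s)
    tr <- helixscreen:::random_rigid()
    moved <- transform_structure(fx$model, tr$rotation, tr$translation)
    got <- interface_residues(moved)
    expect_equal(got$min_atom_distance, base$min_atom_distance,
                 tolerance = 1e-9)
    expect_identical(got$binder_resid, base$binder_resid)
    expect_identical(got$receptor_resid, base$receptor_resid)
  }
})

test_that("interface pairs export as a TSV pair list", {
  fx <- make_helix_complex(helix_complex_spec(seed = 9))
  iface <- interface_residues(fx$model)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_interface_pairs(iface, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(iface))
  expect_true(all(c("binder_chain", "binder_resid", "receptor_chain",
                    "receptor_resid", "min_atom_distance") %in%
                    names(back)))
})

test_that("missing chain roles error", {
  h <- ideal_helix(8)
  m <- new_structure(h)  # single chain: receptor only, no binder
  expect_error(interface_residues(m), "binder")
})
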