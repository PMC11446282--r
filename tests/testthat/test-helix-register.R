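test_that("an ideal helix is assigned as one long segment", {
  h <- ideal_helix(12)
  m <- new_structure(h)
  seg <- assign_helices(m, "B")
  expect_equal(nrow(seg), 1L)
  expect_gte(seg$length, 10L)  # termini each lack one dihedral
})

test_that("extended strands are never called helical", {
  # build an extended chain with NeRF at beta-ish torsions
  g <- helixscreen:::.helix_geo
  n <- 10
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N
  N[1, ] <- c(0, 0, 0); CA[1, ] <- c(1.458, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in 2:n) {
    N[i, ] <- helixscreen:::nerf_place(N[i-1,], CA[i-1,], C[i-1,],
                                       g$b_c_n, g$a_ca_c_n, 120)
    CA[i, ] <- helixscreen:::nerf_place(CA[i-1,], C[i-1,], N[i,],
                                        g$b_n_ca, g$a_c_n_ca, 180)
    C[i, ] <- helixscreen:::nerf_place(C[i-1,], N[i,], CA[i,],
                                       g$b_ca_c, g$a_n_ca_c, -120)
  }
  atoms <- dplyr::bind_rows(lapply(1:n, function(i) {
    tibble::tibble(chain = "B", resid = i, resname = "ALA",
                   atom = c("N", "CA", "C"),
                   x = c(N[i,1], CA[i,1], C[i,1]),
                   y = c(N[i,2], CA[i,2], C[i,2]),
                   z = c(N[i,3], CA[i,3], C[i,3]))
  }))
  m <- new_structure(atoms)
  expect_equal(nrow(assign_helices(m, "B")), 0L)
})

test_that("helix-loop-helix gives exactly two segments", {
  m <- helix_loop_helix()
  seg <- assign_helices(m, "B")
  expect_equal(nrow(seg), 2L)
  expect_true(all(seg$length >= 4))
})

test_that("residues with missing backbone warn and are skipped", {
  h <- ideal_helix(8)
  h <- h[!(h$resid == 4 & h$atom == "CA"), ]
  m <- new_structure(h)
  expect_warning(seg <- assign_helices(m, "B"), "backbone")
})

test_that("patch contacts label by receptor patch membership", {
  fx <- make_helix_complex(cdca4_spec())
  iface <- interface_residues(fx$model, site = b55_site())
  pc <- classify_patch_contacts(iface, b55_site())
  expect_setequal(pc$patch[pc$binder_resid == 56], "patch1")
  expect_setequal(pc$patch[pc$binder_resid == 58], "patch3")
  expect_setequal(pc$patch[pc$binder_resid == 60], "patch1")
  expect_setequal(pc$patch[pc$binder_resid == 61], "patch2")
  # residues with no pairs are absent
  expect_false(57 %in% pc$binder_resid)
  # removing a pair never adds a label
  pc_less <- classify_patch_contacts(iface[-1, ], b55_site())
  expect_true(nrow(pc_less) <= nrow(pc))
  expect_true(all(paste(pc_less$binder_resid, pc_less$patch) %in%
                    paste(pc$binder_resid, pc$patch)))
})

test_that("a residue contacting two patches carries both labels", {
  # hand-built: one binder residue with two probes from patch2 and patch3
  binder <- tibble::tibble(
    chain = "B", resid = 7L, resname = "ALA",
    atom = c("CB", "CA", "N", "C"),
    x = c(0, 0, -1.4, 1.2), y = c(0, -1.5, -2.1, -2.3), z = 0)
  probe <- function(resid, y0, name) {
    tibble::tibble(chain = "A", resid = resid, resname = name,
                   atom = c("CB", "CA"), x = 0, y = c(y0, y0 + 1.5), z = 0)
  }
  probe_down <- tibble::tibble(chain = "A", resid = 340L, resname = "ASP",
                               atom = c("CB", "CA"), x = 3.9,
                               y = c(0, 1.5), z = 0)  # 3.9 A sideways
  m <- new_structure(dplyr::bind_rows(probe(284L, 3.5, "ILE"), probe_down,
                                      binder), receptor_chain = "A")
  iface <- interface_residues_exhaustive(m, site = b55_site())
  pc <- classify_patch_contacts(iface, b55_site())
  expect_setequal(pc$patch[pc$binder_resid == 7], c("patch2", "patch3"))
})

test_that("the CDCA4-like register is recovered (anchor 56, offsets 0/2/4/5)", {
  fx <- make_helix_complex(cdca4_spec())
  iface <- interface_residues(fx$model, site = b55_site())
  helices <- assign_helices(fx$model)
  pc <- classify_patch_contacts(iface, b55_site())
  reg <- assign_register(helices, pc, iface, fx$model)
  expect_equal(register_anchor(reg), 56L)
  tab <- register_table(reg)
  expect_equal(tab$patches[tab$offset == 0], "patch1")
  expect_equal(tab$patches[tab$offset == 2], "patch3")
  expect_equal(tab$patches[tab$offset == 4], "patch1")
  expect_equal(tab$patches[tab$offset == 5], "patch2")
  expect_false(1 %in% tab$offset)
})

test_that("a single patch-1 contact anchors the register by itself", {
  spec <- helix_complex_spec(binder_length = 12, anchor_resid = 30,
                             binder_start = 26,
                             contacts = c("0" = "patch1"), seed = 5)
  fx <- make_helix_complex(spec)
  iface <- interface_residues(fx$model, site = b55_site())
  reg <- assign_register(assign_helices(fx$model),
                         classify_patch_contacts(iface, b55_site()),
                         iface, fx$model)
  expect_equal(register_anchor(reg), 30L)
  expect_equal(register_table(reg)$offset, 0L)
})

test_that("the helix with more patch-1 residues wins selection", {
  m <- helix_loop_helix()
  # helix 1: residues 1-10, helix 2: residues 16-25; give helix 2 three
  # patch-1 contacts and helix 1 one, via a synthetic interface map
  pairs <- tibble::tibble(
    binder_chain = "B", binder_resid = c(3L, 17L, 18L, 21L),
    receptor_chain = "A", receptor_resid = c(178L, 197L, 222L, 225L),
    min_atom_distance = 3.5, n_atom_contacts = 1L)
  attr(pairs, "excluded_low_plddt") <-
    tibble::tibble(chain = character(), resid = integer(),
                   plddt = numeric())
  attr(pairs, "params") <- list()
  class(pairs) <- c("interface_map", class(tibble::tibble()))
  pc <- classify_patch_contacts(pairs, b55_site())
  seg <- assign_helices(m, "B")
  reg <- assign_register(seg, pc, pairs, m)
  bh <- binding_helix(reg)
  expect_gte(bh$start, 16L)
  expect_equal(register_anchor(reg), 17L)  # 17/21 form the i/i+4 pair
  # the stray helix-1 contact lands in unassigned, not in the offsets
  expect_true(3 %in% unassigned_contacts(reg)$resid)
})

test_that("adjacent-helix contacts stay in unassigned_contacts", {
  m <- helix_loop_helix()
  pairs <- tibble::tibble(
    binder_chain = "B", binder_resid = c(17L, 19L, 21L, 4L),
    receptor_chain = "A", receptor_resid = c(178L, 340L, 197L, 287L),
    min_atom_distance = 3.5, n_atom_contacts = 1L)
  attr(pairs, "excluded_low_plddt") <-
    tibble::tibble(chain = character(), resid = integer(),
                   plddt = numeric())
  attr(pairs, "params") <- list()
  class(pairs) <- c("interface_map", class(tibble::tibble()))
  pc <- classify_patch_contacts(pairs, b55_site())
  reg <- assign_register(assign_helices(m, "B"), pc, pairs, m)
  expect_equal(register_anchor(reg), 17L)
  expect_true(4 %in% unassigned_contacts(reg)$resid)
  expect_false(4 %in% register_table(reg)$resid)
})

test_that("no patch-1 contact raises the non-canonical binder error", {
  fx <- make_helix_complex(helix_complex_spec(
    contacts = c("2" = "patch3"), seed = 8))
  iface <- interface_residues(fx$model, site = b55_site())
  pc <- classify_patch_contacts(iface, b55_site())
  expect_error(assign_register(assign_helices(fx$model), pc, iface,
                               fx$model), "non-canonical")
})

test_that("motif report marks patches under the right residues", {
  fx <- make_helix_complex(cdca4_spec())
  iface <- interface_residues(fx$model, site = b55_site())
  pc <- classify_patch_contacts(iface, b55_site())
  reg <- assign_register(assign_helices(fx$model), pc, iface, fx$model)
  rep_ <- motif_report(reg, fx$model, pc)
  expect_length(rep_, 5L)
  # locate columns for residues 56/58/60/61 in the span
  header <- rep_[1]
  lo <- as.integer(sub(".*residues (\\d+)-.*", "\\1", header))
  patch_line <- sub("^patches: ", "", rep_[4])
  anchor_line <- sub("^anchor : ", "", rep_[5])
  col <- function(resid) resid - lo + 1L
  expect_equal(substr(patch_line, col(56), col(56)), "1")
  expect_equal(substr(patch_line, col(58), col(58)), "3")
  expect_equal(substr(patch_line, col(60), col(60)), "1")
  expect_equal(substr(patch_line, col(61), col(61)), "2")
  expect_equal(substr(anchor_line, col(56), col(56)), "i")
})

test_that("motif report is byte-identical under rigid transforms", {
  fx <- make_helix_complex(cdca4_spec())
  run <- function(model) {
    iface <- interface_residues(model, site = b55_site())
    pc <- classify_patch_contacts(iface, b55_site())
    reg <- assign_register(assign_helices(model), pc, iface, model)
    motif_report(reg, model, pc)
  }
  base <- run(fx$model)
  set.seed(99)
  tr <- helixscreen:::random_rigid()
  moved <- transform_structure(fx$model, tr$rotation, tr$translation)
  expect_identical(run(moved), base)
})

test_that("register shifts with constant residue renumbering", {
  run_anchor <- function(shift) {
    spec <- helix_complex_spec(binder_length = 14,
                               anchor_resid = 56L + shift,
                               binder_start = 52L + shift,
                               contacts = c("0" = "patch1", "2" = "patch3",
                                            "4" = "patch1"), seed = 3)
    fx <- make_helix_complex(spec)
    iface <- interface_residues(fx$model, site = b55_site())
    pc <- classify_patch_contacts(iface, b55_site())
    register_anchor(assign_register(assign_helices(fx$model), pc, iface,
                                    fx$model))
  }
  expect_equal(run_anchor(0L), 56L)
  expect_equal(run_anchor(100L), 156L)
})
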