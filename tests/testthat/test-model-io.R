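test_that("a minimal single-residue PDB parses into one chain / residue", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.600   0.000  1.00 77.70           N",
    "ATOM      2  CA  ALA A   1       1.400   0.000   0.000  1.00 77.70           C",
    "ATOM      3  C   ALA A   1       2.200   1.300   0.000  1.00 77.70           C",
    "ATOM      4  O   ALA A   1       1.700   2.400   0.000  1.00 77.70           O",
    "ATOM      5  CB  ALA A   1       1.900  -0.900  -1.200  1.00 77.70           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- read_structure(f)
  expect_equal(length(unique(m$chain)), 1L)
  expect_equal(nrow(residue_table(m)), 1L)
  expect_equal(nrow(m), 5L)
  expect_equal(unique(m$b), 77.7)
  expect_equal(unique(m$role), "receptor")
})

test_that("write/read round trips preserve identity and coordinates", {
  fx <- make_helix_complex(helix_complex_spec(seed = 7))
  for (fmt in c("pdb", "mmcif")) {
    f <- withr::local_tempfile(fileext = paste0(".", sub("mmcif", "cif", fmt)))
    write_structure(fx$model, f, format = fmt)
    back <- read_structure(f, receptor_chain = "A")
    expect_equal(nrow(back), nrow(fx$model))
    expect_equal(back$chain, fx$model$chain)
    expect_equal(back$resid, fx$model$resid)
    expect_equal(back$atom, fx$model$atom)
    expect_equal(back$x, fx$model$x, tolerance = 2e-3)
    expect_equal(back$y, fx$model$y, tolerance = 2e-3)
    expect_equal(back$z, fx$model$z, tolerance = 2e-3)
  }
})

test_that("round trip holds for randomized fixtures (coordinate precision)", {
  for (seed in 1:50) {
    fx <- make_helix_complex(random_complex_spec(seed))
    f <- withr::local_tempfile(fileext = ".pdb")
    write_structure(fx$model, f)
    back <- read_structure(f, receptor_chain = "A")
    expect_equal(as.matrix(back[, c("x", "y", "z")]),
                 as.matrix(fx$model[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_identical(back$resid, fx$model$resid)
    unlink(f)
  }
})

test_that("two-chain fixture reports the generator's chain sizes", {
  spec <- helix_complex_spec(binder_length = 12, anchor_resid = 5,
                             binder_start = 1,
                             contacts = c("0" = "patch1", "4" = "patch1"),
                             n_far_probes = 4, seed = 3)
  fx <- make_helix_complex(spec)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fx$model, f)
  m <- read_structure(f, receptor_chain = "A")
  counts <- residue_table(m) |> dplyr::count(chain)
  expect_equal(counts$n[counts$chain == "A"], 6L)  # 2 contacts + 4 far
  expect_equal(counts$n[counts$chain == "B"], 12L)
})

test_that("gzipped structures read transparently", {
  fx <- make_helix_complex(helix_complex_spec(seed = 2))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fx$model, f)
  gz <- paste0(f, ".gz")
  con <- gzfile(gz, "w")
  writeLines(readLines(f), con)
  close(con)
  back <- read_structure(gz, receptor_chain = "A")
  expect_equal(nrow(back), nrow(fx$model))
})

test_that("degenerate writes and reads error clearly", {
  fx <- make_helix_complex(helix_complex_spec(seed = 1))
  expect_error(write_structure(fx$model[0, ], tempfile()), "empty")
  bad <- fx$model
  bad$x[1] <- NaN
  expect_error(write_structure(bad, tempfile()), "non-finite")
  expect_error(read_structure(tempfile(fileext = ".pdb")),
               "does not exist")
})

test_that("author numbering passes through unmodified (resid 999)", {
  h <- ideal_helix(6, start_resid = 995L)
  m <- new_structure(h)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  raw <- readLines(f)
  expect_true(any(grepl(" 999 ", substr(raw, 21, 30))))
  back <- read_structure(f)
  expect_true(999L %in% back$resid)
})

test_that("insertion codes are rejected", {
  lines <- c(
    "ATOM      1  CA  ALA A   1A      0.000   0.000   0.000  1.00 50.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00 50.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  expect_error(read_structure(f), "nsertion")
})

test_that("scores_json accepts both PAE key dialects, validates shape", {
  fx <- make_helix_complex(helix_complex_spec(seed = 4))
  n <- nrow(residue_table(fx$model))
  for (key in c("predicted_aligned_error", "pae")) {
    js <- withr::local_tempfile(fileext = ".json")
    payload <- list(plddt = rep(90, n))
    payload[[key]] <- matrix(7, n, n)
    jsonlite::write_json(payload, js, digits = NA, matrix = "rowmajor")
    conf <- read_confidence(js, model = fx$model)
    expect_equal(dim(conf$pae), c(n, n))
    expect_equal(unique(as.vector(conf$pae)), 7)
    expect_equal(nrow(conf$index_map), n)
  }
  # non-square matrix
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(plddt = rep(90, n),
                            pae = matrix(7, n, n - 1)),
                       js, digits = NA, matrix = "rowmajor")
  expect_error(read_confidence(js, model = fx$model), "square")
  # pLDDT out of range
  js2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(plddt = c(rep(90, n - 1), 101),
                            pae = matrix(7, n, n)),
                       js2, digits = NA, matrix = "rowmajor")
  expect_error(read_confidence(js2, model = fx$model), "\\[0, 100\\]")
})

test_that("bfactor_plddt dialect takes per-residue pLDDT, leaves PAE absent", {
  fx <- make_helix_complex(helix_complex_spec(seed = 5))
  m <- fx$model
  m$b <- 77.7
  conf <- read_confidence(m, dialect = "bfactor_plddt")
  expect_true(all(conf$plddt == 77.7))
  expect_null(conf$pae)
  iface <- interface_residues(m, conf = conf)
  expect_error(score_model(iface, conf), "PAE")
})

test_that("synthetic scores file carries the prescribed interface block", {
  sf <- scored_fixture(seed = 6, interface_value = 5.0)
  js <- withr::local_tempfile(fileext = ".json")
  write_confidence(sf$conf, js)
  conf <- read_confidence(js, model = sf$fx$model)
  b <- unique(sf$fx$truth$binder_resid)
  r <- unique(sf$fx$truth$receptor_resid)
  bi <- conf$index_map$index[match(paste("B", b),
                                   paste(conf$index_map$chain,
                                         conf$index_map$resid))]
  ri <- conf$index_map$index[match(paste("A", r),
                                   paste(conf$index_map$chain,
                                         conf$index_map$resid))]
  expect_true(all(conf$pae[bi, ri] == 5.0))
})

test_that("index map is a bijection over all residues", {
  for (seed in c(1, 12, 31)) {
    fx <- make_helix_complex(random_complex_spec(seed))
    conf <- make_confidence(fx$model)
    expect_setequal(conf$index_map$index,
                    seq_len(nrow(residue_table(fx$model))))
    expect_equal(nrow(conf$index_map), nrow(residue_table(fx$model)))
  }
})
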