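# All structure tests run against the generated ring-multimer fixture,
# whose geometry (and therefore every label) is known by construction.

fx <- make_fixture_structure(n_chains = 5, n_residues = 8)
model <- load_structure(fx$path)

test_that("the pentamer fixture loads with its chains and planted ions", {
  expect_equal(model$chains, c("A", "B", "C", "D", "E"))
  expect_equal(nrow(model$atoms), 5 * 8 * 3)
  expect_setequal(model$ions$species, c("Ca2+", "K+", "Cl-"))
  # planted ion coordinates are recovered exactly
  ca <- model$ions[model$ions$species == "Ca2+", ]
  expect_equal(unname(unlist(ca[, c("x", "y", "z")])),
               unname(unlist(fx$ions[fx$ions$species == "Ca2+",
                                     c("x", "y", "z")])),
               tolerance = 1e-3)
  # estimated pore axis is the construction's z axis
  expect_equal(abs(unname(model$axis$direction[3])), 1, tolerance = 1e-6)
})

test_that("interface detection finds exactly the facing residues", {
  # adjacent chains touch only at their innermost residue (4.1 A apart)
  ir <- interface_residues(model, "A", "B", cutoff = 5)
  expect_equal(ir$resno, 1L)
  expect_equal(ir$min_dist, 2 * 3.5 * sin(pi / 5), tolerance = 1e-4)
  # symmetry of the relation
  expect_equal(interface_residues(model, "B", "A", cutoff = 5)$resno, 1L)
  # non-adjacent chains are farther than the cutoff; cutoff 0 is empty
  expect_equal(nrow(interface_residues(model, "A", "C", cutoff = 5)), 0L)
  expect_equal(nrow(interface_residues(model, "A", "B", cutoff = 0)), 0L)
  expect_error(interface_residues(model, "A", "Z"), "unknown chain")
})

test_that("ion proximity reports distance and owning chain", {
  pr <- site_proximity(model, "A", 4, "Ca2+", cutoff = 8)
  expect_true(pr$applicable && pr$within)
  expect_equal(pr$distance, 2 - 0.6, tolerance = 1e-6) # N atom sits 0.6 above CA
  expect_equal(pr$ion_chain, "B")  # the clasp belongs to the neighbour
  far <- site_proximity(model, "A", 8, "Ca2+", cutoff = 8)
  expect_false(far$within)
  expect_gt(far$distance, 8)

  # a species absent from the model is not-applicable, not an error
  no_ions <- model
  no_ions$ions <- model$ions[model$ions$species != "Cl-", ]
  na_res <- site_proximity(no_ions, "A", 1, "Cl-")
  expect_false(na_res$applicable)
})

test_that("location classification matches the generator's ground truth", {
  for (i in seq_len(nrow(fx$truth))) {
    rl <- classify_variant_location(model, sprintf("p.(Gly%dAla)", i))
    expect_setequal(rl$labels,
                    strsplit(fx$truth$labels[i], ";", fixed = TRUE)[[1]])
  }
  expect_error(classify_variant_location(model, "p.(Gly400Ala)"),
               "outside the modelled range")
})

test_that("labels are monotone in the cutoffs", {
  base <- location_cutoffs()
  wide <- location_cutoffs(interface = base$interface * 2,
                           ion = base$ion * 2, pore = base$pore * 2)
  for (i in seq_len(8)) {
    v <- sprintf("p.(Gly%dAla)", i)
    l1 <- setdiff(classify_variant_location(model, v, base)$labels, "other")
    l2 <- setdiff(classify_variant_location(model, v, wide)$labels, "other")
    expect_true(all(l1 %in% l2))
  }
})

test_that("consequence lookup maps labels to mechanisms", {
  cons <- location_consequences(c("interface:B", "near-Ca-site:A",
                                  "pore-lining"))
  expect_true("channel formation and stability" %in% cons)
  expect_true("channel activation" %in% cons)
  expect_true(any(grepl("gating", cons)))
})

test_that("degenerate structures load but restrict queries", {
  fx1 <- make_fixture_structure(n_chains = 1, n_residues = 4)
  m1 <- load_structure(fx1$path)
  expect_equal(length(m1$chains), 1L)
  expect_error(interface_residues(m1, "A", "A"), "at least 2 subunits")
  # an unknown het species is dropped with a warning; waters are dropped
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   3       6.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4 MG    MG A   4       0.000   5.000   0.000  1.00  0.00          MG",
    "HETATM    5  O   HOH A   5       0.000   8.000   0.000  1.00  0.00           O",
    "END"), tmp)
  expect_warning(m2 <- load_structure(tmp), "unknown het species")
  expect_equal(nrow(m2$ions), 0L)
  expect_equal(nrow(m2$atoms), 3L)
})
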