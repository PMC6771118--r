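test_that("dimerization energy is the plain difference of totals", {
  expect_equal(dimerization_energy(energy_components(-100, -40, -45)), -15)
  expect_equal(dimerization_energy(energy_components(0, 0, 0)), 0)
  expect_equal(dimerization_energy(
    energy_components(-250.5, -120.25, -110.25)), -20)
})

test_that("relative dimerization energy is antisymmetric and gauge-free", {
  var <- energy_components(-115, -50, -50, label = "var")    # dE = -15
  nat <- energy_components(-110, -50, -50, label = "native") # dE = -10
  expect_equal(relative_dimerization_energy(var, nat), -5)
  expect_equal(relative_dimerization_energy(nat, var), 5)
  expect_equal(relative_dimerization_energy(nat, nat), 0)
  # constant offset on every total of both species cancels
  set.seed(3)
  for (i in 1:20) {
    e <- runif(6, -300, 0); off <- runif(1, -50, 50)
    a <- energy_components(e[1], e[2], e[3])
    b <- energy_components(e[4], e[5], e[6])
    a2 <- energy_components(e[1] + off, e[2] + off, e[3] + off)
    b2 <- energy_components(e[4] + off, e[5] + off, e[6] + off)
    expect_equal(relative_dimerization_energy(a2, b2),
                 relative_dimerization_energy(a, b), tolerance = 1e-9)
    # offset applied to the dimer totals only is pure gauge too
    a3 <- energy_components(e[1] + off, e[2], e[3])
    b3 <- energy_components(e[4] + off, e[5], e[6])
    expect_equal(relative_dimerization_energy(a3, b3),
                 relative_dimerization_energy(a, b), tolerance = 1e-9)
  }
})

test_that("calcium-binding energy halves the two-ion difference", {
  c1 <- energy_components(-200, -90, -90, e_tot_dimer_2ca = -300,
                          e_sol_ca = -40)
  expect_equal(ca_binding_energy(c1), -10)
  c0 <- energy_components(0, 0, 0, e_tot_dimer_2ca = 0, e_sol_ca = 0)
  expect_equal(ca_binding_energy(c0), 0)
  c2 <- energy_components(-400, -90, -90, e_tot_dimer_2ca = -600,
                          e_sol_ca = -80)
  expect_equal(ca_binding_energy(c2), 2 * ca_binding_energy(c1))

  v <- energy_components(-200, -90, -90, -296, -40)   # dE_Cabin = -8
  n <- energy_components(-200, -90, -90, -300, -40)   # dE_Cabin = -10
  expect_equal(relative_ca_binding_energy(v, n), 2)
  expect_equal(relative_ca_binding_energy(n, v), -2)
  expect_equal(relative_ca_binding_energy(n, n), 0)
})

test_that("missing components raise missing-data errors", {
  expect_error(energy_components(NA, 0, 0), "finite")
  expect_error(energy_components(0, 0, 0, e_tot_dimer_2ca = -10),
               "e_sol_ca")
  plain <- energy_components(-100, -40, -45)
  expect_error(ca_binding_energy(plain), "calcium components missing")
})

test_that("component tables round-trip into relative-energy tables", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "label,e_tot_dimer,e_tot_monomer_a,e_tot_monomer_b,e_tot_dimer_2ca,e_sol_ca",
    "native,-110,-50,-50,-300,-40",
    "p.(Thr2Ile),-115,-50,-50,-296,-40",
    "p.(Gly15Asp),-108,-50,-50,NA,NA"), tmp)
  comp <- read_energy_components(tmp)
  expect_named(comp, c("native", "p.(Thr2Ile)", "p.(Gly15Asp)"))
  tab <- energy_table(comp)
  expect_equal(tab$dde_dim[tab$variant == "p.(Thr2Ile)"], -5)
  # hand check: dE_Cabin(var) = (-296 + 115 + 80)/2 = -50.5,
  #             dE_Cabin(native) = (-300 + 110 + 80)/2 = -55
  expect_equal(tab$dde_cabin[tab$variant == "p.(Thr2Ile)"], 4.5)
  expect_equal(tab$dde_dim[tab$variant == "p.(Gly15Asp)"], 2)
  expect_true(is.na(tab$dde_cabin[tab$variant == "p.(Gly15Asp)"]))
  expect_error(energy_table(comp, native_label = "missing"),
               "no component entry")
})
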