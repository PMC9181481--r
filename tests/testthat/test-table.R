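test_that("the reference table is internally consistent", {
  tab <- rons_reference_table()
  expect_equal(nrow(tab), 12L)
  # additive identity holds exactly at printed precision for every row
  expect_true(all(abs(tab$dg_gs + tab$dg_sl - tab$dg_hydr) <= 0.01 + 1e-12))
  # classification grouping: 9 hydrophilic, 3 hydrophobic
  cl <- classify_species(tab$dg_hydr)
  expect_equal(sum(cl == "hydrophilic"), 9L)
  expect_equal(tab$species[cl == "hydrophobic"], c("O3", "NO", "NO2"))
  # the OH barrier implied by the identity
  oh <- tab[tab$species == "OH", ]
  expect_equal(oh$dg_hydr - oh$dg_gs, 5.53, tolerance = 1e-9)
})

test_that("recomputed enhancements agree with the printed ones", {
  tab <- rons_reference_table()
  es <- concentration_enhancement(tab$dg_gs, 300)
  eb <- concentration_enhancement(tab$dg_hydr, 300)
  tol_s <- interfep:::.enhancement_tol(tab$enhancement_surface,
                                       tab$surface_decimals)
  tol_b <- interfep:::.enhancement_tol(tab$enhancement_bulk,
                                       tab$bulk_decimals)
  expect_true(all(abs(es - tab$enhancement_surface) <= tol_s))
  expect_true(all(abs(eb - tab$enhancement_bulk) <= tol_b))
})

test_that("feeding the reference table to the validator passes every cell", {
  tab <- rons_reference_table()
  report <- dplyr::mutate(tab,
                          enhancement_surface = enhancement_surface,
                          enhancement_bulk = enhancement_bulk,
                          hydro_class = classify_species(dg_hydr))
  diff <- validate_against_table(report, tab)
  expect_equal(nrow(diff), 48L)
  expect_true(all(diff$pass))
})

test_that("the validator is sensitive to a perturbed barrier", {
  tab <- rons_reference_table()
  report <- dplyr::mutate(tab, hydro_class = classify_species(dg_hydr))
  report$dg_sl[report$species == "OH"] <-
    report$dg_sl[report$species == "OH"] + 0.02
  diff <- validate_against_table(report, tab)
  bad <- diff[diff$species == "OH" & diff$cell == "identity", ]
  expect_false(bad$pass)
  expect_true(all(diff$pass[diff$species != "OH"]))
})

test_that("schema mismatches are reported", {
  tab <- rons_reference_table()
  expect_error(validate_against_table(tab[, c("species", "dg_gs")], tab),
               "missing columns")
  rep2 <- dplyr::mutate(tab, hydro_class = classify_species(dg_hydr),
                        species = paste0(species, "_x"))
  expect_error(validate_against_table(rep2, tab), "no species")
})
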