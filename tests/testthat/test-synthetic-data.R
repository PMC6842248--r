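# Generators: determinism, planted structure, and contract errors.

test_that("expression generator plants perfectly correlated modules when noise-free", {
  mod <- module_spec("m1", paste0("g", 1:10))
  m <- generate_expression_matrix(20, 30, list(mod), noise_sd = 0, seed = 4)
  rho <- cor(t(m[mod$member_genes, ]), method = "spearman")
  expect_true(all(rho == 1))
  # background stays background
  bg <- setdiff(rownames(m), mod$member_genes)[1]
  expect_false(any(abs(cor(t(m), method = "spearman")[mod$member_genes,
                                                      bg]) == 1))
})

test_that("independent module latents stay uncorrelated at compendium scale", {
  between <- unlist(lapply(1:20, function(seed) {
    mods <- list(module_spec("a", paste0("a", 1:5)),
                 module_spec("b", paste0("b", 1:5)))
    m <- generate_expression_matrix(10, 155, mods, noise_sd = 0, seed = seed)
    cor(t(m[paste0("a", 1:5), ]), t(m[paste0("b", 1:5), ]),
        method = "spearman")
  }))
  expect_lt(median(abs(between)), 0.3)
})

test_that("expression generator is deterministic and validates its inputs", {
  mods <- list(module_spec("m", paste0("g", 1:4), 0.8))
  m1 <- generate_expression_matrix(30, 12, mods, noise_sd = 0.2, seed = 11)
  m2 <- generate_expression_matrix(30, 12, mods, noise_sd = 0.2, seed = 11)
  expect_identical(m1, m2)
  expect_false(identical(
    m1, generate_expression_matrix(30, 12, mods, noise_sd = 0.2, seed = 12)))
  overlapping <- list(module_spec("a", c("g1", "g2")),
                      module_spec("b", c("g2", "g3")))
  expect_error(generate_expression_matrix(10, 12, overlapping, 0, 1),
               "overlap")
  expect_error(generate_expression_matrix(10, 4, mods, 0, 1),
               "n_conditions")
})

test_that("expression matrix TSV round-trips and load-time validation rejects bad input", {
  m <- generate_expression_matrix(8, 6, list(), noise_sd = 0, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  expect_equal(read_expression_matrix(path), m, tolerance = 1e-12)
  bad <- m; bad[1, 1] <- NA
  expect_error(validate_expression_matrix(bad), "missing")
  expect_error(validate_expression_matrix(m[, 1:4]), "5 conditions")
})

test_that("GO annotation generator plants module terms and is seed-stable", {
  genes <- sprintf("g%04d", 1:1000)
  mod <- module_spec("m", genes[1:20], enriched_terms = "GO:PLANT")
  ann <- generate_go_annotations(genes, list(mod), background_terms = 50,
                                 terms_per_gene = 2, seed = 9)
  planted <- ann$gene[ann$term == "GO:PLANT"]
  expect_setequal(planted, genes[1:20])
  expect_identical(ann, generate_go_annotations(genes, list(mod), 50, 2, 9))
  # every annotated gene has >= 1 term by construction of the table
  expect_true(all(table(ann$gene) >= 1))
  expect_error(generate_go_annotations(character(), list(), 10, 1, 1),
               "non-empty")
})

test_that("with no background pool genes carry exactly their planted terms", {
  genes <- c("a", "b", "c", "d")
  mod <- module_spec("m", c("a", "b"), enriched_terms = c("GO:1", "GO:2"))
  ann <- generate_go_annotations(genes, list(mod), background_terms = 0,
                                 terms_per_gene = 1, seed = 1)
  expect_setequal(ann$term[ann$gene == "a"], c("GO:1", "GO:2"))
  expect_setequal(ann$term[ann$gene == "b"], c("GO:1", "GO:2"))
  expect_false(any(c("c", "d") %in% ann$gene))  # unannotated, outside universe
})

test_that("rendered pellets and fragments match their requested geometry", {
  sp <- image_spec(400, 400, 1,
                   pellets = list(pellet_spec(c(100, 100), 100)),
                   fragments = list(fragment_spec(c(300, 300), 200),
                                    fragment_spec(c(100, 300), 120, "line")))
  out <- render_culture_image(sp)
  expect_equal(out$truth$size_class, c("pellet", "dispersed", "dispersed"))
  expect_equal(out$truth$true_area_um2[1], pi * 50^2, tolerance = 1e-12)
  measured <- measure_structures(out$image, 1)
  # rendered areas within 3% of requested (labelling order is raster order,
  # so pair structures with truth rows by nearest area)
  idx <- vapply(out$truth$true_area_um2,
                function(a) which.min(abs(measured$area_um2 - a)), integer(1))
  expect_true(all(abs(measured$area_um2[idx] / out$truth$true_area_um2 - 1)
                  <= 0.03))
})

test_that("renderer rejects overlapping or out-of-bounds objects, accepts empty spec", {
  expect_error(render_culture_image(
    image_spec(200, 200, 1, pellets = list(pellet_spec(c(100, 100), 80),
                                           pellet_spec(c(130, 100), 80)))),
    "overlap")
  expect_error(render_culture_image(
    image_spec(100, 100, 1, pellets = list(pellet_spec(c(10, 50), 40)))),
    "outside")
  blank <- render_culture_image(image_spec(50, 50, 1))
  expect_equal(sum(blank$image), 0)
  expect_equal(nrow(blank$truth), 0L)
})

test_that("rendered area error stays within 3% across a randomized shape suite", {
  set.seed(42)  # test-local randomization of requested shapes
  for (i in 1:10) {
    major <- runif(1, 40, 120)
    minor <- runif(1, 0.5, 1) * major
    rough <- runif(1, 0, 0.2)
    sp <- image_spec(400, 400, 1,
                     pellets = list(pellet_spec(c(200, 200), major, minor,
                                                orientation_deg = runif(1, 0, 180),
                                                roughness = rough)),
                     seed = i)
    out <- render_culture_image(sp)
    measured <- measure_structures(out$image, 1)
    expect_equal(measured$area_um2, out$truth$true_area_um2, tolerance = 0.03)
  }
})

test_that("fermentation generator reproduces model means exactly when noise-free", {
  spec <- dose_response_spec(noise_cv = 0, seed = 5)
  tab <- generate_fermentation_table(spec)
  em <- spec$effect_model
  expect_equal(nrow(tab), nrow(em) * spec$replicate_count)
  first <- tab[tab$replicate == 1, ]
  expect_equal(first$protein_mg, em$protein_mg)
  expect_equal(first$citric_g_l, em$citric_g_l)
  # zero model means stay exactly zero even with noise
  noisy <- generate_fermentation_table(dose_response_spec(noise_cv = 0.3, seed = 5))
  expect_true(all(noisy$citric_g_l[noisy$strain == "TC4.4" &
                                     noisy$dox_ug_ml <= 0.2] == 0))
})

test_that("fermentation generator is deterministic and validates noise", {
  s1 <- generate_fermentation_table(dose_response_spec(noise_cv = 0.2, seed = 8))
  s2 <- generate_fermentation_table(dose_response_spec(noise_cv = 0.2, seed = 8))
  expect_identical(s1, s2)
  expect_error(dose_response_spec(noise_cv = -0.1), "nonnegative")
  expect_error(dose_response_spec(replicate_count = 1), ">= 2")
})
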