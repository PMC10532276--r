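tab2_labels <- c(
  "Chemical_Dosing", "Control", "CPB_adults", "CPB_eggs", "CPB_larvae",
  "CPB_pupae", "E_puttleri_Pop", "E_puttleri_Rep", "Eclosion", "Foliage",
  "Hatching", "Health_of_E_puttleri", "Health_of_L_decemlineata",
  "Health_of_O_dichrous", "Health_of_Potato", "Infestation",
  "L_decemlineata_Est", "L_decemlineata_Pop", "L_decemlineata_Rep",
  "Level_of_Infestation", "O_dichrous_Pop", "O_dichrous_Rep", "Pesticide",
  "Potato_Rep", "Pupation", "Tuber", "Tuberization", "Underground_Bud",
  "Vegetative_Rep")

test_that("the agroecosystem network has the full 29-material, 11-unit structure", {
  net <- potato_cpb_network()
  expect_length(net$materials, 29)
  expect_length(net$units, 11)
  expect_equal(n_nodes(net), 40)
  expect_setequal(names(net$materials), tab2_labels)
  expect_setequal(net$products, c("Tuber", "Level_of_Infestation", "Control"))
  g <- as_igraph(net)
  expect_true(igraph::is_connected(g, mode = "weak"))
})

test_that("the maximal structure retains every process of the full model", {
  net <- potato_cpb_network()
  m <- msg(net, net$products)
  expect_setequal(names(m$units), names(net$units))
  expect_equal(n_nodes(m), 40)
  # and is a fixed point
  expect_setequal(names(msg(m)$units), names(net$units))
})

test_that("the bundled model file reproduces the in-code network", {
  f <- system.file("extdata", "potato_cpb.json", package = "sepgraph")
  net <- load_network(f)
  expect_length(net$materials, 29)
  expect_length(net$units, 11)
  expect_equal(net, potato_cpb_network())
})

test_that("the scenario suite yields ten distinct structures including the null", {
  suite <- cached_suite()
  expect_length(suite$results, 10)
  keys <- vapply(suite$results, function(r)
    paste(r$structure$unit_ids, collapse = ","), character(1))
  expect_length(unique(keys), 10)
  expect_identical(suite$results$null$structure$unit_ids, character(0))
  expect_identical(
    vapply(suite$results, `[[`, character(1), "label"),
    c(curative_chemical = "SS1", biocontrol_parasitoid = "SS2",
      biocontrol_predator = "SS3", preventative_chemical = "SS4",
      preventative_parasitoid = "SS5", preventative_predator = "SS6",
      uncontrolled = "SS7", healthy = "SS8", no_potato_chemical = "SS9",
      null = "SS10"))
})

test_that("scenario optima land on the narrated unit sets", {
  suite <- cached_suite()
  u <- function(nm) suite$results[[nm]]$structure$unit_ids
  pest_chain <- c("cpb_establishment", "cpb_infestation", "cpb_reproduction",
                  "egg_hatching", "larval_pupation", "pupal_eclosion")
  potato <- c("potato_reproduction", "tuberization")
  expect_setequal(u("healthy"), potato)
  expect_setequal(u("uncontrolled"), c(potato, pest_chain))
  expect_setequal(u("curative_chemical"), c(potato, pest_chain, "pesticide_dosing"))
  expect_setequal(u("biocontrol_parasitoid"),
                  c(potato, pest_chain, "e_puttleri_reproduction"))
  expect_setequal(u("biocontrol_predator"),
                  c(potato, pest_chain, "o_dichrous_reproduction"))
  expect_setequal(u("preventative_chemical"),
                  c(potato, "cpb_establishment", "pesticide_dosing"))
  expect_setequal(u("preventative_parasitoid"),
                  c(potato, "cpb_establishment", "e_puttleri_reproduction"))
  expect_setequal(u("preventative_predator"),
                  c(potato, "cpb_establishment", "egg_hatching",
                    "larval_pupation", "pupal_eclosion",
                    "o_dichrous_reproduction"))
  expect_setequal(u("no_potato_chemical"),
                  c("cpb_establishment", "pesticide_dosing"))
})

test_that("chemical control eradicates both natural enemies", {
  suite <- cached_suite()
  for (nm in c("curative_chemical", "preventative_chemical",
               "no_potato_chemical")) {
    res <- suite$results[[nm]]
    # neither enemy population is produced ...
    expect_equal(product_rate(res, "Control"), 1, tolerance = 1e-9)
    expect_false("e_puttleri_reproduction" %in% res$structure$unit_ids)
    expect_false("o_dichrous_reproduction" %in% res$structure$unit_ids)
    # ... while the dosing process consumes both enemies' health in full
    nf <- res$flow$net_flows
    expect_equal(unname(nf[["Health_of_E_puttleri"]]), -1, tolerance = 1e-9)
    expect_equal(unname(nf[["Health_of_O_dichrous"]]), -1, tolerance = 1e-9)
  }
})

test_that("no scenario structure runs both biocontrol agents together", {
  suite <- cached_suite()
  both <- vapply(suite$results, function(r) {
    all(c("e_puttleri_reproduction", "o_dichrous_reproduction") %in%
          r$structure$unit_ids)
  }, logical(1))
  expect_false(any(both))
})

test_that("a dual-release scenario gains nothing over the single-agent optimum", {
  rs <- sepgraph:::potato_raw_sets()
  dual <- structure(list(
    name = "dual_biocontrol", label = NA_character_,
    description = "both natural enemies released into an established infestation",
    available_raws = sort(unique(c(rs$potato, rs$invasion, rs$life_cycle,
                                   rs$parasitoid, rs$predator)), method = "radix"),
    required_products = "Control", required_flows = c(Control = 1),
    rate_overrides = numeric(0), allow_null = FALSE), class = "scenario_config")
  res <- run_scenario(dual, n_best = 5)
  # releasing both agents buys nothing over the single-agent optimum ...
  single <- run_scenario("biocontrol_parasitoid")
  expect_equal(res$flow$objective_value, single$flow$objective_value,
               tolerance = 1e-9)
  # ... and at most one agent is ever active at the optimum
  agents <- c("e_puttleri_reproduction", "o_dichrous_reproduction")
  active <- names(which(res$flow$levels[intersect(agents, names(res$flow$levels))] > 1e-9))
  expect_lte(length(active), 1)
  # no ranked structure with both agents active beats the single-agent optimum
  for (p in res$ranking) {
    lv <- p$flow$levels
    if (all(agents %in% names(lv)) && all(lv[agents] > 1e-9)) {
      expect_lte(p$flow$objective_value, single$flow$objective_value + 1e-9)
    }
  }
})

test_that("scenario errors are informative", {
  expect_error(potato_cpb_scenarios("no_such"), "unknown scenario")
  sc <- potato_cpb_scenarios("healthy")
  sc$rate_overrides <- c(not_a_unit = 0.5)
  expect_error(build_potato_cpb(sc), "nonexistent unit")
})
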