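test_that("constructors validate ids, ratios and bipartite references", {
  expect_error(material(""), "non-empty")
  expect_error(operating_unit("u", c(A = 1), c(A = 1)), "disjoint")
  expect_error(operating_unit("u", c(A = 0), c(B = 1)), "> 0")
  expect_error(operating_unit("u", numeric(0), c(B = 1)), "non-empty")
  expect_error(
    process_network(list(material("A", "raw"), material("A", "raw")), list()),
    "duplicate material")
  expect_error(
    process_network(list(material("A", "raw")),
                    list(operating_unit("u1", c(A = 1), c(Ghost_Material = 1)))),
    "Ghost_Material")
  # a raw material can never be produced (axiom S2 at network level)
  expect_error(
    process_network(list(material("A", "raw"), material("B", "raw")),
                    list(operating_unit("u1", c(A = 1), c(B = 1)))),
    "S2")
  # minimal valid network: one raw, one product, one unit
  net <- process_network(list(material("R", "raw"), material("P", "product")),
                         list(operating_unit("u1", c(R = 1), c(P = 1))))
  expect_s3_class(net, "process_network")
  expect_equal(n_nodes(net), 3)
})

test_that("model files round-trip through JSON and YAML", {
  net <- toy1()
  for (ext in c(".json", ".yaml")) {
    f <- tempfile(fileext = ext)
    write_network(net, f)
    expect_equal(load_network(f), net)
    unlink(f)
  }
  # parse errors carry file context
  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(load_network(bad), "cannot parse")
  unlink(bad)
  expect_error(load_network(tempfile(fileext = ".json")), "not found")
  # undeclared reference in a file is a validation error naming both sides
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    materials = list(list(id = "R", kind = "raw")),
    units = list(list(id = "u1", inputs = list(R = 1),
                      outputs = list(Ghost_Material = 1)))),
    f2, auto_unbox = TRUE)
  expect_error(load_network(f2), "u1.*Ghost_Material")
  unlink(f2)
})

test_that("axiom checker flags S1/S2/S4 violations on the toy network", {
  net <- toy1()
  # {u1} satisfies all five axioms when P is required
  expect_identical(nrow(check_axioms(net, "u1", "P")), 0L)
  # {u2}: P absent (S1) and u2 has no path to a product (S4)
  v <- check_axioms(net, "u2", "P")
  expect_setequal(v$axiom, c("S1", "S4"))
  expect_true(all(c("P", "u2") %in% v$node))
  # null structure vacuously consistent with no required products
  expect_identical(nrow(check_axioms(net, character(0))), 0L)
  # ... but violates S1 the moment a product is required
  expect_identical(check_axioms(net, character(0), "P")$axiom, "S1")
  # unknown unit is an error, not a violation (S3 precondition)
  expect_error(check_axioms(net, "nope"), "unknown unit")
  # consumed-but-unproducible non-raw input is a hard S2 violation
  net2 <- process_network(
    list(material("R", "raw"), material("X", "intermediate"),
         material("P", "product")),
    list(operating_unit("u1", c(R = 1, X = 1), c(P = 1))))
  expect_identical(check_axioms(net2, "u1", "P")$axiom, "S2")
  expect_length(brute_force_structures(net2, "P"), 0)
})

test_that("structure materials are exactly the incident materials (S5)", {
  net <- toy1()
  for (ids in list("u1", c("u1", "u2"), c("u1", "u2", "u3"), character(0))) {
    s <- solution_structure(net, ids)
    expected <- sort(unique(unlist(lapply(net$units[ids], function(u)
      c(names(u$inputs), names(u$outputs))))))
    expect_identical(s$material_ids, as.character(expected))
  }
  # a tampered material set is caught as an S5 violation
  s <- solution_structure(net, "u1")
  s$material_ids <- c(s$material_ids, "I")
  expect_identical(check_axioms(net, s, "P")$axiom, "S5")
})

test_that("graph export renders the bipartite digraph in DOT and GraphML", {
  net <- toy1()
  dot <- export_graph(net, format = "dot")
  # 6 nodes and 6 arcs
  expect_length(grep("shape=", strsplit(dot, "\n")[[1]]), 6)
  expect_length(grep("->", strsplit(dot, "\n")[[1]]), 6)
  # null structure gives an empty graph document
  dot0 <- export_graph(net, solution_structure(net), format = "dot")
  expect_false(grepl("->", dot0))
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 6)
  xml <- export_graph(net, format = "graphml")
  expect_match(xml, "graphml")
})
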