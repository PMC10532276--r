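test_that("msg keeps exactly the units that can take part in a feasible structure", {
  net <- toy1()
  m <- msg(net, "P")
  expect_setequal(names(m$units), c("u1", "u2", "u3"))
  # a unit whose output feeds nothing is pruned
  net2 <- process_network(
    list(material("R", "raw"), material("I", "intermediate"),
         material("I2", "intermediate"), material("P", "product")),
    list(operating_unit("u1", c(R = 1), c(P = 1)),
         operating_unit("u2", c(R = 1), c(I = 1)),
         operating_unit("u3", c(I = 1), c(P = 1)),
         operating_unit("u4", c(R = 1), c(I2 = 1))))
  expect_setequal(names(msg(net2, "P")$units), c("u1", "u2", "u3"))
  # infeasible problem: empty network plus a warning
  net3 <- process_network(
    list(material("R", "raw"), material("X", "intermediate"),
         material("P", "product")),
    list(operating_unit("u1", c(X = 1), c(P = 1))))
  expect_warning(m3 <- msg(net3, "P"), "infeasible")
  expect_length(m3$units, 0)
})

test_that("msg is idempotent", {
  for (seed in 1:10) {
    net <- generate_instance(sweep_spec(seed))$network
    m1 <- suppressWarnings(msg(net, quiet = TRUE))
    m2 <- suppressWarnings(msg(m1, quiet = TRUE))
    expect_equal(names(m2$units), names(m1$units))
    expect_equal(names(m2$materials), names(m1$materials))
  }
})

test_that("ssg enumerates the toy structures in deterministic order", {
  net <- toy1()
  s <- ssg(msg(net, "P"), "P")
  expect_identical(unit_key_set(s), c("u1", "u1,u2,u3", "u2,u3"))
  # lexicographic ordering of the returned list itself
  expect_identical(vapply(s, function(x) paste(x$unit_ids, collapse = ","),
                          character(1)),
                   c("u1", "u1,u2,u3", "u2,u3"))
  # optional products: same three plus the null structure
  s0 <- ssg(msg(net), allow_null = TRUE)
  expect_length(s0, 4)
  expect_identical(s0[[1]]$unit_ids, character(0))
  # repeated runs are identical
  expect_identical(unit_key_set(ssg(msg(net, "P"), "P")), unit_key_set(s))
})

test_that("brute force refuses oversized networks and handles edge cases", {
  mats <- c(list(material("R", "raw"), material("P", "product")),
            lapply(sprintf("I%02d", 1:21), material, kind = "intermediate"))
  units <- c(list(operating_unit("u00", c(R = 1), c(P = 1))),
             lapply(1:21, function(i)
               operating_unit(sprintf("u%02d", i), c(R = 1),
                              stats::setNames(1, sprintf("I%02d", i)))))
  big <- process_network(mats, units)
  expect_error(brute_force_structures(big, "P"), "more than 20")
  single <- process_network(list(material("R", "raw"), material("P", "product")),
                            list(operating_unit("u1", c(R = 1), c(P = 1))))
  expect_identical(unit_key_set(brute_force_structures(single, "P")), "u1")
})

test_that("ssg agrees with brute-force enumeration across random instances", {
  for (seed in 1:40) {
    inst <- generate_instance(sweep_spec(seed))
    net <- inst$network
    for (req in list(character(0), net$products)) {
      s1 <- ssg(suppressWarnings(msg(net, req, quiet = TRUE)), req,
                allow_null = TRUE)
      s2 <- brute_force_structures(net, req, allow_null = TRUE)
      expect_identical(unit_key_set(s1), unit_key_set(s2))
    }
  }
})

test_that("msg equals the union of all brute-force structures", {
  for (seed in 1:40) {
    net <- generate_instance(sweep_spec(seed))$network
    for (req in list(character(0), net$products)) {
      m <- suppressWarnings(msg(net, req, quiet = TRUE))
      bf <- brute_force_structures(net, req, allow_null = TRUE)
      expect_identical(sort(names(m$units)), structure_union(bf))
    }
  }
})

test_that("every ssg structure is axiom-consistent and inside the maximal structure", {
  for (seed in 1:20) {
    net <- generate_instance(sweep_spec(seed))$network
    m <- suppressWarnings(msg(net, quiet = TRUE))
    for (s in ssg(m)) {
      expect_identical(nrow(check_axioms(net, s)), 0L)
      expect_true(all(s$unit_ids %in% names(m$units)))
    }
  }
})
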