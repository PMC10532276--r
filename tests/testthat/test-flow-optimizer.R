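test_that("single capacity-saturated unit delivers its capacity", {
  net <- process_network(list(material("R", "raw"), material("P", "product")),
                         list(operating_unit("u1", c(R = 1), c(P = 1), 0.5)))
  fr <- optimize_structure("u1", flow_model(net, objective = c(P = 1)))
  expect_identical(fr$status, "optimal")
  expect_equal(unname(fr$net_flows[["P"]]), 0.5)
  expect_equal(unname(fr$net_flows[["R"]]), -0.5)
})

test_that("exact balance propagates a 2:1 conversion through a chain", {
  chain <- process_network(
    list(material("R", "raw"), material("I", "intermediate"),
         material("P", "product")),
    list(operating_unit("u2", c(R = 1), c(I = 1), 1),
         operating_unit("u3", c(I = 2), c(P = 1), 1)))
  fr <- optimize_structure(c("u2", "u3"),
                           flow_model(chain, balance_mode = "exact",
                                      objective = c(P = 1)))
  expect_equal(unname(fr$levels[c("u2", "u3")]), c(1, 0.5))
  expect_equal(unname(fr$net_flows[["P"]]), 0.5)
  expect_equal(unname(fr$net_flows[["I"]]), 0, tolerance = 1e-9)
})

test_that("required flows beyond reach give an infeasible result, not an error", {
  net <- process_network(list(material("R", "raw"), material("P", "product")),
                         list(operating_unit("u1", c(R = 1), c(P = 1), 0.5)))
  fr <- optimize_structure("u1",
                           flow_model(net, objective = c(P = 1),
                                      required_flows = c(P = 2)))
  expect_identical(fr$status, "infeasible")
  expect_true("P" %in% names(fr$violated))
})

test_that("an unbounded objective path is reported as a capacity error", {
  net <- process_network(list(material("R", "raw"), material("P", "product")),
                         list(operating_unit("u1", c(R = 1), c(P = 1))))
  expect_error(optimize_structure("u1", flow_model(net, objective = c(P = 1))),
               "capacity")
})

test_that("the null structure solves to zero flows", {
  net <- toy1()
  fr <- optimize_structure(solution_structure(net), flow_model(net))
  expect_identical(fr$status, "optimal")
  expect_equal(fr$objective_value, 0)
})

test_that("abb reproduces the worked three-structure ranking", {
  net <- toy1(caps = c(u1 = 0.3, u2 = 1, u3 = 1))
  rk <- abb(flow_model(net, objective = c(P = 1)), n_best = 3,
            required_products = "P")
  expect_length(rk, 3)
  expect_identical(lapply(rk, function(p) p$structure$unit_ids),
                   list(c("u1", "u2", "u3"), c("u2", "u3"), "u1"))
  expect_equal(vapply(rk, function(p) p$flow$objective_value, numeric(1)),
               c(1.3, 1.0, 0.3))
  expect_error(abb(flow_model(net), n_best = 0), "n_best")
})

test_that("degenerate all-zero capacities rank lexicographically", {
  net <- toy1(caps = c(u1 = 0, u2 = 0, u3 = 0))
  rk <- abb(flow_model(net, objective = c(P = 1)), n_best = Inf,
            required_products = "P")
  expect_true(all(vapply(rk, function(p) p$flow$objective_value, numeric(1)) == 0))
  keys <- vapply(rk, function(p) paste(p$structure$unit_ids, collapse = ","),
                 character(1))
  expect_identical(keys, sort(keys))
})

test_that("abb matches the exhaustive SSG+LP ranking on random instances", {
  for (seed in 1:25) {
    inst <- generate_instance(sweep_spec(seed))
    model <- flow_model(inst$network)
    rk <- abb(model, n_best = Inf, allow_null = TRUE)
    oracle <- exhaustive_ranking(inst$network, model, allow_null = TRUE)
    expect_length(rk, length(oracle))
    for (i in seq_along(rk)) {
      expect_identical(rk[[i]]$structure$unit_ids, oracle[[i]]$structure$unit_ids)
      expect_equal(rk[[i]]$flow$objective_value,
                   oracle[[i]]$flow$objective_value, tolerance = 1e-9)
    }
    # pruned finite-n search returns the same leading entries
    rk3 <- abb(model, n_best = 3, allow_null = TRUE)
    expect_identical(lapply(rk3, function(p) p$structure$unit_ids),
                     lapply(rk[seq_len(min(3, length(rk)))],
                            function(p) p$structure$unit_ids))
  }
})

test_that("relaxation bounds are admissible for every completion", {
  set.seed(42)
  for (seed in 1:10) {
    inst <- generate_instance(sweep_spec(seed))
    model <- flow_model(inst$network)
    net <- suppressWarnings(msg(inst$network, quiet = TRUE))
    if (!length(net$units)) next
    uids <- names(net$units)
    rk <- abb(model, n_best = Inf, allow_null = TRUE)
    for (rep in 1:5) {
      excl <- uids[stats::runif(length(uids)) < 0.4]
      obj <- model$objective[names(model$objective) %in% names(net$materials)]
      bound <- abb_bound(flow_model(net, capacities = model$capacities[uids],
                                    objective = obj),
                         excluded = excl)
      # every feasible structure avoiding the excluded units is a completion
      for (p in rk) {
        if (!any(p$structure$unit_ids %in% excl)) {
          expect_gte(bound, p$flow$objective_value - 1e-9)
        }
      }
    }
  }
})

test_that("flow results conserve intermediates and respect capacities", {
  for (seed in 1:15) {
    inst <- generate_instance(sweep_spec(seed))
    net <- inst$network
    for (mode in c("surplus", "exact")) {
      model <- flow_model(net, balance_mode = mode)
      for (s in ssg(suppressWarnings(msg(net, quiet = TRUE)))) {
        fr <- optimize_structure(s, model)
        if (!identical(fr$status, "optimal")) next
        expect_true(all(fr$levels <= model$capacities[names(fr$levels)] + 1e-9))
        expect_true(all(fr$levels >= -1e-12))
        inter <- setdiff(names(fr$net_flows), c(net$raws, net$products))
        if (mode == "exact" && length(inter)) {
          expect_true(all(abs(fr$net_flows[inter]) <= 1e-9))
        } else if (length(inter)) {
          expect_true(all(fr$net_flows[inter] >= -1e-9))
        }
        raws <- intersect(names(fr$net_flows), net$raws)
        if (length(raws)) expect_true(all(fr$net_flows[raws] <= 1e-9))
        prods <- intersect(names(fr$net_flows), net$products)
        if (length(prods)) expect_true(all(fr$net_flows[prods] >= -1e-9))
      }
    }
  }
})

test_that("objective values agree with an independent LP solver", {
  skip_if_not_installed("pracma")
  checked <- 0
  for (seed in 1:10) {
    inst <- generate_instance(sweep_spec(seed))
    model <- flow_model(inst$network)
    for (s in ssg(suppressWarnings(msg(inst$network, quiet = TRUE)))) {
      v2 <- pracma_lp_value(model, s$unit_ids)
      if (is.null(v2)) next
      v1 <- optimize_structure(s, model)$objective_value
      expect_equal(v1, v2, tolerance = 1e-6)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 20)
})

test_that("removing a unit never increases the optimal objective", {
  for (seed in 1:10) {
    inst <- generate_instance(sweep_spec(seed))
    model <- flow_model(inst$network)
    ss <- ssg(suppressWarnings(msg(inst$network, quiet = TRUE)))
    vals <- stats::setNames(
      vapply(ss, function(s) optimize_structure(s, model)$objective_value,
             numeric(1)),
      vapply(ss, function(s) paste(s$unit_ids, collapse = ","), character(1)))
    for (s in ss) {
      for (drop in s$unit_ids) {
        key <- paste(setdiff(s$unit_ids, drop), collapse = ",")
        if (key %in% names(vals)) {
          expect_lte(vals[[key]],
                     vals[[paste(s$unit_ids, collapse = ",")]] + 1e-9)
        }
      }
    }
  }
})
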