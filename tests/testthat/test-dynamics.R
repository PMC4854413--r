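# Synchronous/asynchronous simulation, attractor detection, ON-times.

test_that("synchronous step follows rules and holds clamped nodes", {
  net <- two_node_chain()
  s <- initial_state(net)
  expect_identical(unname(s), c(1L, 0L))
  s1 <- step_synchronous(net, s)
  expect_identical(s1[["EGFR1"]], 1L)
  expect_identical(s1[["EGF"]], 1L)
  # a fixed point maps to itself
  expect_identical(step_synchronous(net, s1), s1)
  expect_error(step_synchronous(net, s[1]), "cover every node")
})

test_that("a NOT-self toggle alternates, matching its truth table", {
  net <- parse_network(c("[nodes]", "A, intermediate, 0",
                         "[rules]", "A, NOT A"))
  tr <- simulate_synchronous(net, 6)
  expect_identical(unname(tr["A", ]), c(0L, 1L, 0L, 1L, 0L, 1L, 0L))
})

test_that("an unstimulated network stays all-zero", {
  net <- parse_network(c("[nodes]", "A, intermediate, 0",
                         "B, intermediate, 0",
                         "[rules]", "A, B", "B, A"))
  tr <- simulate_synchronous(net, 5)
  expect_true(all(tr == 0L))
})

test_that("switch hierarchy: inhibitor fires, Rac1 off next step, RhoA on after", {
  net <- rcp_network(hierarchy_spec())
  tr <- simulate_synchronous(net, 50)
  pg_on <- first_switch(tr, "pRacGAP1")
  rac_off <- first_switch(tr, "Rac1", from = 1L, to = 0L)
  rhoa_on <- first_switch(tr, "RhoA")
  expect_identical(rac_off, pg_on + 1L)
  expect_identical(rhoa_on, rac_off + 1L)
  # and the outputs never revert within the horizon
  expect_true(all(tr["Rac1", as.character(rac_off:50)] == 0L))
  expect_true(all(tr["RhoA", as.character(rhoa_on:50)] == 1L))
})

test_that("cyclic hierarchy: Sos1E switches Rac1 on one increment later", {
  net <- rcp_network(hierarchy_spec("Sos1E"))
  tr <- simulate_synchronous(net, 50)
  sos_on <- first_switch(tr, "Sos1E")
  rac_on <- first_switch(tr, "Rac1")            # first OFF -> ON
  rac_off <- first_switch(tr, "Rac1", 1L, 0L)   # initial inhibitor switch
  rhoa_off <- first_switch(tr, "RhoA", 1L, 0L)
  expect_identical(rac_off, first_switch(tr, "pRacGAP1") + 1L)
  expect_identical(rac_on, sos_on + 1L)
  expect_identical(rhoa_off, rac_on + 1L)
})

test_that("attractor detection matches exhaustive enumeration", {
  # 3-node odd inhibitory ring: no fixed point, cycle found by both routes
  ring <- parse_network(c("[nodes]", "A, intermediate, 1",
                          "B, intermediate, 0", "C, intermediate, 0",
                          "[rules]", "A, NOT C", "B, A", "C, B"))
  rep_ <- find_attractor(ring)
  orc <- oracle_attractor(ring)
  expect_gt(rep_$period, 1L)
  expect_identical(rep_$period, orc$period)
  expect_identical(rep_$transient, orc$transient)
  expect_setequal(encode_columns(rep_$cycle), orc$cycle)
  # random networks, several seeds and sizes
  for (seed in 1:15) {
    net <- gen_random_network(2 + (seed %% 9), seed = seed)
    rep_ <- find_attractor(net)
    orc <- oracle_attractor(net)
    expect_identical(rep_$period, orc$period)
    expect_identical(rep_$transient, orc$transient)
    expect_setequal(encode_columns(rep_$cycle), orc$cycle)
  }
})

test_that("cycle is consistent: one step maps last cycle state to first", {
  net <- rcp_network()
  rep_ <- find_attractor(net)
  last <- stats::setNames(rep_$cycle[, rep_$period], rownames(rep_$cycle))
  back <- step_synchronous(net, last)
  expect_identical(unname(back), unname(rep_$cycle[, 1]))
  expect_true(all(rep_$cycle %in% c(0L, 1L)))
  # cyclic class iff strictly intermediate ON fraction
  expect_identical(rep_$node_class == "cyclic",
                   rep_$on_fraction > 0 & rep_$on_fraction < 1)
})

test_that("output classification covers the three published categories", {
  expect_identical(
    classify_hierarchy_output(
      find_attractor(rcp_network(hierarchy_spec("Vav2"))))$category,
    "rac_persistent")
  cls <- classify_hierarchy_output(
    find_attractor(rcp_network(hierarchy_spec("Sos1E"))))
  expect_identical(cls$category, "cyclic")
  expect_true(cls$rhoa_dominant)
  expect_identical(
    classify_hierarchy_output(
      find_attractor(rcp_network(hierarchy_spec())))$category,
    "switch")
  expect_error(
    classify_hierarchy_output(find_attractor(two_node_chain())),
    "lacks output")
})

test_that("asynchronous updates are seed-deterministic and fixed-point safe", {
  net <- rcp_network()
  t1 <- simulate_asynchronous(net, 200, seed = 7)
  t2 <- simulate_asynchronous(net, 200, seed = 7)
  expect_identical(unclass(t1), unclass(t2))
  t3 <- simulate_asynchronous(net, 200, seed = 8)
  expect_false(identical(unclass(t1), unclass(t3)))
  # a network at a fixed point yields a flat trace
  chain <- parse_network(c("EGF, <input>", "EGFR1, EGF"))
  s <- c(EGF = 1L, EGFR1 = 1L)
  tr <- simulate_asynchronous(chain, 20, seed = 1, state = s)
  expect_true(all(tr == 1L))
  # exactly one unstable node behaves as a single synchronous update
  tr1 <- simulate_asynchronous(chain, 1, seed = 1)
  expect_identical(tr1[, 2], step_synchronous(chain, initial_state(chain)))
})

test_that("asynchronous steps flip at most one node and conserve clamps", {
  net <- rcp_network()
  tr <- simulate_asynchronous(net, 300, seed = 3)
  flips <- colSums(tr[, -1, drop = FALSE] != tr[, -ncol(tr), drop = FALSE])
  expect_true(all(flips <= 1))
  for (nd in clamped_nodes(net))
    expect_true(all(tr[nd, ] == tr[nd, 1]))
  expect_true(all(tr %in% c(0L, 1L)))
})

test_that("ON-time bookkeeping after the Rac1/RhoA switch", {
  mk <- function(rac, rho) {
    m <- rbind(Rac1 = rac, RhoA = rho)
    colnames(m) <- seq_along(rac) - 1L
    m
  }
  # switch at t=2, RhoA stays on, Rac1 stays off: (0, T-k)
  tr <- mk(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 1, 1))
  res <- on_time_after_switch(tr)
  expect_true(res$switched)
  expect_identical(res$switch_time, 2L)
  expect_identical(res$rac_on, 0L)
  expect_identical(res$rhoa_on, 3L)
  # no switch -> flagged, not an error
  res2 <- on_time_after_switch(mk(c(1, 1, 1), c(0, 0, 0)))
  expect_false(res2$switched)
  expect_true(is.na(res2$rac_on))
  expect_error(on_time_after_switch(matrix(0, 1, 3,
                                           dimnames = list("Rac1", 0:2))),
               "lacks output")
})

test_that("trace exports use the heatmap layout deterministically", {
  net <- rcp_network()
  tr <- simulate_synchronous(net, 10)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  export_trace_tsv(tr, f1)
  export_trace_tsv(tr, f2)
  expect_identical(readLines(f1), readLines(f2))
  tab <- utils::read.delim(f1, check.names = FALSE)
  expect_identical(nrow(tab), 41L)
  expect_identical(tab$node, net$nodes$name)
  expect_identical(colnames(tab), c("node", as.character(0:10)))
})
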