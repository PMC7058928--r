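lib <- builtin_library()
phlf <- dplyr::filter(lib$gates, name == "P1-PhlF")

test_that("hill_response hits its analytic anchors", {
  expect_equal(hill_response(phlf, 0), 6.9)                      # y_max
  expect_equal(hill_response(phlf, phlf$K), (6.9 + 0.004) / 2)   # half repression
  expect_equal(hill_response(phlf, 1e9), 0.004, tolerance = 1e-6) # y_min limit
  expect_error(hill_response(phlf, -1), "non-negative")
})

test_that("hill_response is monotone non-increasing and bounded for random gates", {
  set.seed(1)
  for (i in 1:20) {
    g <- random_library(n_gates = 1)$gates[1, ]
    x <- sort(c(0, stats::runif(30, 0, 10)))
    y <- hill_response(g, x)
    expect_true(all(diff(y) <= 1e-12))
    expect_true(all(y > g$y_min & y <= g$y_max * (1 + 1e-12)))
  }
})

test_that("roadblock_factor spans [alpha*beta, alpha] and vanishes at unity", {
  expect_equal(roadblock_factor(phlf, 0), phlf$alpha)
  expect_equal(roadblock_factor(phlf, 1e9), phlf$alpha * phlf$beta,
               tolerance = 1e-6)
  expect_equal(roadblock_factor(phlf, phlf$K),
               phlf$alpha * (1 + phlf$beta) / 2)
  unity <- phlf
  unity$alpha <- 1; unity$beta <- 1
  expect_equal(roadblock_factor(unity, c(0, 0.1, 5, 100)), rep(1, 4))
  # monotone non-increasing when beta < 1
  x <- seq(0, 5, length.out = 50)
  f <- roadblock_factor(phlf, x)
  expect_true(all(diff(f) <= 1e-12))
  expect_true(all(f >= phlf$alpha * phlf$beta - 1e-12 & f <= phlf$alpha + 1e-12))
})

test_that("sensor occupancy follows the two-state rule", {
  s <- sensor_record("S", off_rpu = 0.01, on_rpu = 2, alpha = 0.8, beta = 0.3,
                     mode = "repressor")
  expect_equal(roadblock_factor(s, TRUE), 0.8)
  expect_equal(roadblock_factor(s, FALSE), 0.8 * 0.3)
  a <- sensor_record("A", off_rpu = 0.01, on_rpu = 2, alpha = 0.7, beta = 0.3,
                     mode = "activator")
  expect_equal(roadblock_factor(a, c(TRUE, FALSE)), c(0.7, 0.7))
})

test_that("compose_tandem reduces to addition at factor 1", {
  expect_equal(compose_tandem(0.5, 1, 0.3), 0.8)
  expect_equal(compose_tandem(0, 0.42, 0.7), 0.7)
  # factor from P1-PhlF at x_down = K
  f <- roadblock_factor(phlf, phlf$K)
  expect_equal(f, 0.1166)
  expect_equal(compose_tandem(2.0, f, 0.004), 0.2372)
})

test_that("a sensor wired straight to the output passes its flux through", {
  nl <- circuit_netlist(tibble::tibble(
    node = c("x1", "g1", "out"), type = c("INPUT", "NOT", "OUTPUT"),
    in1 = c(NA, "x1", "g1"), sensor = c("P_Tac", NA, NA)))
  asg <- new_assignment(c(g1 = "P1-PhlF"))
  st_on <- evaluate_state(nl, asg, lib, 1)
  st_off <- evaluate_state(nl, asg, lib, 0)
  # NOT gate driven by P_Tac ON: single formula evaluation
  expect_equal(st_on$output_flux[st_on$node == "g1"],
               hill_response(phlf, 1.686))
  expect_equal(st_on$total_input[st_on$node == "g1"], 1.686)
  expect_equal(st_off$total_input[st_off$node == "g1"], 0.008)
  # passthrough netlist: sensor directly drives the output stage
  nl2 <- circuit_netlist(tibble::tibble(
    node = c("x1", "out"), type = c("INPUT", "OUTPUT"),
    in1 = c(NA, "x1"), sensor = c("P_Tac", NA)))
  st <- evaluate_state(nl2, new_assignment(character(0)), lib, 1)
  expect_equal(st$output_flux[st$node == "out"], 1.686)
})

test_that("interference and additive models differ exactly when occupancy < 1", {
  nl <- nand_netlist()
  asg <- new_assignment(c(g_up = "A1-AmtR_2", g_down = "P1-PhlF"))
  for (bits in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    st_i <- evaluate_state(nl, asg, lib, bits, model = "interference")
    st_a <- evaluate_state(nl, asg, lib, bits, model = "additive")
    occ2 <- st_i$occupancy_factor[st_i$node == "g_down"]
    out_i <- st_i$output_flux[st_i$node == "out"]
    out_a <- st_a$output_flux[st_a$node == "out"]
    if (occ2 < 1) expect_lt(out_i, out_a) else expect_equal(out_i, out_a)
  }
})

test_that("evaluate_state agrees with the recursive oracle on random circuits", {
  set.seed(7)
  for (i in 1:25) {
    nl <- random_netlist()
    asg <- random_assignment(nl, lib)
    n_in <- sum(nl$type == "INPUT")
    bits <- sample(0:1, n_in, replace = TRUE)
    for (model in c("interference", "additive")) {
      st <- evaluate_state(nl, asg, lib, bits, model = model)
      for (nd in nl$node) {
        expect_equal(st$output_flux[st$node == nd],
                     oracle_eval_node(nl, asg, lib, as.logical(bits), nd, model),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("every gate output lies within its response bounds", {
  set.seed(8)
  for (i in 1:10) {
    nl <- random_netlist()
    asg <- random_assignment(nl, lib)
    tab <- truth_table_prediction(nl, asg, lib)
    for (k in seq_len(nrow(tab))) {
      ns <- tab$nodes[[k]]
      for (j in which(ns$type %in% c("NOT", "NOR2"))) {
        g <- dplyr::filter(lib$gates, name == asg$node_to_gate[[ns$node[j]]])
        expect_gt(ns$output_flux[j], g$y_min - 1e-12)
        expect_lte(ns$output_flux[j], g$y_max + 1e-12)
        expect_gt(ns$occupancy_factor[j], 0)
        expect_lte(ns$occupancy_factor[j], 1)
      }
    }
  }
})

test_that("truth tables enumerate all states in canonical binary order", {
  nl <- nand_netlist()
  asg <- new_assignment(c(g_up = "P1-PhlF", g_down = "S1-SrpR"))
  tab <- truth_table_prediction(nl, asg, lib)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$bits, c("00", "01", "10", "11"))
  # NAND: logically low only when both inputs are high
  expect_equal(which.min(tab$output), 4)
  expect_gt(min(tab$output[1:3]) / tab$output[4], 1)
})

test_that("circuit_score is the min-ON/max-OFF ratio, invariant to row order", {
  tab <- tibble::tibble(output = c(1.0, 0.1, 5, 9),
                        target = c("1", "0", "X", "X"))
  expect_equal(circuit_score(tab), 10)
  tab2 <- tibble::tibble(output = c(0.5, 0.5), target = c("1", "0"))
  expect_equal(circuit_score(tab2), 1)
  set.seed(3)
  tab3 <- tibble::tibble(output = stats::runif(8), target = rep(c("1", "0"), 4))
  expect_equal(circuit_score(tab3), circuit_score(tab3[sample(8), ]))
  expect_error(circuit_score(tibble::tibble(output = 1, target = "1")),
               "required-O")
})

test_that("netlist structural validation rejects malformed circuits", {
  expect_error(circuit_netlist(tibble::tibble(
    node = c("x1", "g1", "out"), type = c("INPUT", "NOR2", "OUTPUT"),
    in1 = c(NA, "x1", "g1"), sensor = c("P_Tac", NA, NA))), "arity")
  expect_error(circuit_netlist(tibble::tibble(
    node = c("x1", "g1", "g2", "out"), type = c("INPUT", "NOT", "NOT", "OUTPUT"),
    in1 = c(NA, "g2", "g1", "g1"), sensor = c("P_Tac", NA, NA, NA))),
    "cycle|not fed")
  expect_error(circuit_netlist(tibble::tibble(
    node = c("x1", "g1", "out"), type = c("INPUT", "NOT", "OUTPUT"),
    in1 = c(NA, "g1", "g1"), sensor = c("P_Tac", NA, NA))), "cycle")
})

test_that("the tandem validation suite produces 20 circuits x 4 states", {
  suite <- tandem_validation_suite(lib)
  expect_equal(nrow(suite), 80)
  expect_equal(length(unique(suite$circuit)), 20)
  expect_true(all(table(suite$circuit) == 4))
  # interference never increases the prediction relative to additive
  add <- tandem_validation_suite(lib, model = "additive")
  expect_true(all(suite$output <= add$output + 1e-12))
})
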