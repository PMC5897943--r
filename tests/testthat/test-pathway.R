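# Reaction-network loading, kinetics, perturbations, and steady states.

test_that("the packaged network loads and validates", {
  net <- pdl1_network()
  expect_s3_class(net, "pd_network")
  expect_true("PDL1" %in% net$outputs)
  expect_length(net$outputs, 24)
  expect_true(all(c(dc_chemokines(), ism_molecules()) %in% net$outputs))
  expect_true(validate_network(net))
})

test_that("network validation rejects malformed specs", {
  sp <- data.frame(name = c("A", "B"), synthesis = c(1, 0),
                   degradation = c(0.5, 0.5), init = c(0, 0))
  # nonpositive Km
  expect_error(pd_network(sp, list(list(id = "r", kind = "michaelis_menten",
                                        substrate = "A", product = "B",
                                        Vmax = 1, Km = 0))),
               "Km")
  # undeclared species
  expect_error(pd_network(sp, list(list(id = "r", kind = "michaelis_menten",
                                        substrate = "Z", product = "B",
                                        Vmax = 1, Km = 1))),
               "undeclared")
  # bad modifier role
  expect_error(pd_network(sp, list(list(id = "r", kind = "michaelis_menten",
                                        substrate = "A", product = "B",
                                        Vmax = 1, Km = 1,
                                        modifiers = list(
                                          list(species = "B", role = "x",
                                               Ka = 1))))),
               "role")
  # degenerate network: species only, no reactions
  expect_silent(pd_network(sp))
})

test_that("Michaelis-Menten rate law has its textbook anchors", {
  expect_equal(michaelis_menten_rate(1, Vmax = 2, Km = 1), 1)    # S = Km
  expect_equal(michaelis_menten_rate(0, Vmax = 2, Km = 1), 0)
  expect_equal(michaelis_menten_rate(3, Vmax = 2, Km = 1), 1.5)
  expect_error(michaelis_menten_rate(-1, 1, 1), "substrate")
  expect_error(michaelis_menten_rate(1, 1, 0), "Km")
})

test_that("perturbations are pure and scale the intended parameters", {
  net <- pdl1_network()
  before <- net$species
  kras <- apply_perturbations(net, mutation_profile("RAS", "oncogene_gof"))
  expect_identical(net$species, before)  # input untouched
  i <- match("RAS", kras$species$name)
  expect_equal(kras$species$activity[i], 5)
  expect_equal(kras$species$synth_mult[i], 1)

  none <- apply_perturbations(net, mutation_profile(character(0),
                                                    character(0)))
  expect_identical(none, net)

  p53 <- apply_perturbations(net, mutation_profile("TP53", "tsg_lof"))
  expect_equal(p53$species$activity[match("TP53", p53$species$name)], 0.1)

  amp <- apply_perturbations(net, mutation_profile("EGFR", "amplification",
                                                   3))
  expect_equal(amp$species$synth_mult[match("EGFR", amp$species$name)], 3)
  del <- apply_perturbations(net, mutation_profile("EGFR", "deletion"))
  expect_equal(del$species$synth_mult[match("EGFR", del$species$name)], 0)

  expect_error(apply_perturbations(net, mutation_profile("NOTAGENE",
                                                         "tsg_lof")),
               "valid nodes")
  # common gene symbols map onto network nodes
  ali <- apply_perturbations(net, mutation_profile("KRAS", "oncogene_gof"))
  expect_equal(ali$species$activity[match("RAS", ali$species$name)], 5)
})

test_that("mutation profiles parse from TSV with per-effect defaults", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("gene\teffect\tmagnitude",
               "RAS\toncogene_gof\t",
               "TP53\ttsg_lof\t4"), tmp)
  muts <- read_mutations(tmp)
  expect_equal(muts$magnitude, c(5, 4))
  expect_error(mutation_profile("RAS", "unknown_effect"), "effect")
  expect_error(mutation_profile("RAS", "oncogene_gof", -1), "magnitude")
})

test_that("single-species steady state matches the closed form k/d", {
  net <- pd_network(data.frame(name = "X", synthesis = 1,
                               degradation = 0.5, init = 0))
  out <- simulate_steady_state(net)
  expect_true(out$converged)
  expect_equal(unname(out$state["X"]), 2, tolerance = 1e-6)

  dead <- pd_network(data.frame(name = c("A", "B"),
                                synthesis = c(0, 0),
                                degradation = c(0.5, 0.2),
                                init = c(3, 1)))
  out <- simulate_steady_state(dead)
  expect_true(out$converged)
  expect_equal(max(abs(out$state)), 0, tolerance = 1e-6)
})

test_that("packaged baseline reproduces the frozen reference state", {
  ref <- read.csv(test_path("baseline_state.csv"),
                  stringsAsFactors = FALSE)
  out <- simulate_steady_state(pdl1_network())
  expect_true(out$converged)
  expect_lt(out$residual, 1e-9)
  expect_equal(out$state[ref$species], setNames(ref$concentration,
                                                ref$species),
               tolerance = 1e-6)
})

test_that("steady state is insensitive to halving the tolerances", {
  net <- pdl1_network()
  a <- simulate_steady_state(net)
  b <- simulate_steady_state(net, tol_abs = 5e-10, tol_rel = 5e-9)
  expect_lt(max(abs(a$state - b$state) / pmax(abs(a$state), 1e-12)), 1e-4)
})

test_that("zero perturbation leaves all percent changes at zero", {
  sim <- predict_profile(pdl1_network())
  expect_true(sim$converged)
  expect_lt(max(abs(sim$percent_changes)), 0.01)
})

test_that("KRAS activation raises PD-L1 with a monotone dose response", {
  net <- pdl1_network()
  kras <- predict_profile(net, mutation_profile("RAS", "oncogene_gof"))
  expect_gt(kras$percent_changes[["PDL1"]], 0)
  doses <- c(1, 2, 5, 10)
  pdl1 <- vapply(doses, function(m) {
    predict_profile(net, mutation_profile("RAS", "oncogene_gof",
                                          m))$percent_changes[["PDL1"]]
  }, numeric(1))
  expect_true(all(diff(pdl1) > 0))
  expect_equal(pdl1[1], 0, tolerance = 0.01)  # magnitude 1 = no change
})

test_that("KRAS co-mutation subgroups order PD-L1 as reported: KP > K > KL > KC", {
  net <- pdl1_network()
  gof <- function(g) mutation_profile(g, "oncogene_gof")
  lof <- function(g) mutation_profile(g, "tsg_lof")
  pdl1 <- function(muts) {
    predict_profile(net, muts)$percent_changes[["PDL1"]]
  }
  k <- pdl1(gof("RAS"))
  kp <- pdl1(rbind(gof("RAS"), lof("TP53")))
  kl <- pdl1(rbind(gof("RAS"), lof("STK11"), lof("KEAP1")))
  kc <- pdl1(rbind(gof("RAS"), lof("CDKN2A")))
  p53 <- pdl1(lof("TP53"))
  expect_gt(kp, k)
  expect_gt(k, kl)
  expect_gt(kl, kc)
  expect_gt(kp, p53)  # co-mutation beats either single mutation
})
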