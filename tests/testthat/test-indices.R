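test_that("flow accounts of the example web match definition arithmetic", {
  b <- fw_balance(fw_example_web())
  fl <- fw_flows(b)
  expect_equal(fl$T["phytoplankton", "herbivore"], 100)
  expect_equal(fl$T["herbivore", "carnivore"], 5)
  expect_equal(sum(fl$T > 0), 2L)
  expect_equal(unname(fl$exports), rep(0, 4))   # no catch, no migration
  # adding catch raises the carnivore's export and its herbivore EE source
  m <- fw_example_web()
  m$groups$Y[4] <- 2
  b2 <- fw_balance(m)
  expect_equal(unname(b2$flows$exports["carnivore"]), 2)
  expect_equal(b2$model$groups$EE[4], 2 / 1)   # catch 2 over P = 1
})

test_that("summary statistics reproduce the example web component sums", {
  st <- fw_summary_stats(fw_balance(fw_example_web()))
  expect_equal(st$sum_consumption, 105)
  expect_equal(st$sum_respiration, 63)
  expect_equal(st$sum_to_detritus, 937)
  expect_equal(st$TST, 1105)
  expect_equal(st$TPP, 1000)
  expect_equal(st$NSP, 937)
  expect_equal(st$TB, 31)
  # invariant: TST is exactly the sum of its components
  expect_equal(st$TST, st$sum_consumption + st$sum_exports +
                 st$sum_respiration + st$sum_to_detritus)
})

test_that("connectance counts realized links among living groups", {
  expect_equal(fw_connectance(fw_example_web()), 2 / 6)
  # linear 3-group chain
  g <- data.frame(name = c("a", "b", "c"),
                  type = c("producer", "consumer", "consumer"),
                  B = c(10, 1, 0.1), PB = c(10, 2, 1),
                  QB = c(NA, 8, 5), UC = c(NA, 0.2, 0.2))
  d <- matrix(0, 3, 3); d[1, 2] <- 1; d[2, 3] <- 1
  expect_equal(fw_connectance(fw_model(g, d)), 2 / 6)
  # saturated guild: every ordered pair linked
  g2 <- data.frame(name = c("x", "y", "z"), type = "consumer",
                   B = 1, PB = 1, QB = 5, UC = 0.2)
  d2 <- matrix(1 / 2, 3, 3); diag(d2) <- 0
  expect_equal(fw_connectance(fw_model(g2, d2)), 1)
  # undefined below two living groups
  g3 <- data.frame(name = "only", type = "producer", B = 1, PB = 1)
  expect_true(is.na(fw_connectance(fw_model(g3))))
})

test_that("acyclic webs have zero cycling and the two-node loop matches the series oracle", {
  b <- fw_balance(fw_example_web())
  fn <- fw_finn(b$flows)
  expect_equal(fn$FCI, 0)
  expect_equal(fn$throughput_cycled_incl, 0)
  expect_equal(fn$throughput_cycled_excl, 0)

  # detritus fed 4 by import and 6 by its consumer, which eats 10 from it
  fl <- structure(list(
    T = matrix(c(0, 0, 10, 0), 2, 2,
               dimnames = list(c("det", "worm"), c("det", "worm"))),
    imports = c(det = 4, worm = 0), exports = c(det = 0, worm = 0),
    respiration = c(det = 0, worm = 4), to_detritus = c(det = 0, worm = 6),
    detritus_nodes = 1L, living = 2L), class = "fw_flows")
  fn2 <- fw_finn(fl)
  expect_equal(unname(diag(fn2$L)), c(2.5, 2.5))
  expect_equal(fn2$throughput_cycled_incl, 12)
  expect_equal(fn2$FCI, 60)   # of compartmental throughput 20
})

test_that("closed-form cycling equals power-series path enumeration on random webs", {
  for (s in 1:6) {
    m <- fw_generate(fw_recipe(seed = 200 + s))$model
    b <- fw_balance(m)
    fn <- fw_finn(b$flows)
    Tfull <- b$flows$T
    d1 <- b$flows$detritus_nodes[1]
    Tfull[, d1] <- Tfull[, d1] + b$flows$to_detritus
    oracle <- finn_by_power_series(Tfull, b$flows$imports)
    expect_equal(sum(fn$cycled), sum(oracle$cycled), tolerance = 1e-10)
  }
})

test_that("Shannon diversity follows the biomass-share formula", {
  mk <- function(B) {
    g <- data.frame(name = paste0("g", seq_along(B)), type = "producer",
                    B = B, PB = 10)
    fw_balance(fw_model(g))
  }
  expect_equal(fw_shannon(mk(rep(3, 4))), log(4))
  expect_equal(fw_shannon(mk(5)), 0)
  expect_equal(fw_shannon(mk(c(2, 1, 1))),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
})

test_that("information indices: even split has zero ascendency, chains are fully determined", {
  mkfl <- function(Tm, imports = 0, exports = 0, resp = 0) {
    n <- nrow(Tm)
    structure(list(T = Tm, imports = rep(imports, n),
                   exports = rep(exports, n), respiration = rep(resp, n),
                   to_detritus = rep(0, n), detritus_nodes = integer(0),
                   living = seq_len(n)), class = "fw_flows")
  }
  # one source splitting equally into two sinks
  Tm <- matrix(0, 3, 3); Tm[1, 2] <- 5; Tm[1, 3] <- 5
  info <- fw_information(mkfl(Tm))
  expect_equal(info$A, 0)
  expect_equal(info$C, 10)
  # deterministic chain: ascendency reaches capacity
  Tc <- matrix(0, 3, 3); Tc[1, 2] <- 5; Tc[2, 3] <- 5
  info2 <- fw_information(mkfl(Tc))
  expect_equal(info2$AC, 100)
  # 0 <= A <= C on generated webs
  for (s in c(31, 32)) {
    b <- fw_balance(fw_generate(fw_recipe(seed = s))$model)
    ii <- fw_information(b$flows)
    expect_gte(ii$A, 0)
    expect_lte(ii$A, ii$C + 1e-9)
    expect_gt(ii$AC, 0)
    expect_lte(ii$AC, 100)
  }
})

test_that("indices are invariant to group reordering and zero-flow group deletion", {
  w <- fw_generate(fw_recipe(seed = 12))$model
  st <- fw_statistics(fw_balance(w))
  perm <- c(3, 1, 2, seq(4, nrow(w$groups)))
  w2 <- fw_model(w$groups[perm, ], w$diet[perm, perm],
                 w$import_fraction[perm])
  st2 <- fw_statistics(fw_balance(w2))
  for (k in c("TST", "FCI", "FML", "CI", "SOI", "shannon", "A", "C"))
    expect_equal(st[[k]], st2[[k]], tolerance = 1e-9, label = k)

  # append a producer with zero biomass and no links
  g3 <- rbind(w$groups,
              data.frame(name = "ghost", type = "producer", B = 0, PB = 10,
                         QB = NA, EE = NA, UC = NA, Y = 0, NM = 0, BA = 0,
                         R = NA, detritus_import = NA))
  d3 <- rbind(cbind(w$diet, 0), 0)
  w3 <- fw_model(g3, d3, c(w$import_fraction, 0))
  st3 <- fw_statistics(fw_balance(w3))
  for (k in c("TST", "FCI", "FML", "SOI", "A", "C"))
    expect_equal(st[[k]], st3[[k]], tolerance = 1e-9, label = k)
})
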