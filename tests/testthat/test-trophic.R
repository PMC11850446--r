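# brute-force TL oracle: enumerate diet paths down to level-1 sources
tl_by_path_enumeration <- function(model) {
  g <- model$groups
  n <- nrow(g)
  tl <- function(j, depth = 0) {
    if (depth > 20) stop("not acyclic")
    if (g$type[j] != "consumer") return(1)
    col <- model$diet[, j]
    1 + sum(vapply(which(col > 0), function(i)
      col[i] * tl(i, depth + 1), numeric(1))) +
      model$import_fraction[j] * 1
  }
  vapply(seq_len(n), tl, numeric(1))
}

test_that("fractional trophic levels solve the diet-weighted linear system", {
  m <- fw_example_web()
  TL <- fw_trophic_levels(m)
  expect_equal(unname(TL), c(1, 1, 2, 3))

  # consumer feeding entirely on level-1 resources sits at exactly 2.00
  g <- data.frame(name = c("det", "macrophytes", "snail"),
                  type = c("detritus", "producer", "consumer"),
                  B = c(5, 10, 1), PB = c(NA, 8, 2), QB = c(NA, NA, 12),
                  UC = c(NA, NA, 0.4))
  d <- matrix(0, 3, 3); d[1, 3] <- 0.5; d[2, 3] <- 0.5
  expect_equal(unname(fw_trophic_levels(fw_model(g, d))[3]), 2.00)

  # 50% on a TL-2 prey and 50% on a producer -> 2.5
  g2 <- data.frame(name = c("alga", "grazer", "omni"),
                   type = c("producer", "consumer", "consumer"),
                   B = c(10, 1, 0.5), PB = c(20, 2, 1),
                   QB = c(NA, 10, 5), UC = c(NA, 0.2, 0.2))
  d2 <- matrix(0, 3, 3); d2[1, 2] <- 1; d2[1, 3] <- 0.5; d2[2, 3] <- 0.5
  expect_equal(unname(fw_trophic_levels(fw_model(g2, d2))[3]), 2.5)

  # pure self-sustaining cannibal is singular
  g3 <- data.frame(name = c("p", "cann"), type = c("producer", "consumer"),
                   B = c(5, 1), PB = c(10, 1), QB = c(NA, 4),
                   UC = c(NA, 0.2))
  d3 <- matrix(0, 2, 2); d3[2, 2] <- 1
  expect_error(fw_trophic_levels(fw_model(g3, d3)), "singular")
})

test_that("trophic levels match brute-force path expansion on random acyclic webs", {
  for (s in 1:8) {
    m <- random_acyclic_web(sample(4:8, 1), seed = 100 + s)
    expect_equal(unname(fw_trophic_levels(m)),
                 tl_by_path_enumeration(m), tolerance = 1e-10)
  }
})

test_that("omnivory index is the diet variance of prey trophic levels", {
  # 50/50 diet on TL 1 and TL 2 -> OI = 0.25 at own TL 2.5
  g <- data.frame(name = c("alga", "grazer", "omni"),
                  type = c("producer", "consumer", "consumer"),
                  B = c(100, 10, 0.5), PB = c(20, 2, 1),
                  QB = c(NA, 10, 5), UC = c(NA, 0.2, 0.2))
  d <- matrix(0, 3, 3); d[1, 2] <- 1; d[1, 3] <- 0.5; d[2, 3] <- 0.5
  b <- fw_balance(fw_model(g, d))
  omn <- fw_omnivory(b)
  expect_equal(unname(omn$OI["omni"]), 0.25)
  expect_equal(unname(omn$OI["grazer"]), 0)   # specialist

  # a web of specialists has SOI exactly 0
  b2 <- fw_balance(fw_example_web())
  expect_equal(fw_omnivory(b2)$SOI, 0)
})

test_that("Lindeman spine reproduces the example chain and conserves intake", {
  b <- fw_balance(fw_example_web())
  sp <- fw_lindeman(b)
  expect_equal(sp$combined$inflow[2], 100)   # herbivore consumption
  expect_equal(sp$combined$to_next[2], 5)    # passed to the carnivore
  expect_equal(sp$combined$TE[2], 5)         # 5 / 100 in percent
  expect_equal(sp$combined$TE[3], 0)
  # per-level conservation at consumer levels: inflow = outflow parts
  for (k in 2:3) {
    out <- sp$combined$to_next[k] + sp$combined$export_catch[k] +
      sp$combined$respiration[k] + sp$combined$to_detritus[k]
    expect_equal(sp$combined$inflow[k], out, tolerance = 1e-9)
  }
  # apportioned intake sums to total consumption per group
  tot <- rowSums(sp$distribution$producer) + rowSums(sp$distribution$detritus)
  cons <- b$budget$type == "consumer"
  expect_equal(unname(tot[cons]), rep(1, sum(cons)), tolerance = 1e-9)
})

test_that("level IV is empty when no consumer exceeds fractional TL 3", {
  m <- fw_example_web()   # chain tops out at TL 3
  sp <- fw_lindeman(fw_balance(m))
  expect_equal(sp$combined$inflow[4], 0)
  expect_true(is.na(sp$combined$TE[4]))
})

test_that("a TL-3.2 consumer without predators yields TE at level IV of exactly 0", {
  b <- fw_balance(truncated_web())
  expect_equal(unname(fw_trophic_levels(b$model)["mixed"]), 3.2)
  sp <- fw_lindeman(b)
  expect_gt(sp$combined$inflow[4], 0)
  expect_equal(sp$combined$to_next[4], 0)
  expect_identical(sp$combined$TE[4], 0)
})

test_that("transfer efficiencies are scale-invariant in biomass", {
  m <- fw_generate(fw_recipe(seed = 4))$model
  te1 <- fw_transfer_efficiency(fw_lindeman(fw_balance(m)))
  m$groups$B <- m$groups$B * 7.3
  te2 <- fw_transfer_efficiency(fw_lindeman(fw_balance(m)))
  expect_equal(te1$TE_combined, te2$TE_combined, tolerance = 1e-9)
})

test_that("mean transfer efficiency uses the geometric mean over levels II-IV", {
  sp <- fw_lindeman(fw_balance(truncated_web()))
  # constant-chain identity checked directly on the summary function
  fake <- sp
  fake$combined$TE <- c(NA, 10, 10, 10, rep(NA, 4))
  expect_equal(fw_transfer_efficiency(fake)$mean_combined, 10)
  fake$combined$TE <- c(NA, 4, 9, NA, rep(NA, 4))
  expect_equal(fw_transfer_efficiency(fake)$mean_combined, 6)  # sqrt(4*9)
  fake$combined$TE <- c(NA, 4, 9, NA, rep(NA, 4))
  expect_equal(
    fw_transfer_efficiency(fake, mean_type = "arithmetic")$mean_combined,
    6.5)
})
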