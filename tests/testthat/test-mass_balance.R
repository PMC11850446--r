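test_that("solver reproduces the hand-computed budget of the example web", {
  b <- fw_balance(fw_example_web())
  ee <- setNames(b$model$groups$EE, b$model$groups$name)
  # predation on phyto = 10*10*1 = 100 over P = 20*50 = 1000
  expect_equal(unname(ee["phytoplankton"]), 0.100)
  expect_equal(unname(ee["herbivore"]), 0.250)   # 1*5*1 / (10*2)
  expect_equal(unname(ee["carnivore"]), 0)
  expect_true(b$balanced)
  # energy balance Q = P + R + UC*Q per consumer
  cons <- b$budget$type == "consumer"
  uc <- b$model$groups$UC[cons]
  expect_equal(b$budget$Q[cons],
               b$budget$P[cons] + b$budget$R[cons] + uc * b$budget$Q[cons],
               tolerance = 1e-12)
  expect_equal(b$budget$R[b$budget$name == "herbivore"], 60)
  # production balance residual
  liv <- b$budget$type != "detritus"
  resid <- abs(b$budget$P[liv] * b$budget$EE[liv] -
                 b$budget$predation[liv])
  expect_lt(max(resid), 1e-9 * max(b$budget$P[liv]))
})

test_that("producer with no mortality sinks solves to EE = 0", {
  g <- data.frame(name = "algae", type = "producer", B = 5, PB = 20)
  b <- fw_balance(fw_model(g))
  expect_identical(b$model$groups$EE, 0)
})

test_that("EE above 1 is returned flagged, not clamped or raised", {
  b <- fw_balance(fw_example_web(carnivore_qb = 150))
  expect_equal(b$model$groups$EE[3], 7.5)   # 1*150 / (10*2)
  expect_false(b$balanced)
  diag <- fw_diagnose(b)
  expect_identical(diag$name[diag$flag_EE], "herbivore")
})

test_that("unknown biomass solves linearly and negative solutions error", {
  m <- fw_example_web()
  # give the herbivore a known EE instead of B
  m$groups$B[3] <- NA
  m$groups$EE[3] <- 0.25
  b <- fw_balance(m)
  expect_equal(b$model$groups$B[3], 10, tolerance = 1e-12)

  # emigration exceeding production forces a negative biomass
  g2 <- data.frame(name = "alga", type = "producer", B = NA, PB = 10,
                   EE = 0.1, NM = -50)
  expect_error(fw_balance(fw_model(g2)), "negative solved biomass")
})

test_that("per-consumer budget arithmetic matches direct computation", {
  out <- fw_budget(Q = 10, UC = 0.2, P = 2)
  expect_equal(out$R, 6)
  expect_equal(out$GE, 0.2)
  expect_equal(out$RA, 0.75)
  expect_equal(out$PR, 1 / 3)
  # boundary: zero respiration leaves P/R undefined
  out2 <- fw_budget(Q = 10, UC = 0, P = 10)
  expect_equal(out2$R, 0)
  expect_true(is.na(out2$PR))
})

test_that("detritus budget decomposes into unassimilated, unutilized and import", {
  b <- fw_balance(fw_example_web())
  # phyto unutilized 900 + herb (20 UC + 15 unutilized) + carn (1 + 1)
  expect_equal(b$detritus$inflow, 937)
  expect_equal(b$detritus$outflow, 0)
  expect_equal(b$detritus$EE, 0)
  m <- fw_example_web()
  m$groups$detritus_import[1] <- 5
  expect_equal(fw_balance(m)$detritus$inflow, 942)
})

test_that("detritivore consuming the whole inflow gives detritus EE of 1", {
  g <- data.frame(name = c("det", "algae", "worm"),
                  type = c("detritus", "producer", "consumer"),
                  B = c(1, 10, NA), PB = c(NA, 10, 1),
                  QB = c(NA, NA, 10), UC = c(NA, NA, 0.4),
                  EE = c(NA, 0.0, NA))
  d <- matrix(0, 3, 3)
  d[1, 3] <- 1
  # worm B solves so detritus outflow = inflow: inflow = 100 + 0.4 Q + P_w
  # with Q = 10 B, P = B: 10B = 100 + 4B + B  =>  B = 20
  g$EE[2] <- 0   # algae entirely unutilized
  m <- fw_model(g, d)
  m$groups$B[3] <- 20
  m$groups$EE[3] <- NA
  b <- fw_balance(m)
  expect_equal(b$detritus$EE, 1, tolerance = 1e-12)
})

test_that("diagnostics flag gross efficiency outside the plausible band", {
  m <- fw_example_web()
  m$groups$PB[3] <- 3.5    # GE = 35/100 = 0.35
  d <- fw_diagnose(fw_balance(m))
  expect_true(d$flag_GE[d$name == "herbivore"])
  expect_false(any(fw_diagnose(fw_balance(fw_example_web()))$flag_GE))
})

test_that("diet adjustment drives EE to 1 while preserving normalization", {
  m <- fw_example_web(carnivore_qb = 150)
  out <- fw_adjust_diet(m, max_iter = 100, step = 0.1)
  expect_true(out$balanced)
  bal <- fw_balance(out$model)
  expect_true(all(bal$model$groups$EE <= 1 + 1e-9, na.rm = TRUE))
  cons <- out$model$groups$type == "consumer"
  expect_equal(unname(colSums(out$model$diet)[cons] +
                        out$model$import_fraction[cons]),
               rep(1, sum(cons)), tolerance = 1e-9)
  # the over-consumed prey's EE never increased
  expect_lte(bal$model$groups$EE[3], 7.5)
  expect_gt(nrow(out$log), 0)

  # already balanced model is a fixed point with an empty log
  out0 <- fw_adjust_diet(fw_example_web())
  expect_identical(nrow(out0$log), 0L)
  expect_equal(out0$model$diet, fw_example_web()$diet)
})

test_that("two predators sharing an over-consumed prey are reduced together", {
  g <- data.frame(name = c("det", "algae", "prey", "p1", "p2"),
                  type = c("detritus", rep("producer", 1), rep("consumer", 3)),
                  B = c(5, 50, 2, 3, 1), PB = c(NA, 30, 2, 1, 1),
                  QB = c(NA, NA, 10, 6, 6), UC = c(NA, NA, 0.2, 0.2, 0.2))
  d <- matrix(0, 5, 5)
  d[2, 3] <- 1                       # prey eats algae
  d[3, 4] <- 0.5; d[2, 4] <- 0.5     # p1: half prey half algae
  d[3, 5] <- 0.5; d[2, 5] <- 0.5     # p2 likewise
  m <- fw_model(g, d)
  b0 <- fw_balance(m)
  expect_gt(b0$model$groups$EE[3], 1)   # prey over-consumed
  out <- fw_adjust_diet(m)
  expect_true(out$balanced)
  # both predator columns were reduced on the shared prey
  expect_lt(out$model$diet[3, 4], 0.5)
  expect_lt(out$model$diet[3, 5], 0.5)
  expect_true(all(c("p1", "p2") %in% out$log$predator))
})

test_that("conservation: total predation equals in-system consumption", {
  for (s in c(3, 17)) {
    w <- fw_generate(fw_recipe(seed = s))$model
    b <- fw_balance(w)
    lhs <- sum(b$budget$predation)
    rhs <- sum(b$budget$Q * (1 - w$import_fraction))
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})
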