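# Small fixture webs built in code.

# isolated predator-prey pair: both impact shares are 1
pair_web <- function() {
  g <- data.frame(name = c("prey", "pred"),
                  type = c("producer", "consumer"),
                  B = c(10, 1), PB = c(10, 2), QB = c(NA, 5),
                  UC = c(NA, 0.2))
  d <- matrix(c(0, 0, 1, 0), 2, 2)
  fw_model(g, d)
}

# base model whose herbivore sits at EE = 0.95, one predator above it:
# perturbing QB alone moves EE_herb across 1 at a known threshold
mc_fixture <- function() {
  g <- data.frame(name = c("phyto", "herb", "carn"),
                  type = c("producer", "consumer", "consumer"),
                  B = c(20, 10, 1), PB = c(10, 2, 1),
                  QB = c(NA, 5, 19), UC = c(NA, 0.2, 0.2))
  d <- matrix(0, 3, 3)
  d[1, 2] <- 1
  d[2, 3] <- 1
  fw_model(g, d)
}

# truncated web whose top consumer (fractional TL 3.2) has no predators:
# discrete level IV receives inflow but passes nothing upward
truncated_web <- function() {
  g <- data.frame(
    name = c("detritus", "producer", "grazer", "specialist", "mixed"),
    type = c("detritus", "producer", "consumer", "consumer", "consumer"),
    B = c(50, 100, 5, 0.5, 0.2),
    PB = c(NA, 30, 4, 2, 1.5),
    QB = c(NA, NA, 20, 8, 6),
    UC = c(NA, NA, 0.2, 0.2, 0.2))
  d <- matrix(0, 5, 5)
  d[2, 3] <- 1          # grazer eats producer -> TL 2
  d[3, 4] <- 1          # specialist eats grazer -> TL 3
  d[3, 5] <- 0.8        # mixed: 80% TL-2 grazer
  d[4, 5] <- 0.2        #        20% TL-3 specialist -> TL 3.2
  fw_model(g, d)
}

# random acyclic web with n groups (1 detritus, 1-2 producers, rest
# consumers feeding strictly downward); always solvable
random_acyclic_web <- function(n, seed) {
  set.seed(seed)
  n_prod <- sample(1:2, 1)
  types <- c("detritus", rep("producer", n_prod),
             rep("consumer", n - 1 - n_prod))
  g <- data.frame(name = paste0("g", seq_len(n)), type = types,
                  B = NA, PB = NA, QB = NA, UC = NA,
                  stringsAsFactors = FALSE)
  g$B <- c(10, runif(n_prod, 5, 20), runif(n - 1 - n_prod, 0.2, 5))
  g$PB[g$type == "producer"] <- runif(n_prod, 20, 60)
  cons <- which(g$type == "consumer")
  g$PB[cons] <- runif(length(cons), 0.5, 4)
  ge <- runif(length(cons), 0.12, 0.28)
  g$QB[cons] <- g$PB[cons] / ge
  g$UC[cons] <- 0.2
  d <- matrix(0, n, n)
  for (j in cons) {
    pool <- seq_len(j - 1)
    k <- sample(seq_along(pool), 1)
    prey <- sample(pool, k)
    w <- rgamma(k, 2)
    d[prey, j] <- w / sum(w)
  }
  # shrink consumer biomass until every EE <= 0.95
  m <- fw_model(g, d)
  for (it in 1:50) {
    b <- suppressWarnings(fw_balance(m))
    ee <- b$model$groups$EE[m$groups$type != "detritus"]
    if (all(ee <= 0.95)) break
    m$groups$B[m$groups$type == "consumer"] <-
      m$groups$B[m$groups$type == "consumer"] * 0.6
  }
  m
}

expect_no_violations <- function(model) {
  expect_identical(nrow(fw_validate(model)), 0L)
}
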