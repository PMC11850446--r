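#' Recipe for a synthetic river food web
#'
#' Describes the guild structure and statistical parameters of a
#' generated web, emulating a subtropical river community: detritus and
#' producer pools (phytoplankton, periphyton, macrophytes), invertebrate
#' guilds (zooplankton, gastropods, bivalves, shrimps, insect larvae),
#' fish feeding guilds (detritivore through piscivore) and an apex
#' reptile (softshell turtle), with a biomass pyramid, physiologically
#' plausible gross efficiencies, and Dirichlet-drawn diets restricted to
#' lower trophic guild levels.
#'
#' @param guilds data.frame with columns `name`, `type`, `level` (guild
#'   level: 1 producers/detritus, 2 primary consumers, ...); the default
#'   is a 16-group roster spanning levels 1-5.
#' @param biomass_base producer-level biomass scale (g/m2).
#' @param biomass_decay multiplicative biomass decline per guild level,
#'   in (0, 1).
#' @param ge_range target gross-efficiency interval (default (0.1, 0.3)).
#' @param uc_default unassimilated fractions: 0.4 for detritivores and
#'   herbivores, 0.2 otherwise (named vector `low`/`high` trophic).
#' @param diet_concentration Dirichlet concentration controlling diet
#'   evenness (larger = more even, broader diets).
#' @param demand_cap maximum fraction of any prey's production that
#'   generated predators may consume (default 0.9, guaranteeing every
#'   ground-truth EE < 1).
#' @param seed integer; all randomness derives from it.
#' @return list of class `fw_recipe`.
#' @export
fw_recipe <- function(guilds = default_guilds(),
                      biomass_base = 10,
                      biomass_decay = 0.5,
                      ge_range = c(0.1, 0.3),
                      uc_default = c(low = 0.4, high = 0.2),
                      diet_concentration = 2,
                      demand_cap = 0.9,
                      detritus_use = 0.8,
                      seed = 1) {
  stopifnot(is.data.frame(guilds),
            all(c("name", "type", "level") %in% names(guilds)),
            biomass_decay > 0, biomass_decay < 1,
            ge_range[1] > 0, ge_range[2] < 1, ge_range[1] < ge_range[2],
            demand_cap > 0, demand_cap <= 0.95)
  stopifnot(detritus_use >= 0, detritus_use < demand_cap)
  structure(list(guilds = guilds, biomass_base = biomass_base,
                 biomass_decay = biomass_decay, ge_range = ge_range,
                 uc_default = uc_default,
                 diet_concentration = diet_concentration,
                 demand_cap = demand_cap, detritus_use = detritus_use,
                 seed = seed),
            class = "fw_recipe")
}

# Default 16-group roster: detritus + 3 producers + 5 invertebrate guilds
# + 6 fish guilds + apex softshell turtle.
default_guilds <- function() {
  data.frame(
    name = c("detritus", "phytoplankton", "periphyton", "macrophytes",
             "zooplankton", "gastropods", "bivalves", "shrimps",
             "insect larvae", "detritivorous fish", "herbivorous fish",
             "zooplanktivorous fish", "omnivorous fish",
             "insectivorous fish", "piscivorous fish",
             "softshell turtle"),
    type = c("detritus", rep("producer", 3), rep("consumer", 12)),
    level = c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 2, 3, 3, 3, 4, 5),
    stringsAsFactors = FALSE)
}

#' Generate a balanced synthetic food web
#'
#' Builds a model from a recipe by forward construction so the true
#' ecotrophic efficiencies are known exactly: producer biomasses follow
#' the pyramid, each consumer draws a gross efficiency in `ge_range` and
#' a Dirichlet diet over guilds at strictly lower levels (level-2
#' consumers may also feed on detritus), and consumer biomasses are
#' assigned in increasing guild-level order, capped so cumulative demand
#' on every prey never exceeds `demand_cap` of its production. The
#' returned ground-truth EEs (demand / production) are therefore all
#' below `demand_cap`, and [fw_balance()] must recover them.
#'
#' @param recipe an `fw_recipe`.
#' @return list with `model` (an `fw_model`, EE unset for solving) and
#'   `truth` (named vector of ground-truth EEs for living groups).
#' @export
#' @examples
#' w <- fw_generate(fw_recipe(seed = 7))
#' all.equal(unname(fw_balance(w$model)$model$groups$EE[-1]),
#'           unname(w$truth), tolerance = 1e-12)
fw_generate <- function(recipe) {
  stopifnot(inherits(recipe, "fw_recipe"))
  set.seed(recipe$seed)
  gl <- recipe$guilds
  n <- nrow(gl)
  lev <- gl$level
  type <- gl$type
  cons <- which(type == "consumer")
  prod <- which(type == "producer")
  det <- which(type == "detritus")
  if (!length(prod)) stop("recipe needs at least one producer")

  B <- numeric(n)
  PB <- rep(NA_real_, n)
  QB <- rep(NA_real_, n)
  UC <- rep(NA_real_, n)
  # producers: pyramid base with lognormal scatter, high turnover
  B[prod] <- recipe$biomass_base * stats::rlnorm(length(prod), 0, 0.4)
  PB[prod] <- stats::runif(length(prod), 20, 60)
  B[det] <- recipe$biomass_base
  P <- numeric(n)
  P[prod] <- B[prod] * PB[prod]

  diet <- matrix(0, n, n, dimnames = list(gl$name, gl$name))
  demand <- numeric(n)          # cumulative predation on each group
  avail <- numeric(n)           # demand_cap * production, set when known
  avail[prod] <- recipe$demand_cap * P[prod]
  # detritus receives at least the producers' unutilized production;
  # a conservative availability floor keeps detritivory feasible
  avail[det] <- recipe$demand_cap * 0.5 * sum(P[prod])

  for (j in cons[order(lev[cons])]) {
    lowtroph <- lev[j] <= 2
    UC[j] <- unname(recipe$uc_default[if (lowtroph) "low" else "high"])
    ge <- stats::runif(1, recipe$ge_range[1] + 0.02,
                       recipe$ge_range[2] - 0.02)
    PB[j] <- stats::runif(1, 0.5, 3) * (1 + 2 * lowtroph)
    QB[j] <- PB[j] / ge
    # prey pool: strictly lower guild levels; detritus only for level 2
    pool <- which(lev < lev[j] & seq_len(n) != j &
                    (type != "detritus" | lev[j] == 2))
    pool <- pool[avail[pool] - demand[pool] > 0]
    if (!length(pool))
      stop("infeasible recipe: no prey with spare production for '",
           gl$name[j], "' — lower QB or raise biomass_decay")
    k <- min(length(pool), max(2, stats::rbinom(1, length(pool), 0.7)))
    pool <- sort(sample(pool, k))
    w <- stats::rgamma(k, shape = recipe$diet_concentration, rate = 1)
    w <- w / sum(w)
    # detritivorous guilds feed predominantly on detritus, sustaining the
    # detrital recycling loop typical of subtropical river webs
    if (grepl("detritiv", gl$name[j]) && any(pool %in% det)) {
      dshare <- stats::runif(1, 0.75, 0.9)
      isdet <- pool %in% det
      w[!isdet] <- w[!isdet] / sum(w[!isdet]) * (1 - dshare)
      w[isdet] <- dshare / sum(isdet)
    } else if (any(pool %in% det)) {
      # filter- and collector-feeding guilds take a substantial
      # detrital/seston supplement
      isdet <- pool %in% det
      dshare <- stats::runif(1, 0.25, 0.5)
      w[!isdet] <- w[!isdet] / sum(w[!isdet]) * (1 - dshare)
      w[isdet] <- dshare / sum(isdet)
    }
    diet[pool, j] <- w
    # biomass: pyramid target, capped by spare production of every prey
    target <- recipe$biomass_base * recipe$biomass_decay^(lev[j] - 1) *
      stats::rlnorm(1, 0, 0.3)
    cap <- min((avail[pool] - demand[pool]) / (QB[j] * diet[pool, j]))
    B[j] <- min(target, 0.95 * cap)
    if (B[j] <= 0)
      stop("infeasible recipe: demand cap unreachable for '", gl$name[j],
           "' — lower QB or raise biomass_decay")
    demand <- demand + B[j] * QB[j] * diet[, j]
    P[j] <- B[j] * PB[j]
    avail[j] <- recipe$demand_cap * P[j]
  }

  # scale detritus feeders up until the detrital pool is substantially
  # utilized (benthic detritivores dominate real river webs), keeping
  # every prey's cumulative demand below the cap
  detfeed <- cons[colSums(diet[det, cons, drop = FALSE]) > 0]
  if (length(detfeed) && recipe$detritus_use > 0) {
    for (pass in 1:6) {
      Qv <- B * ifelse(is.na(QB), 0, QB)
      demand <- as.vector(diet %*% Qv)
      EEliv <- ifelse(P > 0, demand / P, 0)
      D_in <- sum((1 - EEliv[cons]) * P[cons]) +
        sum((1 - EEliv[prod]) * P[prod]) +
        sum(UC[cons] * Qv[cons], na.rm = TRUE)
      Q_det <- sum(Qv[detfeed] * colSums(diet[det, detfeed, drop = FALSE]))
      if (Q_det <= 0) break
      f <- recipe$detritus_use * D_in / Q_det
      # cap: scaled demand on every living prey stays within demand_cap
      extra <- as.vector(diet[, detfeed, drop = FALSE] %*% Qv[detfeed])
      liv <- c(prod, setdiff(cons, detfeed))
      bind <- liv[extra[liv] > 0]
      if (length(bind))
        f <- min(f, min((recipe$demand_cap * P[bind] -
                           (demand[bind] - extra[bind])) / extra[bind]))
      # self- and mutual predation among detritus feeders scales with
      # them, so only non-detfeed prey constrain the factor
      f <- max(f, 1e-6)
      if (abs(f - 1) < 0.02) break
      B[detfeed] <- B[detfeed] * f
      P[detfeed] <- B[detfeed] * PB[detfeed]
    }
    Qv <- B * ifelse(is.na(QB), 0, QB)
    demand <- as.vector(diet %*% Qv)
  }

  groups <- data.frame(name = gl$name, type = type, B = B, PB = PB,
                       QB = QB, UC = UC, Y = 0, NM = 0, BA = 0,
                       stringsAsFactors = FALSE)
  groups$PB[det] <- NA
  groups$B[det] <- B[det]
  model <- fw_model(groups, diet,
                    metadata = list(site = "synthetic river web",
                                    seed = recipe$seed))
  living <- which(type != "detritus")
  truth <- stats::setNames(demand[living] / P[living], gl$name[living])
  list(model = model, truth = truth)
}

#' Apply a disturbance scenario to a food web
#'
#' Three stylized degradation modes observed along polluted subtropical
#' rivers:
#' \describe{
#'   \item{industrial}{water-pollution collapse of the upper food web:
#'     removes every consumer with fractional trophic level above
#'     `2 + intensity` and scales pollution-tolerant detritivore biomass
#'     up by `1 + 4 * intensity` (capped so detritus consumption stays
#'     within the detritus inflow).}
#'   \item{overfishing}{adds catch `Y = intensity * P` to the
#'     top-quartile trophic-level groups.}
#'   \item{invasion}{inserts a high-biomass exotic consumer at trophic
#'     level 2 with no predators, feeding on producers' spare (unutilized)
#'     production, so its own production is entirely redundant (EE 0).}
#' }
#' `intensity = 0` returns the model unchanged.
#'
#' @param model a balanced `fw_model`.
#' @param scenario `"industrial"`, `"overfishing"` or `"invasion"`.
#' @param intensity disturbance strength in `[0, 1]`.
#' @return the degraded `fw_model`.
#' @export
fw_degrade <- function(model, scenario = c("industrial", "overfishing",
                                           "invasion"),
                       intensity = 0.5) {
  stopifnot(inherits(model, "fw_model"),
            intensity >= 0, intensity <= 1)
  scenario <- match.arg(scenario)
  if (intensity == 0) return(model)
  TL <- fw_trophic_levels(model)
  g <- model$groups
  bal <- fw_balance(model)

  if (scenario == "industrial") {
    # pollution truncates the web from the top: the cutoff descends from
    # the pristine web's maximum consumer level to 3 at full intensity
    # (a fully impacted zone keeps nothing above trophic level 3)
    tl_max <- max(TL[g$type == "consumer"])
    cutoff <- tl_max - intensity * max(tl_max - 3, 0)
    drop <- which(g$type == "consumer" & TL > cutoff)
    if (length(drop) == sum(g$type == "consumer"))
      stop("scenario removes all consumers")
    keep <- setdiff(seq_len(nrow(g)), drop)
    # consumers left with no surviving prey starve out too
    repeat {
      diet2 <- model$diet[keep, keep, drop = FALSE]
      starved <- keep[g$type[keep] == "consumer" & colSums(diet2) +
                        model$import_fraction[keep] == 0]
      if (!length(starved)) break
      keep <- setdiff(keep, starved)
      if (!any(g$type[keep] == "consumer"))
        stop("scenario removes all consumers")
    }
    g2 <- g[keep, , drop = FALSE]
    imp2 <- model$import_fraction[keep]
    # renormalize surviving predators' diets over surviving prey
    for (j in seq_len(ncol(diet2))) {
      s <- sum(diet2[, j]) + imp2[j]
      if (s > 0) {
        diet2[, j] <- diet2[, j] / s
        imp2[j] <- imp2[j] / s
      }
    }
    m2 <- fw_model(g2, diet2, imp2, metadata = model$metadata)
    # boost tolerant detritivores, capped so the extra demand stays
    # within every prey's spare production (and detritus availability)
    detrows <- which(g2$type == "detritus")
    detfeed <- which(g2$type == "consumer" &
                       colSums(diet2[detrows, , drop = FALSE]) > 0.3)
    if (length(detfeed) && intensity > 0) {
      boost <- 1 + 4 * intensity
      b2 <- suppressWarnings(fw_balance(m2))
      extra <- rowSums(sapply(detfeed, function(j)
        (boost - 1) * m2$groups$B[j] * m2$groups$QB[j] * diet2[, j]))
      spare <- numeric(nrow(g2))
      liv2 <- g2$type != "detritus"
      spare[liv2] <- pmax((0.9 - b2$model$groups$EE[liv2]) *
                            b2$budget$P[liv2], 0)
      spare[detrows] <- max(0.9 * b2$detritus$inflow -
                              b2$detritus$outflow, 0)
      binding <- extra > 0
      f <- min(1, if (any(binding)) min(spare[binding] / extra[binding])
               else 1)
      m2$groups$B[detfeed] <- m2$groups$B[detfeed] * (1 + (boost - 1) * f)
    }
    m2
  } else if (scenario == "overfishing") {
    consTL <- TL[g$type == "consumer"]
    thresh <- stats::quantile(consTL, 0.75)
    top <- which(g$type == "consumer" & TL >= thresh)
    P <- bal$budget$P
    model$groups$Y[top] <- ifelse(is.na(g$Y[top]), 0, g$Y[top]) +
      intensity * P[top]
    model
  } else {
    prod <- which(g$type == "producer")
    spare <- pmax((1 - bal$model$groups$EE[prod]) * bal$budget$P[prod], 0)
    if (sum(spare) <= 0) stop("no spare producer production to invade")
    w <- spare / sum(spare)
    living_B <- sum(g$B[g$type != "detritus"], na.rm = TRUE)
    QBi <- 30
    PBi <- 6
    UCi <- 0.4
    # biomass scaled to intensity but capped at 90% of spare production
    Bi <- min(intensity * 0.5 * living_B,
              0.9 * sum(spare) / QBi)
    n <- nrow(g)
    g2 <- rbind(g, data.frame(name = "exotic invader", type = "consumer",
                              B = Bi, PB = PBi, QB = QBi, EE = NA,
                              UC = UCi, Y = 0, NM = 0, BA = 0, R = NA,
                              detritus_import = NA))
    diet2 <- rbind(cbind(model$diet, 0), 0)
    diet2[prod, n + 1] <- w
    fw_model(g2, diet2, c(model$import_fraction, 0),
             metadata = model$metadata)
  }
}
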