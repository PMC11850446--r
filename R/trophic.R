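#' Fractional trophic levels
#'
#' Producers and detritus sit at trophic level 1 by definition; a
#' consumer's level is one plus the diet-weighted mean level of its prey,
#' \deqn{TL_j = 1 + \sum_i DC_{ij} TL_i,}
#' solved as a linear system so that diet cycles (including cannibalism)
#' are handled exactly. Diet imported from outside the system contributes
#' at level 1.
#'
#' @param model an `fw_model` with a valid diet matrix.
#' @return named numeric vector of trophic levels (>= 1).
#' @export
#' @examples
#' fw_trophic_levels(fw_example_web())
fw_trophic_levels <- function(model) {
  stopifnot(inherits(model, "fw_model"))
  g <- model$groups
  n <- nrow(g)
  TL <- rep(1, n)
  cons <- which(g$type == "consumer" &
                  (colSums(model$diet) + model$import_fraction) > 0)
  if (length(cons)) {
    # (I - A) TL_cons = 1 + contribution of non-consumer (level-1) prey
    A <- t(model$diet[cons, cons, drop = FALSE])
    base <- which(!(seq_len(n) %in% cons))
    rhs <- 1 + as.vector(t(model$diet[base, cons, drop = FALSE]) %*%
                           TL[base]) + model$import_fraction[cons]
    M <- diag(length(cons)) - A
    if (abs(det(M)) < 1e-12)
      stop("singular trophic-level system (self-sustaining diet loop) ",
           "involving: ", paste(g$name[cons], collapse = ", "))
    TL[cons] <- solve(M, rhs)
  }
  stats::setNames(TL, g$name)
}

#' Omnivory indices
#'
#' A consumer's omnivory index is the diet-weighted variance of its prey
#' trophic levels about the consumer's own level minus one:
#' \deqn{OI_j = \sum_i DC_{ij} (TL_i - (TL_j - 1))^2.}
#' The system omnivory index (SOI) is the consumption-weighted average of
#' consumer OIs with logarithmic weights,
#' `SOI = sum(OI_j log Q_j) / sum(log Q_j)` over consumers with `Q > 1`.
#'
#' @param balanced an `fw_balanced` (consumption weights come from it).
#' @param TL optional precomputed trophic levels.
#' @return list with `OI` (per-consumer vector) and `SOI`.
#' @export
fw_omnivory <- function(balanced, TL = NULL) {
  stopifnot(inherits(balanced, "fw_balanced"))
  model <- balanced$model
  if (is.null(TL)) TL <- fw_trophic_levels(model)
  g <- model$groups
  cons <- which(g$type == "consumer")
  OI <- stats::setNames(numeric(length(cons)), g$name[cons])
  for (k in seq_along(cons)) {
    j <- cons[k]
    w <- model$diet[, j]
    imp <- model$import_fraction[j]
    if (sum(w) + imp == 0) next
    mu <- TL[j] - 1
    OI[k] <- sum(w * (TL - mu)^2) + imp * (1 - mu)^2
  }
  Q <- balanced$budget$Q[cons]
  use <- Q > 1
  SOI <- if (any(use)) sum(OI[use] * log(Q[use])) / sum(log(Q[use])) else 0
  list(OI = OI, SOI = SOI)
}

# Per-group distribution of trophic activity over discrete levels,
# split by level-I origin (producer vs detritus). Row g, column k of each
# matrix = fraction of group g's intake arriving via diet paths of length
# k - 1 from a level-I source of that origin. Producers and detritus are
# their own level-I sources. Imported diet counts as producer-origin
# level-I material.
level_distribution <- function(model, max_level = 8) {
  g <- model$groups
  n <- nrow(g)
  K <- max_level
  Pd <- matrix(0, n, K, dimnames = list(g$name, NULL))
  Dd <- matrix(0, n, K)
  prod <- g$type == "producer"
  det <- g$type == "detritus"
  cons <- which(g$type == "consumer")
  Pd[prod, 1] <- 1
  Dd[det, 1] <- 1
  if (length(cons)) {
    DC <- model$diet
    for (k in 2:K) {
      Pd[cons, k] <- as.vector(crossprod(DC[, cons, drop = FALSE],
                                         Pd[, k - 1]))
      Dd[cons, k] <- as.vector(crossprod(DC[, cons, drop = FALSE],
                                         Dd[, k - 1]))
      if (k == 2) Pd[cons, 2] <- Pd[cons, 2] + model$import_fraction[cons]
    }
  }
  total <- rowSums(Pd) + rowSums(Dd)
  list(producer = Pd, detritus = Dd,
       remainder = stats::setNames(pmax(1 - total, 0), g$name))
}

#' Lindeman spine: flows aggregated onto discrete trophic levels
#'
#' Apportions every group's consumption, respiration, exports/catch and
#' detritus flow onto the discrete trophic levels I, II, ... by the
#' canonical trophic aggregation: a consumer's intake at level k + 1 is the
#' share of its diet consisting of material at level k, applied
#' recursively, so a group with fractional level 2.3 acts 70% at level II
#' and 30% at level III. Producers and detritus sit wholly at level I. The
#' chains originating from producers and from detritus are kept separate
#' and also combined; per-level transfer efficiency is
#' `TE_k = (flow to level k+1 + exports and catch at k) / inflow at k`.
#'
#' Diet cycles route some material through arbitrarily long paths; mass
#' beyond `max_level` is reported as `remainder` (with a warning above
#' `1e-6` of total consumption).
#'
#' @param balanced an `fw_balanced`.
#' @param max_level level cap (default 8).
#' @return Object of class `fw_spine`: list of per-chain data.frames
#'   (`combined`, `producer`, `detritus`; columns level, inflow, to_next,
#'   export_catch, respiration, to_detritus, TE), plus the per-group
#'   level distribution and the unapportioned remainder.
#' @export
#' @examples
#' sp <- fw_lindeman(fw_balance(fw_example_web()))
#' sp$combined
fw_lindeman <- function(balanced, max_level = 8) {
  stopifnot(inherits(balanced, "fw_balanced"))
  model <- balanced$model
  b <- balanced$budget
  g <- model$groups
  K <- max_level
  dist <- level_distribution(model, K)
  rem_mass <- sum(dist$remainder * b$Q)
  if (rem_mass > 1e-6 * max(sum(b$Q), 1))
    warning(sprintf(
      "level cap %d truncates %.3g g/m2/yr of cyclic consumption", K,
      rem_mass))

  chains <- list()
  for (orig in c("producer", "detritus")) {
    A <- dist[[orig]]
    inflow <- as.vector(crossprod(A, b$Q))        # consumer intake per level
    # level-I inflow: the chain's source material entering the system
    if (orig == "producer") {
      prod <- g$type == "producer"
      imp_cons <- sum(b$Q * model$import_fraction)
      inflow[1] <- sum(b$P[prod]) + sum(b$R[prod]) + imp_cons
    } else {
      inflow[1] <- balanced$detritus$inflow
    }
    # each group's boundary flows are apportioned by its level shares;
    # producers/detritus already carry weight 1 at level I of their chain
    out_w <- A
    expc <- as.vector(crossprod(out_w, b$export))
    resp <- as.vector(crossprod(out_w, b$R))
    ftd <- as.vector(crossprod(out_w, b$flow_to_detritus))
    to_next <- c(inflow[-1], 0)
    TE <- ifelse(inflow > 0, 100 * (to_next + expc) / inflow, NA_real_)
    chains[[orig]] <- data.frame(
      level = seq_len(K), inflow = inflow, to_next = to_next,
      export_catch = expc, respiration = resp, to_detritus = ftd, TE = TE)
  }
  comb <- chains$producer
  for (col in c("inflow", "to_next", "export_catch", "respiration",
                "to_detritus"))
    comb[[col]] <- chains$producer[[col]] + chains$detritus[[col]]
  comb$TE <- ifelse(comb$inflow > 0,
                    100 * (comb$to_next + comb$export_catch) / comb$inflow,
                    NA_real_)
  structure(list(combined = comb, producer = chains$producer,
                 detritus = chains$detritus,
                 distribution = dist, remainder = dist$remainder),
            class = "fw_spine")
}

#' @export
print.fw_spine <- function(x, ...) {
  cat("Lindeman spine (combined producer + detritus chains)\n")
  show <- x$combined[x$combined$inflow > 0 | x$combined$level <= 4, ]
  print(show, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-level transfer efficiencies and their mean
#'
#' Reads the transfer efficiency of each discrete level from a Lindeman
#' spine and summarizes levels II-IV (configurable) by the geometric mean
#' (the convention for "mean transfer efficiency"; arithmetic available).
#' Levels with no inflow have undefined TE and are excluded from the
#' mean; TE exactly 0 forces a geometric mean of 0 when included.
#'
#' @param spine an `fw_spine`.
#' @param levels integer levels entering the mean (default `2:4`).
#' @param mean_type `"geometric"` or `"arithmetic"`.
#' @return list with per-chain TE vectors (`TE_combined`, `TE_producer`,
#'   `TE_detritus`, in %) and mean TEs (`mean_combined`, `mean_producer`,
#'   `mean_detritus`).
#' @export
fw_transfer_efficiency <- function(spine, levels = 2:4,
                                   mean_type = c("geometric",
                                                 "arithmetic")) {
  stopifnot(inherits(spine, "fw_spine"))
  mean_type <- match.arg(mean_type)
  mfun <- function(te) {
    te <- te[!is.na(te)]
    if (!length(te)) return(NA_real_)
    if (mean_type == "arithmetic") mean(te)
    else if (any(te == 0)) 0 else exp(mean(log(te)))
  }
  pick <- function(chain) {
    te <- chain$TE
    stats::setNames(te, paste0("TL_", chain$level))
  }
  out <- list(TE_combined = pick(spine$combined),
              TE_producer = pick(spine$producer),
              TE_detritus = pick(spine$detritus))
  out$mean_combined <- mfun(spine$combined$TE[levels])
  out$mean_producer <- mfun(spine$producer$TE[levels])
  out$mean_detritus <- mfun(spine$detritus$TE[levels])
  out
}
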