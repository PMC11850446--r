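#' Solve the trophic mass balance
#'
#' Solves, for every living group i, the production balance
#' \deqn{P/B_i B_i EE_i = Y_i + \sum_j B_j Q/B_j DC_{ij} + NM_i + BA_i}
#' together with the consumer energy balance
#' \deqn{Q_i = P_i + R_i + UC_i Q_i.}
#' Each living group must have exactly one unknown among `{B, EE}`. The
#' unknown biomasses form a linear system (their equations are the ones
#' whose EE is given); unknown ecotrophic efficiencies then follow
#' directly. Solved `EE > 1` is returned and flagged, never clamped: the
#' standard balancing workflow inspects the imbalance and adjusts inputs
#' (see [fw_adjust_diet()]).
#'
#' Consumption flows are `T[i, j] = B_j * QB_j * DC[i, j]` (prey i to
#' predator j, g/m2/yr). Producer respiration is 0 unless a measured `R`
#' was supplied. Detritus EE is derived from the detritus budget:
#' inflow is unassimilated consumption plus unutilized production plus
#' external import; outflow is consumption of detritus.
#'
#' @param model an `fw_model` passing [fw_validate()].
#' @param tol relative residual tolerance for the post-solve check.
#' @return Object of class `fw_balanced`: list with `model` (all B/EE
#'   filled), `budget` (per-group data.frame: B, P, Q, R, EE, GE,
#'   predation, flow_to_detritus, unutilized, export), `flows`
#'   (see [fw_flows()]), `detritus` (inflow components, outflow, EE per
#'   detritus pool), and `balanced` (logical: all EE <= 1).
#' @references Polovina (1984) ECOPATH; Christensen & Pauly (1992).
#' @export
#' @examples
#' b <- fw_balance(fw_example_web())
#' b$budget
fw_balance <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "fw_model"))
  g <- model$groups
  n <- nrow(g)
  living <- which(g$type != "detritus")
  cons <- which(g$type == "consumer")
  QB <- ifelse(is.na(g$QB), 0, g$QB)
  Y  <- ifelse(is.na(g$Y), 0, g$Y)
  NM <- ifelse(is.na(g$NM), 0, g$NM)
  BA <- ifelse(is.na(g$BA), 0, g$BA)
  UC <- ifelse(is.na(g$UC), 0, g$UC)
  PB <- ifelse(is.na(g$PB), 0, g$PB)
  B  <- g$B
  EE <- g$EE

  unkB <- intersect(which(is.na(B)), living)
  for (i in living)
    if (is.na(B[i]) && is.na(EE[i]))
      stop("group '", g$name[i], "': both B and EE unset")

  if (length(unkB)) {
    # equations of groups with known EE are linear in the unknown biomasses
    eqs <- intersect(which(!is.na(EE)), living)
    if (length(eqs) < length(unkB))
      stop("underdetermined system: ", length(unkB), " unknown biomasses, ",
           length(eqs), " equations with known EE")
    A <- matrix(0, length(eqs), length(unkB))
    rhs <- numeric(length(eqs))
    for (r in seq_along(eqs)) {
      i <- eqs[r]
      rhs[r] <- Y[i] + NM[i] + BA[i]
      for (j in seq_len(n)) {
        dem <- QB[j] * model$diet[i, j]
        if (dem == 0) next
        if (j %in% unkB) {
          A[r, match(j, unkB)] <- A[r, match(j, unkB)] - dem
        } else {
          rhs[r] <- rhs[r] + dem * B[j]
        }
      }
      if (i %in% unkB)
        A[r, match(i, unkB)] <- A[r, match(i, unkB)] + PB[i] * EE[i]
    }
    sol <- tryCatch(qr.solve(A, rhs),
                    error = function(e)
                      stop("singular mass-balance system for group(s): ",
                           paste(g$name[unkB], collapse = ", "),
                           call. = FALSE))
    if (any(sol < 0))
      stop("negative solved biomass for group(s): ",
           paste(g$name[unkB][sol < 0], collapse = ", "))
    B[unkB] <- sol
  }

  # consumption flows and predation mortality
  Tm <- sweep(model$diet, 2, B * QB, "*")
  Tm[is.na(Tm)] <- 0
  dimnames(Tm) <- dimnames(model$diet)
  predation <- rowSums(Tm)

  P <- ifelse(g$type == "detritus", NA_real_, PB * B)
  for (i in living)
    if (is.na(EE[i])) {
      sinks <- predation[i] + Y[i] + NM[i] + BA[i]
      EE[i] <- if (P[i] > 0) sinks / P[i] else if (sinks == 0) 0 else Inf
    }

  Q <- ifelse(seq_len(n) %in% cons, B * QB, 0)
  R <- numeric(n)
  R[cons] <- Q[cons] * (1 - UC[cons]) - P[cons]
  prodR <- which(g$type == "producer" & !is.na(g$R))
  R[prodR] <- g$R[prodR]
  GE <- ifelse(Q > 0, P / Q, NA_real_)
  unutil <- ifelse(g$type == "detritus", NA_real_, (1 - EE) * P)
  ftd <- numeric(n)
  ftd[living] <- (1 - EE[living]) * P[living]
  ftd[cons] <- ftd[cons] + UC[cons] * Q[cons]

  # residual check of the production balance
  res <- abs(P[living] * EE[living] -
               (predation[living] + Y[living] + NM[living] + BA[living]))
  scale <- max(P[living], 1)
  if (any(res > tol * scale))
    warning("mass-balance residual above tolerance for: ",
            paste(g$name[living][res > tol * scale], collapse = ", "))

  model$groups$B <- B
  model$groups$EE <- EE
  det <- which(g$type == "detritus")
  det_import <- ifelse(is.na(g$detritus_import), 0, g$detritus_import)
  det_in <- sum(ftd[living]) + sum(det_import[det])
  det_out <- sum(predation[det])
  EE_det <- if (det_in > 0) det_out / det_in else if (det_out > 0) NA else 0
  if (det_in == 0 && det_out > 0)
    stop("detritus imbalance: consumption of detritus with zero inflow")
  model$groups$EE[det] <- EE_det

  budget <- data.frame(
    name = g$name, type = g$type, B = B,
    P = P, Q = Q, R = R, EE = model$groups$EE, GE = GE,
    predation = predation, flow_to_detritus = ftd,
    unutilized = unutil, export = Y + pmax(NM, 0),
    stringsAsFactors = FALSE)

  flows <- build_flows(model, budget, Tm)
  structure(list(model = model, budget = budget, flows = flows,
                 detritus = list(inflow = det_in, outflow = det_out,
                                 EE = EE_det,
                                 components = c(
                                   unassimilated = sum(UC[cons] * Q[cons]),
                                   unutilized = sum((1 - EE[living]) *
                                                      P[living]),
                                   import = sum(det_import[det]))),
                 balanced = all(model$groups$EE <= 1 + 1e-12, na.rm = TRUE)),
            class = "fw_balanced")
}

#' @export
print.fw_balanced <- function(x, ...) {
  cat("Balanced food-web model (", nrow(x$budget), " groups) — ",
      if (x$balanced) "all EE <= 1" else "IMBALANCED (some EE > 1)",
      "\n", sep = "")
  print(x$budget[, c("name", "type", "B", "P", "Q", "R", "EE", "GE")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

# Assemble the flow matrix with boundary vectors from a solved budget.
build_flows <- function(model, budget, Tm) {
  g <- model$groups
  n <- nrow(g)
  Q <- budget$Q
  det <- which(g$type == "detritus")
  det_import <- ifelse(is.na(g$detritus_import), 0, g$detritus_import)
  imports <- Q * model$import_fraction
  imports[det] <- imports[det] + det_import[det]
  # producer gross production enters the system as an external input
  prod <- which(g$type == "producer")
  imports[prod] <- imports[prod] + budget$P[prod] + budget$R[prod]
  exports <- budget$export
  structure(list(T = Tm,
                 imports = stats::setNames(imports, g$name),
                 exports = stats::setNames(exports, g$name),
                 respiration = stats::setNames(budget$R, g$name),
                 to_detritus = stats::setNames(budget$flow_to_detritus,
                                               g$name),
                 detritus_nodes = det,
                 living = which(g$type != "detritus")),
            class = "fw_flows")
}

#' Per-consumer energy budget
#'
#' From consumption `Q`, unassimilated fraction `UC`, and production `P`:
#' respiration `R = Q (1 - UC) - P`, gross efficiency `GE = P/Q`,
#' respiration/assimilation `RA = R / (Q (1 - UC))`, and
#' production/respiration `PR = P/R` (`NA` when `R = 0`). Negative `R`
#' is returned as-is — it is a diagnostic violation, not an error.
#'
#' @param Q consumption (g/m2/yr), > 0.
#' @param UC unassimilated fraction in `[0, 1)`.
#' @param P production (g/m2/yr).
#' @return list with `R`, `GE`, `RA`, `PR`.
#' @export
fw_budget <- function(Q, UC, P) {
  stopifnot(Q > 0, UC >= 0, UC < 1)
  A <- Q * (1 - UC)
  R <- A - P
  list(R = R, GE = P / Q, RA = R / A,
       PR = if (R == 0) NA_real_ else P / R)
}

#' Physiological and balance diagnostics
#'
#' Screens a solved model against the standard plausibility constraints:
#' gross efficiency in (0.1, 0.3), gross efficiency below net efficiency,
#' respiration/assimilation below 1, production/respiration below 1
#' (consumers only — producer-dominated systems violate it trivially),
#' and ecotrophic efficiency at most 1 for every group.
#'
#' @param balanced an `fw_balanced`.
#' @param ge_range plausible gross-efficiency interval.
#' @return data.frame of class `fw_diagnostics`, one row per group, with
#'   the ratio columns and logical `flag_*` columns that are `TRUE`
#'   exactly when the constraint fails.
#' @export
fw_diagnose <- function(balanced, ge_range = c(0.1, 0.3)) {
  stopifnot(inherits(balanced, "fw_balanced"))
  b <- balanced$budget
  cons <- b$type == "consumer"
  A <- ifelse(cons, b$Q * (1 - ifelse(is.na(balanced$model$groups$UC), 0,
                                      balanced$model$groups$UC)), NA)
  RA <- ifelse(cons & A > 0, b$R / A, NA)
  PR <- ifelse(cons & b$R != 0, b$P / b$R, NA)
  NE <- ifelse(cons & A > 0, b$P / A, NA)   # net efficiency
  out <- data.frame(
    name = b$name, type = b$type,
    EE = b$EE, GE = b$GE, RA = RA, PR = PR, NE = NE,
    flag_EE = !is.na(b$EE) & b$EE > 1 + 1e-12,
    flag_GE = cons & !is.na(b$GE) &
      (b$GE <= ge_range[1] | b$GE >= ge_range[2]),
    flag_GE_NE = cons & !is.na(NE) & !(b$GE < NE),
    flag_RA = cons & !is.na(RA) & !(RA < 1),
    flag_PR = cons & !is.na(PR) & !(PR < 1),
    stringsAsFactors = FALSE)
  class(out) <- c("fw_diagnostics", "data.frame")
  out
}

#' Iterative diet adjustment towards mass balance
#'
#' Implements the standard balancing step for over-consumed prey: for each
#' prey i with `EE_i > 1`, every positive diet entry `DC[i, j]` is reduced
#' by the factor `1 - step * overshoot_i` with
#' `overshoot_i = min(1, (EE_i - 1)/EE_i)`, and the freed diet fraction is
#' redistributed proportionally among predator j's other prey (to detritus
#' when there is none). Iterates until every `EE <= 1` or `max_iter` is
#' reached.
#'
#' The overshoot is measured against a rebalancing target marginally
#' below 1 (default 0.999): aiming at exactly 1 would make EE approach 1
#' asymptotically from above without ever reaching it, whereas a target
#' just below 1 crosses the balance threshold in finitely many steps.
#'
#' @param model an `fw_model` that solves (possibly imbalanced).
#' @param max_iter iteration cap (default 100).
#' @param step fractional reduction per iteration (default 0.1).
#' @param target ecotrophic efficiency aimed for on over-consumed prey.
#' @return list with `model` (adjusted), `balanced` (logical), `iterations`,
#'   and `log` (data.frame of every diet-entry change: iteration, prey,
#'   predator, old, new).
#' @export
fw_adjust_diet <- function(model, max_iter = 100, step = 0.1,
                           target = 1 - 1e-3) {
  stopifnot(inherits(model, "fw_model"))
  g <- model$groups
  det <- which(g$type == "detritus")
  log <- list()
  bal <- fw_balance(model)
  it <- 0L
  while (!bal$balanced && it < max_iter) {
    it <- it + 1L
    EE <- bal$model$groups$EE
    over <- which(g$type != "detritus" & !is.na(EE) & EE > 1 + 1e-12)
    if (!length(over)) break
    for (i in over) {
      shoot <- min(1, (EE[i] - target) / EE[i])
      preds <- which(model$diet[i, ] > 0)
      for (j in preds) {
        old <- model$diet[i, j]
        new <- old * (1 - step * shoot)
        freed <- old - new
        model$diet[i, j] <- new
        others <- setdiff(which(model$diet[, j] > 0), i)
        if (length(others)) {
          w <- model$diet[others, j] / sum(model$diet[others, j])
          model$diet[others, j] <- model$diet[others, j] + freed * w
        } else if (length(det)) {
          model$diet[det[1], j] <- model$diet[det[1], j] + freed
        } else {
          model$import_fraction[j] <- model$import_fraction[j] + freed
        }
        log[[length(log) + 1L]] <- data.frame(
          iteration = it, prey = g$name[i], predator = g$name[j],
          old = old, new = new)
      }
    }
    bal <- fw_balance(model)
  }
  list(model = model, balanced = bal$balanced, iterations = it,
       log = if (length(log)) do.call(rbind, log)
             else data.frame(iteration = integer(), prey = character(),
                             predator = character(), old = numeric(),
                             new = numeric()))
}
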