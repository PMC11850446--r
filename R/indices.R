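#' Flow accounts of a balanced model
#'
#' The flow matrix and boundary vectors underlying all network indices:
#' `T[i, j] = B_j QB_j DC[i, j]` (consumption of prey i by predator j),
#' imports (imported diet, detritus import, and producer gross production
#' entering the system), exports (catch plus positive net migration),
#' respiration, and flows into detritus.
#'
#' @param balanced an `fw_balanced`.
#' @return the `fw_flows` object carried by the balanced model.
#' @export
fw_flows <- function(balanced) {
  stopifnot(inherits(balanced, "fw_balanced"))
  balanced$flows
}

#' Whole-system summary statistics
#'
#' The flow sums and maturity ratios of the standard network-analysis
#' table: sum of all consumption, respiration (TR), back-flows to
#' detritus, total system throughput
#' (TST = consumption + exports + respiration + flows to detritus), total
#' production, total net primary production (TPP), net system production
#' (NSP = TPP - TR), total biomass excluding detritus (TB), and the
#' ratios TPP/TR, TPP/TB and TB/TST — all computed from unrounded values.
#'
#' @param balanced an `fw_balanced`.
#' @return named list of class `fw_stats` (extended by [fw_statistics()]).
#' @export
fw_summary_stats <- function(balanced) {
  stopifnot(inherits(balanced, "fw_balanced"))
  b <- balanced$budget
  fl <- balanced$flows
  cons <- b$type == "consumer"
  living <- b$type != "detritus"
  prod <- b$type == "producer"
  sum_q <- sum(b$Q[cons])
  TR <- sum(b$R)
  ftd <- sum(b$flow_to_detritus[living])
  sum_exp <- sum(fl$exports)
  TST <- sum_q + sum_exp + TR + ftd
  TPP <- sum(b$P[prod])
  TB <- sum(b$B[living], na.rm = TRUE)
  out <- list(
    sum_consumption = sum_q,
    sum_exports = sum_exp,
    sum_respiration = TR,
    sum_to_detritus = ftd,
    TST = TST,
    sum_production = sum(b$P[living]),
    TPP = TPP,
    NSP = TPP - TR,
    TB = TB,
    TPP_TR = if (TR > 0) TPP / TR else NA_real_,
    TPP_TB = if (TB > 0) TPP / TB else NA_real_,
    TB_TST = if (TST > 0) TB / TST else NA_real_)
  class(out) <- "fw_stats"
  out
}

#' Connectance index
#'
#' Realized fraction of possible trophic links:
#' `CI = links / (N (N - 1))` where N counts living (non-detritus) groups
#' and links are the nonzero diet entries of living consumers, including
#' their detritus-feeding links.
#'
#' @param model an `fw_model`.
#' @param count_detritus_links include links onto detritus (default TRUE).
#' @return CI, or `NA` when fewer than two living groups.
#' @export
fw_connectance <- function(model, count_detritus_links = TRUE) {
  stopifnot(inherits(model, "fw_model"))
  g <- model$groups
  living <- g$type != "detritus"
  N <- sum(living)
  if (N < 2) return(NA_real_)
  prey_ok <- if (count_detritus_links) rep(TRUE, nrow(g)) else living
  links <- sum(model$diet[prey_ok, living, drop = FALSE] > 0)
  links / (N * (N - 1))
}

#' Shannon diversity of biomass structure
#'
#' `H = -sum(p_i log p_i)` with `p_i` the biomass share of each living
#' group by default, or each group's share of total consumption with
#' `basis = "flow"`.
#'
#' @param balanced an `fw_balanced`.
#' @param basis `"biomass"` (default) or `"flow"`.
#' @return H (natural log units), `NA` when the chosen totals are zero.
#' @export
fw_shannon <- function(balanced, basis = c("biomass", "flow")) {
  stopifnot(inherits(balanced, "fw_balanced"))
  basis <- match.arg(basis)
  b <- balanced$budget
  living <- b$type != "detritus"
  x <- if (basis == "biomass") b$B[living] else b$Q[living]
  x <- x[!is.na(x) & x > 0]
  if (!length(x) || sum(x) == 0) return(NA_real_)
  p <- x / sum(x)
  -sum(p * log(p))
}

# Compartment inflow (throughput) vector for input-output analysis:
# internal consumption plus boundary imports.
compartment_throughput <- function(Tm, imports) {
  colSums(Tm) + imports
}

#' Finn's cycle analysis
#'
#' Input-output analysis of the flow network. With
#' `G[i, j] = T[i, j] / inflow_j` (the fraction of compartment j's inflow
#' coming from i) and the Leontief-type structure matrix
#' `L = (I - G)^-1`, the cycled part of each compartment's throughput is
#' `inflow_i (L_ii - 1) / L_ii`. Finn's cycling index is the cycled share
#' of total compartmental throughput (in %); the analysis is repeated on
#' the network with detritus compartments deleted to give the throughput
#' cycled excluding detritus and the predator cycling index. Finn's mean
#' path length is `TST / (exports + respiration)` and the
#' straight-through path lengths subtract the cycled throughput from the
#' numerator.
#'
#' @param flows an `fw_flows`.
#' @param TST total system throughput used for the path lengths
#'   (defaults to the sum consumption + exports + respiration + detritus
#'   flows recomputed from `flows`).
#' @return list of class `fw_finn`: `L`, per-compartment `cycled`,
#'   `throughput_cycled_incl`, `throughput_cycled_excl`, `FCI` (%),
#'   `predator_cycling_index` (%), `FML`, `straight_path_incl`,
#'   `straight_path_excl`.
#' @export
fw_finn <- function(flows, TST = NULL) {
  stopifnot(inherits(flows, "fw_flows"))
  Tm <- flows$T
  if (is.null(TST))
    TST <- sum(colSums(Tm)) + sum(flows$exports) + sum(flows$respiration) +
      sum(flows$to_detritus)
  analyse <- function(Tm, imports) {
    thr <- compartment_throughput(Tm, imports)
    n <- nrow(Tm)
    G <- matrix(0, n, n, dimnames = dimnames(Tm))
    pos <- thr > 0
    G[, pos] <- sweep(Tm[, pos, drop = FALSE], 2, thr[pos], "/")
    L <- tryCatch(solve(diag(n) - G),
                  error = function(e)
                    stop("singular input-output structure", call. = FALSE))
    dg <- diag(L)
    cycled <- ifelse(dg > 0, thr * (dg - 1) / dg, 0)
    list(L = L, throughput = thr, cycled = cycled)
  }
  # detritus inflow: flows to detritus are its internal inflow source;
  # represent them inside T so cycles through detritus are visible
  Tfull <- Tm
  det <- flows$detritus_nodes
  if (length(det)) {
    # route each group's flow-to-detritus into the first detritus pool
    Tfull[, det[1]] <- Tfull[, det[1]] + flows$to_detritus
  }
  incl <- analyse(Tfull, flows$imports)
  tot_in <- sum(incl$throughput)
  FCI <- if (tot_in > 0) 100 * sum(incl$cycled) / tot_in else NA_real_

  keep <- setdiff(seq_len(nrow(Tm)), det)
  excl <- analyse(Tm[keep, keep, drop = FALSE], flows$imports[keep])
  tot_ex <- sum(excl$throughput)
  PCI <- if (tot_ex > 0) 100 * sum(excl$cycled) / tot_ex else NA_real_

  denom <- sum(flows$exports) + sum(flows$respiration)
  structure(list(
    L = incl$L,
    cycled = incl$cycled,
    throughput_cycled_incl = sum(incl$cycled),
    throughput_cycled_excl = sum(excl$cycled),
    FCI = FCI,
    predator_cycling_index = PCI,
    FML = if (denom > 0) TST / denom else NA_real_,
    straight_path_incl = if (denom > 0)
      (TST - sum(incl$cycled)) / denom else NA_real_,
    straight_path_excl = if (denom > 0)
      (TST - sum(excl$cycled)) / denom else NA_real_),
    class = "fw_finn")
}

#' Information indices: ascendency and development capacity
#'
#' Over the extended network (internal flows plus boundary compartments
#' for imports, exports and respiration), with `T..` the total flow:
#' ascendency
#' \deqn{A = \sum_{ij} T_{ij} \log_2 \frac{T_{ij} T_{..}}{T_{i.} T_{.j}}}
#' and development capacity
#' \deqn{C = -\sum_{ij} T_{ij} \log_2 \frac{T_{ij}}{T_{..}},}
#' both in flowbits (g/m2/yr x bits); zero flows contribute zero. The
#' ratio A/C (in %) indexes how organized the system's flow structure is
#' relative to its upper bound.
#'
#' @param flows an `fw_flows`.
#' @return list with `A`, `C`, `AC` (= 100 A/C).
#' @export
fw_information <- function(flows) {
  stopifnot(inherits(flows, "fw_flows"))
  n <- nrow(flows$T)
  # nodes: groups, import source (n+1), export sink (n+2), resp sink (n+3)
  N <- n + 3
  M <- matrix(0, N, N)
  M[seq_len(n), seq_len(n)] <- flows$T
  if (length(flows$detritus_nodes)) {
    d1 <- flows$detritus_nodes[1]
    M[seq_len(n), d1] <- M[seq_len(n), d1] + flows$to_detritus
  }
  M[n + 1, seq_len(n)] <- flows$imports
  M[seq_len(n), n + 2] <- flows$exports
  M[seq_len(n), n + 3] <- flows$respiration
  tot <- sum(M)
  if (tot <= 0) return(list(A = 0, C = 0, AC = NA_real_))
  ri <- rowSums(M)
  cj <- colSums(M)
  A <- 0; C <- 0
  idx <- which(M > 0, arr.ind = TRUE)
  t_ <- M[idx]
  A <- sum(t_ * log2(t_ * tot / (ri[idx[, 1]] * cj[idx[, 2]])))
  C <- -sum(t_ * log2(t_ / tot))
  list(A = A, C = C, AC = if (C > 0) 100 * A / C else NA_real_)
}

#' Full system-statistics suite
#'
#' Computes the complete summary table for one balanced model: flow sums,
#' maturity ratios, cycling and path-length indices, connectance, system
#' omnivory, Shannon diversity and the information indices.
#'
#' @param balanced an `fw_balanced`.
#' @param shannon_basis passed to [fw_shannon()].
#' @return named list of class `fw_stats` with every index; see
#'   [fw_stats_table()] for rendering.
#' @export
#' @examples
#' st <- fw_statistics(fw_balance(fw_example_web()))
#' st$TST
fw_statistics <- function(balanced, shannon_basis = "biomass") {
  stopifnot(inherits(balanced, "fw_balanced"))
  out <- fw_summary_stats(balanced)
  fl <- balanced$flows
  fn <- fw_finn(fl, TST = out$TST)
  info <- fw_information(fl)
  omn <- fw_omnivory(balanced)
  out$throughput_cycled_incl <- fn$throughput_cycled_incl
  out$throughput_cycled_excl <- fn$throughput_cycled_excl
  out$predator_cycling_index <- fn$predator_cycling_index
  out$FCI <- fn$FCI
  out$FML <- fn$FML
  out$straight_path_incl <- fn$straight_path_incl
  out$straight_path_excl <- fn$straight_path_excl
  out$CI <- fw_connectance(balanced$model)
  out$SOI <- omn$SOI
  out$shannon <- fw_shannon(balanced, shannon_basis)
  out$C <- info$C
  out$A <- info$A
  out$AC <- info$AC
  class(out) <- "fw_stats"
  out
}

#' @export
print.fw_stats <- function(x, ...) {
  v <- unlist(x)
  cat("System statistics:\n")
  print(data.frame(value = signif(v, 5)))
  invisible(x)
}
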