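#' Direct trophic impact matrix
#'
#' The net direct impact of group i on group j combines a positive
#' bottom-up term (prey i's share of predator j's diet) and a negative
#' top-down term (predator i's share of the total predation on prey j):
#' \deqn{q_{ij} = DC_{ji} - F_{ij},}
#' where `F[i, j] = T[j, i] / sum_k T[j, k]` is i's share of the
#' consumption of j. Detritus has no diet; for its positive term the
#' normalized inflows into detritus play the role of its "diet"
#' composition.
#'
#' @param balanced an `fw_balanced`.
#' @return n x n matrix `q`, row = impacting group, column = impacted.
#' @references Ulanowicz & Puccia (1990) Mixed trophic impacts in
#'   ecosystems.
#' @export
fw_direct_impacts <- function(balanced) {
  stopifnot(inherits(balanced, "fw_balanced"))
  model <- balanced$model
  fl <- balanced$flows
  g <- model$groups
  n <- nrow(g)
  # effective diet: consumers their DC column; detritus its normalized inflow
  D <- model$diet
  for (d in which(g$type == "detritus")) {
    inflow <- fl$to_detritus
    s <- sum(inflow)
    if (s > 0) D[, d] <- inflow / s
  }
  # host shares: F[i, j] = predation by i on j over total predation on j
  pred_tot <- rowSums(fl$T)
  Fm <- matrix(0, n, n)
  pos <- pred_tot > 0
  Fm[, pos] <- t(sweep(fl$T[pos, , drop = FALSE], 1, pred_tot[pos], "/"))
  q <- D - Fm
  dimnames(q) <- list(impacting = g$name, impacted = g$name)
  q
}

#' Mixed trophic impacts
#'
#' Sums the direct impacts over all interaction paths of length >= 1:
#' \deqn{M = (I - q)^{-1} - I,}
#' the closed form of the Neumann series `q + q^2 + q^3 + ...`, which
#' converges exactly when the spectral radius of `q` is below 1.
#'
#' @param q direct impact matrix from [fw_direct_impacts()].
#' @return matrix `M` of total (direct + indirect) impacts.
#' @export
#' @examples
#' b <- fw_balance(fw_example_web())
#' M <- fw_mti(fw_direct_impacts(b))
#' # predation release: the carnivore's net impact on phytoplankton
#' M["carnivore", "phytoplankton"]
fw_mti <- function(q) {
  stopifnot(is.matrix(q), nrow(q) == ncol(q))
  M <- tryCatch(solve(diag(nrow(q)) - q) - diag(nrow(q)),
                error = function(e)
                  stop("non-convergent impact propagation: (I - q) is ",
                       "singular", call. = FALSE))
  dimnames(M) <- dimnames(q)
  M
}

#' Keystoneness and relative total impact
#'
#' A group's overall effect is the root-sum-square of its total impacts
#' on every other living group,
#' \deqn{\epsilon_i = \sqrt{\sum_{j \ne i} m_{ij}^2},}
#' and its keystoneness is
#' \deqn{KS_i = \log_{10}[\epsilon_i (1 - p_i)]}
#' with `p_i` the group's share of total living biomass, so the index is
#' high for groups with low biomass but strong trophic impact; values
#' near or above 0 flag keystone groups. The relative total impact
#' (`epsilon / max(epsilon)`, always in `[0, 1]`) is the conventional
#' x-axis against which KS is plotted.
#'
#' @param M mixed trophic impact matrix from [fw_mti()].
#' @param balanced the `fw_balanced` supplying biomasses and group types.
#' @return data.frame: name, TL-agnostic `epsilon`,
#'   `relative_total_impact`, biomass proportion `p`, `KS` (NA when
#'   `epsilon` is 0), living groups only.
#' @references Libralato, Christensen & Pauly (2006) A method for
#'   identifying keystone species in food web models.
#' @export
fw_keystoneness <- function(M, balanced) {
  stopifnot(inherits(balanced, "fw_balanced"))
  b <- balanced$budget
  living <- which(b$type != "detritus")
  stopifnot(length(living) > 0, sum(b$B[living], na.rm = TRUE) > 0)
  Ml <- M[living, living, drop = FALSE]
  eps <- vapply(seq_along(living), function(k)
    sqrt(sum(Ml[k, -k]^2)), numeric(1))
  p <- b$B[living] / sum(b$B[living], na.rm = TRUE)
  KS <- ifelse(eps > 0, log10(eps * (1 - p)), NA_real_)
  data.frame(name = b$name[living],
             epsilon = eps,
             relative_total_impact = if (max(eps) > 0) eps / max(eps)
                                     else eps,
             p = p, KS = KS,
             stringsAsFactors = FALSE)
}
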