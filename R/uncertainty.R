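#' Pedigree index of input data quality
#'
#' Each basic input (B, PB, QB, diet, catch) of each living group carries
#' a confidence score in `[0, 1]` describing its provenance (locally
#' measured data scoring high, values borrowed from other systems
#' scoring low). The pedigree index of a model is the unweighted mean of
#' all scored entries over living groups.
#'
#' @param model an `fw_model` carrying a `pedigree` matrix (groups x
#'   parameters `B`,`PB`,`QB`,`DC`,`Y`), or such a matrix directly.
#' @return mean score in `[0, 1]`.
#' @export
fw_pedigree <- function(model) {
  ped <- if (inherits(model, "fw_model")) {
    if (is.null(model$pedigree)) stop("model has no pedigree table")
    keep <- model$groups$type != "detritus"
    model$pedigree[keep, , drop = FALSE]
  } else as.matrix(model)
  vals <- ped[!is.na(ped)]
  if (!length(vals)) stop("pedigree table has no scored entries")
  if (any(vals < 0 | vals > 1)) stop("pedigree scores must lie in [0, 1]")
  mean(vals)
}

# Perturb one model: every scored parameter drawn from
# Normal(base, cv * base), truncated positive (resample, then clamp);
# diet columns clipped to [0, 1] and renormalized.
perturb_model <- function(model, cv) {
  g <- model$groups
  n <- nrow(g)
  draw <- function(base, cvp) {
    if (is.na(base) || cvp == 0) return(base)
    sd <- cvp * abs(base)
    for (k in 1:100) {
      x <- stats::rnorm(1, base, sd)
      if (x > 0 || base == 0) return(max(x, 0))
    }
    max(stats::rnorm(1, base, sd), 1e-12)
  }
  for (i in seq_len(n)) {
    if (g$type[i] == "detritus") next
    if (!is.na(g$B[i])) g$B[i] <- draw(g$B[i], cv["B"])
    if (!is.na(g$PB[i])) g$PB[i] <- draw(g$PB[i], cv["PB"])
    if (g$type[i] == "consumer" && !is.na(g$QB[i]))
      g$QB[i] <- draw(g$QB[i], cv["QB"])
    if (!is.na(g$Y[i]) && g$Y[i] > 0) g$Y[i] <- draw(g$Y[i], cv["Y"])
  }
  model$groups <- g
  if (cv["DC"] > 0) {
    for (j in which(g$type == "consumer")) {
      col <- model$diet[, j]
      if (sum(col) == 0) next
      nz <- col > 0
      col[nz] <- pmin(pmax(stats::rnorm(sum(nz), col[nz],
                                        cv["DC"] * col[nz]), 0), 1)
      tot <- sum(col) + model$import_fraction[j]
      if (tot > 0) {
        model$diet[, j] <- col / tot
        model$import_fraction[j] <- model$import_fraction[j] / tot
      }
    }
  }
  model
}

# Acceptance screen for one solved run.
run_accepted <- function(bal, physiology, ge_range) {
  EE <- bal$model$groups$EE
  if (any(!is.na(EE) & EE > 1 + 1e-9)) return(FALSE)
  cons <- bal$budget$type == "consumer"
  if (any(bal$budget$R[cons] < 0)) return(FALSE)
  if (physiology) {
    GE <- bal$budget$GE[cons]
    if (any(!is.na(GE) & (GE <= ge_range[1] | GE >= ge_range[2])))
      return(FALSE)
  }
  TRUE
}

#' Monte Carlo uncertainty propagation
#'
#' Ecoranger-style resampling: each run redraws every basic parameter
#' from a normal distribution centred on its input value with relative
#' error `cv` (truncated positive; diet columns renormalized after
#' perturbation), re-solves the mass balance, and is accepted when the
#' solve succeeds, every ecotrophic efficiency is at most 1 and no
#' consumer respires negatively (optionally also requiring gross
#' efficiencies inside `ge_range` with `physiology = TRUE`). Among the
#' accepted runs the `n_keep` best-fitting scenarios — smallest sum of
#' squared standardized deviations of the drawn inputs from the base
#' inputs — are retained, and input parameters and derived indices are
#' summarized as mean and SD over that kept set.
#'
#' Randomness comes from a single seed; each run uses a substream derived
#' from the run index, so results are reproducible and independent of
#' evaluation order.
#'
#' @param model base `fw_model` (must balance).
#' @param cv named relative errors (fractions) for `B`, `PB`, `QB`, `DC`,
#'   `Y`; missing names default to 0.
#' @param n_total number of runs (default 10000).
#' @param n_keep best-fitting scenarios kept (default 200).
#' @param seed integer seed.
#' @param physiology,ge_range acceptance screen options (see above).
#' @return list of class `fw_ensemble`: `n_total`, `n_accepted`,
#'   `n_keep`, `acceptance_rate`, `parameters` (per group x parameter
#'   mean/sd over kept runs), `indices` (mean/sd of EE, TL, TST, FCI over
#'   kept runs), `seed`.
#' @export
fw_monte_carlo <- function(model, cv, n_total = 10000, n_keep = 200,
                           seed = 1, physiology = FALSE,
                           ge_range = c(0.1, 0.3)) {
  stopifnot(inherits(model, "fw_model"), n_total >= 1)
  cv_full <- c(B = 0, PB = 0, QB = 0, DC = 0, Y = 0)
  stopifnot(all(names(cv) %in% names(cv_full)))
  cv_full[names(cv)] <- cv
  if (any(cv_full < 0)) stop("cv values must be non-negative")
  g <- model$groups
  living <- g$type != "detritus"
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_total)

  base_vec <- param_vector(model)
  sd_vec <- base_sd(base_vec, cv_full)
  keep_score <- rep(Inf, n_total)
  accepted <- logical(n_total)
  par_store <- vector("list", n_total)
  idx_store <- vector("list", n_total)
  for (r in seq_len(n_total)) {
    set.seed(run_seeds[r])
    pm <- perturb_model(model, cv_full)
    bal <- tryCatch(suppressWarnings(fw_balance(pm)),
                    error = function(e) NULL)
    if (is.null(bal)) next
    if (!run_accepted(bal, physiology, ge_range)) next
    accepted[r] <- TRUE
    v <- param_vector(pm)
    dev <- (v - base_vec) / sd_vec
    dev[!is.finite(dev)] <- 0
    keep_score[r] <- sum(dev^2)
    par_store[[r]] <- v
    st <- fw_summary_stats(bal)
    idx_store[[r]] <- c(
      stats::setNames(bal$model$groups$EE[living],
                      paste0("EE.", g$name[living])),
      TST = st$TST, TPP = st$TPP, TB = st$TB)
  }
  n_acc <- sum(accepted)
  if (n_acc == 0)
    stop("no accepted runs out of ", n_total,
         " (all rejected by EE/solve/respiration constraints)")
  kept <- order(keep_score)[seq_len(min(n_keep, n_acc))]

  par_mat <- do.call(rbind, par_store[kept])
  idx_mat <- do.call(rbind, idx_store[kept])
  summarize <- function(m)
    data.frame(parameter = colnames(m),
               mean = colMeans(m),
               sd = apply(m, 2, stats::sd),
               row.names = NULL)
  structure(list(n_total = n_total, n_accepted = n_acc,
                 n_keep = length(kept),
                 acceptance_rate = n_acc / n_total,
                 parameters = summarize(par_mat),
                 indices = summarize(idx_mat),
                 seed = seed),
            class = "fw_ensemble")
}

# Flatten the perturbable inputs of a model into a named vector.
param_vector <- function(model) {
  g <- model$groups
  living <- g$type != "detritus"
  nm <- g$name[living]
  out <- c(stats::setNames(g$B[living], paste0("B.", nm)),
           stats::setNames(g$PB[living], paste0("PB.", nm)),
           stats::setNames(g$QB[living], paste0("QB.", nm)),
           stats::setNames(g$Y[living], paste0("Y.", nm)))
  dc <- as.vector(model$diet)
  names(dc) <- paste0("DC.", rep(g$name, ncol(model$diet)), ".",
                      rep(g$name, each = nrow(model$diet)))
  out <- c(out, dc[dc != 0])
  out[!is.na(out)]
}

base_sd <- function(base_vec, cv) {
  cls <- sub("\\..*$", "", names(base_vec))
  sd <- abs(base_vec) * cv[cls]
  sd[sd == 0 | is.na(sd)] <- 1
  sd
}

#' @export
print.fw_ensemble <- function(x, ...) {
  cat("Monte Carlo ensemble: ", x$n_accepted, "/", x$n_total,
      " runs accepted (", round(100 * x$acceptance_rate, 1),
      "%), ", x$n_keep, " best-fitting kept (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}
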