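#' Canonical statistics-table row set
#'
#' Row labels, units and display-precision classes of the standard
#' summary table (one column per model). Precision classes: `int` (whole
#' flows, g/m2/yr), `flow1` (one decimal), `sig3` (three significant
#' digits for maturity ratios and efficiencies), `dec4` (fixed four
#' decimals for TB/TST), `dec3` (three decimals).
#' @keywords internal
stats_rows <- function() {
  data.frame(
    key = c("sum_consumption", "sum_respiration", "sum_to_detritus",
            "TST", "sum_production", "TPP", "NSP", "TB",
            "TPP_TR", "TPP_TB", "TB_TST",
            "throughput_cycled_excl", "throughput_cycled_incl",
            "predator_cycling_index", "FCI", "FML",
            "straight_path_excl", "straight_path_incl",
            "CI", "SOI", "shannon", "C", "A", "AC"),
    label = c("Sum of all consumption", "Sum of all respiration (TR)",
              "Sum of all back flows to detritus",
              "Total system throughput (TST)", "Sum of all production",
              "Total net primary production (TPP)",
              "Net system production (TPP-TR)",
              "Total biomass (TB, excluding detritus)",
              "Total primary production/total respiration (TPP/TR)",
              "Total primary production/total biomass (TPP/TB)",
              "Total biomass/Total system throughput (TB/TST)",
              "Throughput cycled (excluding detritus)",
              "Throughput cycled (including detritus)",
              "Predator cycling index", "Finn's cycling index (FCI)",
              "Finn's mean path length (FML)",
              "Finn's straight-through path length (excluding detritus)",
              "Finn's straight-through path length (including detritus)",
              "Connectance Index (CI)", "System Omnivory Index (SOI)",
              "Shannon diversity index", "Capacity (C)",
              "Ascendency (A)", "Ascendency/Capacity (A/C)"),
    unit = c(rep("g/m2/year", 8), "", "", "",
             "g/m2/year", "g/m2/year", "%", "%", "", "", "",
             "", "", "", "Flowbits", "Flowbits", "%"),
    class = c(rep("int", 7), "flow1", "sig3", "sig3", "dec4",
              "flow1", "int", "dec3", "sig3", "sig3", "sig3", "sig3",
              "dec3", "dec3", "dec3", "int", "int", "sig3"),
    stringsAsFactors = FALSE)
}

#' Format a statistic to its table precision
#'
#' Applies the display precision class of a named index row: whole flows
#' round to integers, maturity ratios to three significant digits,
#' TB/TST to four fixed decimals, connectance/omnivory/diversity to
#' three decimals. This is the arithmetic used to reproduce printed
#' component-and-ratio pairs (e.g. TPP 557 over TR 306 prints as 1.82).
#'
#' @param x numeric value (unrounded).
#' @param key row key from [stats_rows()] (e.g. `"TPP_TR"`).
#' @return character rendering of `x`.
#' @export
#' @examples
#' fw_format_stat(557 / 306, "TPP_TR")   # "1.82"
#' fw_format_stat(51.3 / 5396, "TB_TST") # "0.0095"
fw_format_stat <- function(x, key) {
  rows <- stats_rows()
  cls <- rows$class[match(key, rows$key)]
  if (is.na(cls)) stop("unknown statistic key: ", key)
  if (is.na(x)) return("-")
  switch(cls,
         int = format(round(x), scientific = FALSE, trim = TRUE,
                      big.mark = ""),
         flow1 = formatC(x, format = "f", digits = 1),
         sig3 = formatC(signif(x, 3), format = "fg", flag = "#",
                        digits = 3),
         dec4 = formatC(x, format = "f", digits = 4),
         dec3 = formatC(x, format = "f", digits = 3))
}

#' Render a statistics table for one or more models
#'
#' @param stats_list named list of `fw_stats` (from [fw_statistics()]).
#' @param formatted return display-formatted strings (default) or raw
#'   numbers.
#' @return data.frame with `Parameter`, `Unit`, and one column per model.
#' @export
fw_stats_table <- function(stats_list, formatted = TRUE) {
  if (inherits(stats_list, "fw_stats")) stats_list <- list(model = stats_list)
  rows <- stats_rows()
  out <- data.frame(Parameter = rows$label, Unit = rows$unit,
                    stringsAsFactors = FALSE)
  for (nm in names(stats_list)) {
    st <- stats_list[[nm]]
    vals <- vapply(rows$key, function(k)
      if (is.null(st[[k]]) || is.na(st[[k]])) NA_real_ else st[[k]],
      numeric(1))
    out[[nm]] <- if (formatted)
      mapply(fw_format_stat, vals, rows$key) else vals
  }
  out
}

#' Rank models by maturity indices
#'
#' Per-index rankings over a set of system-statistics objects
#' (higher-is-more-mature for FCI, FML, SOI, CI, Shannon diversity and
#' TST; closeness to 1 for TPP/TR), combined into a weighted Borda-count
#' composite. Ties share the better rank and are reported.
#'
#' @param stats_list named list of `fw_stats`.
#' @param weights named index weights for the composite (default equal
#'   over the available indices).
#' @return list of class `fw_comparison`: `ranks` (index x model rank
#'   matrix), `scores` (Borda composite, higher = more mature),
#'   `ordering` (model names, most mature first).
#' @export
fw_compare <- function(stats_list, weights = NULL) {
  stopifnot(length(stats_list) >= 2, !is.null(names(stats_list)))
  idx_up <- c("FCI", "FML", "SOI", "CI", "shannon", "TST")
  idx_one <- "TPP_TR"
  keys <- c(idx_up, idx_one)
  score <- function(key) {
    v <- vapply(stats_list, function(s)
      if (is.null(s[[key]]) || is.na(s[[key]])) NA_real_ else s[[key]],
      numeric(1))
    if (key == idx_one) v <- -abs(v - 1)   # closeness to 1
    v
  }
  mat <- t(vapply(keys, score, numeric(length(stats_list))))
  colnames(mat) <- names(stats_list)
  keep <- !apply(mat, 1, anyNA)
  if (any(!keep))
    warning("index missing in some model, skipped: ",
            paste(keys[!keep], collapse = ", "))
  mat <- mat[keep, , drop = FALSE]
  ranks <- t(apply(-mat, 1, rank, ties.method = "min"))
  if (is.null(weights)) weights <- stats::setNames(rep(1, nrow(mat)),
                                                   rownames(mat))
  w <- weights[rownames(ranks)]
  w[is.na(w)] <- 0
  n <- ncol(ranks)
  borda <- colSums((n - ranks) * w)
  ordering <- names(sort(-borda))
  structure(list(ranks = ranks, scores = borda, ordering = ordering,
                 tied = any(duplicated(borda))),
            class = "fw_comparison")
}

#' @export
print.fw_comparison <- function(x, ...) {
  cat("Maturity ranking (most mature first):",
      paste(x$ordering, collapse = " > "), "\n")
  print(x$ranks)
  invisible(x)
}

#' Text rendering of a Lindeman spine
#'
#' One box per discrete trophic level showing inflow, transfer
#' efficiency, respiration and detritus flow; empty levels render with
#' dashes, not zeros.
#'
#' @param spine an `fw_spine`.
#' @param chain `"combined"`, `"producer"` or `"detritus"`.
#' @return character vector of lines, invisibly printed.
#' @export
fw_render_spine <- function(spine, chain = "combined") {
  stopifnot(inherits(spine, "fw_spine"))
  ch <- spine[[chain]]
  lines <- character()
  roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")
  for (k in seq_len(nrow(ch))) {
    if (ch$inflow[k] <= 0 && k > 2) next
    fmt <- function(x) if (is.na(x)) "-" else
      trimws(formatC(x, format = "g", digits = 4))
    lines <- c(lines, sprintf(
      "TL %-4s inflow %-10s TE %-7s resp %-10s to detritus %-10s -> %s",
      roman[min(k, length(roman))], fmt(ch$inflow[k]),
      if (is.na(ch$TE[k])) "-" else paste0(formatC(ch$TE[k], format = "f",
                                                   digits = 2), "%"),
      fmt(ch$respiration[k]), fmt(ch$to_detritus[k]),
      fmt(ch$to_next[k])))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Run the full analysis pipeline
#'
#' Balances a model (optionally auto-adjusting diets), computes the
#' statistics suite, Lindeman spine, impact matrices and keystoneness,
#' optionally a Monte Carlo ensemble, and writes every artifact plus a
#' run manifest to an output directory. Numeric artifacts are
#' deterministic given the model and seed.
#'
#' @param model an `fw_model` or a path readable by [fw_read_model()].
#' @param out_dir output directory (created).
#' @param auto_balance run [fw_adjust_diet()] first when imbalanced.
#' @param ensemble_cv named cv vector to trigger a Monte Carlo stage
#'   (NULL = skip).
#' @param n_total,n_keep,seed Monte Carlo controls.
#' @return invisible list of the computed objects.
#' @export
fw_pipeline <- function(model, out_dir, auto_balance = FALSE,
                        ensemble_cv = NULL, n_total = 1000, n_keep = 100,
                        seed = 1) {
  if (is.character(model)) model <- fw_read_model(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  rep <- fw_validate(model)
  utils::write.csv(rep, file.path(out_dir, "validation.csv"),
                   row.names = FALSE)
  stages <- c(stages, "validate")
  if (auto_balance) {
    adj <- fw_adjust_diet(model)
    model <- adj$model
    utils::write.csv(adj$log, file.path(out_dir, "adjustment_log.csv"),
                     row.names = FALSE)
    stages <- c(stages, "adjust")
  }
  bal <- fw_balance(model)
  utils::write.csv(bal$budget, file.path(out_dir, "budget.csv"),
                   row.names = FALSE)
  stages <- c(stages, "solve")
  st <- fw_statistics(bal)
  utils::write.csv(fw_stats_table(list(model = st)),
                   file.path(out_dir, "stats.csv"), row.names = FALSE)
  stages <- c(stages, "stats")
  sp <- fw_lindeman(bal)
  utils::write.csv(sp$combined, file.path(out_dir, "spine.csv"),
                   row.names = FALSE)
  stages <- c(stages, "spine")
  q <- fw_direct_impacts(bal)
  M <- fw_mti(q)
  utils::write.csv(as.data.frame(M), file.path(out_dir, "mti.csv"))
  ks <- fw_keystoneness(M, bal)
  utils::write.csv(ks, file.path(out_dir, "keystoneness.csv"),
                   row.names = FALSE)
  stages <- c(stages, "impacts")
  ens <- NULL
  if (!is.null(ensemble_cv)) {
    ens <- fw_monte_carlo(model, ensemble_cv, n_total = n_total,
                          n_keep = n_keep, seed = seed)
    jsonlite::write_json(
      list(n_total = ens$n_total, n_accepted = ens$n_accepted,
           acceptance_rate = ens$acceptance_rate,
           parameters = ens$parameters, indices = ens$indices),
      file.path(out_dir, "ensemble.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
    stages <- c(stages, "ensemble")
  }
  fw_export_graph(bal, file.path(out_dir, "network.gml"))
  stages <- c(stages, "graph")
  manifest <- list(package = "fwb",
                   version = as.character(utils::packageVersion("fwb")),
                   stages = stages, seed = seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(balanced = bal, stats = st, spine = sp, mti = M,
                 keystoneness = ks, ensemble = ens))
}

#' Export the flow network as a text graph
#'
#' Writes a GML document (node per group with trophic level and biomass
#' attributes, edge per consumption flow weighted in g/m2/yr) readable
#' by standard graph viewers.
#'
#' @param balanced an `fw_balanced`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
fw_export_graph <- function(balanced, path) {
  stopifnot(inherits(balanced, "fw_balanced"))
  b <- balanced$budget
  TL <- fw_trophic_levels(balanced$model)
  Tm <- balanced$flows$T
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("graph [", con)
  writeLines("  directed 1", con)
  for (i in seq_len(nrow(b)))
    writeLines(sprintf(
      '  node [ id %d label "%s" type "%s" TL %.4f biomass %.6g ]',
      i, b$name[i], b$type[i], TL[i],
      ifelse(is.na(b$B[i]), 0, b$B[i])), con)
  idx <- which(Tm > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx)))
    writeLines(sprintf("  edge [ source %d target %d weight %.6g ]",
                       idx[k, 1], idx[k, 2], Tm[idx[k, 1], idx[k, 2]]),
               con)
  writeLines("]", con)
  invisible(path)
}
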