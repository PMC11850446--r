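#' Construct a food-web model definition
#'
#' A model definition couples a table of functional-group parameters with a
#' diet-composition matrix. It is the unsolved input to [fw_balance()].
#'
#' Group parameters follow the standard trophic mass-balance convention:
#' biomass `B` (g/m2 wet weight), production/biomass ratio `PB` (/yr),
#' consumption/biomass ratio `QB` (/yr, consumers only), ecotrophic
#' efficiency `EE` (dimensionless; `NA` means "solve for it"),
#' unassimilated fraction `UC` (0 to 1), fishery catch `Y`, net migration
#' `NM`, biomass accumulation `BA` (all g/m2/yr), optional measured
#' respiration `R` for producers (g/m2/yr), and `detritus_import`
#' (external detritus inflow, detritus groups only).
#'
#' `NA` always means "not supplied"; 0 is a legal measured value and is
#' never reinterpreted as unknown.
#'
#' @param groups data.frame with at least columns `name` and `type`
#'   (`"producer"`, `"consumer"` or `"detritus"`). Missing parameter
#'   columns are added as `NA`.
#' @param diet numeric matrix of diet proportions, `diet[i, j]` = fraction
#'   of predator `j`'s diet taken from prey `i`. Rows and columns are the
#'   groups, in the order of `groups`. May be `NULL` for webs with no
#'   consumers.
#' @param import_fraction per-predator fraction of diet imported from
#'   outside the system; defaults to 0 for every group.
#' @param pedigree optional numeric matrix (groups x parameters
#'   `B`,`PB`,`QB`,`DC`,`Y`) of data-quality scores in `[0, 1]`.
#' @param metadata free-form named list (site label, units, notes).
#'
#' @return An object of class `fw_model`.
#' @seealso [fw_validate()], [fw_balance()], [fw_read_model()]
#' @export
#' @examples
#' m <- fw_example_web()
#' m
fw_model <- function(groups, diet = NULL, import_fraction = NULL,
                     pedigree = NULL, metadata = list()) {
  if (!is.data.frame(groups) || nrow(groups) == 0L)
    stop("'groups' must be a non-empty data.frame")
  if (!all(c("name", "type") %in% names(groups)))
    stop("'groups' needs 'name' and 'type' columns")
  groups$name <- as.character(groups$name)
  groups$type <- match.arg(as.character(groups$type),
                           c("consumer", "producer", "detritus"),
                           several.ok = TRUE)
  if (anyDuplicated(groups$name))
    stop("duplicate group names: ",
         paste(unique(groups$name[duplicated(groups$name)]), collapse = ", "))
  n <- nrow(groups)
  for (col in c("B", "PB", "QB", "EE", "UC", "Y", "NM", "BA", "R",
                "detritus_import")) {
    if (is.null(groups[[col]])) groups[[col]] <- NA_real_
    groups[[col]] <- as.numeric(groups[[col]])
  }
  groups <- groups[, c("name", "type", "B", "PB", "QB", "EE", "UC",
                       "Y", "NM", "BA", "R", "detritus_import")]
  if (is.null(diet)) diet <- matrix(0, n, n)
  diet <- as.matrix(diet)
  if (!all(dim(diet) == n))
    stop("diet matrix must be ", n, " x ", n, " to match the group list")
  dimnames(diet) <- list(prey = groups$name, predator = groups$name)
  if (is.null(import_fraction)) import_fraction <- rep(0, n)
  if (length(import_fraction) != n)
    stop("import_fraction must have one entry per group")
  import_fraction <- stats::setNames(as.numeric(import_fraction), groups$name)
  if (!is.null(pedigree)) {
    pedigree <- as.matrix(pedigree)
    if (nrow(pedigree) != n)
      stop("pedigree must have one row per group")
  }
  structure(list(groups = groups, diet = diet,
                 import_fraction = import_fraction,
                 pedigree = pedigree, metadata = metadata),
            class = "fw_model")
}

#' @export
print.fw_model <- function(x, ...) {
  tab <- table(factor(x$groups$type,
                      c("producer", "consumer", "detritus")))
  cat("Food-web model definition (", nrow(x$groups), " groups: ",
      tab[["producer"]], " producer, ", tab[["consumer"]], " consumer, ",
      tab[["detritus"]], " detritus)\n", sep = "")
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = " = ", collapse = "; "), "\n")
  nlink <- sum(x$diet > 0)
  cat("  diet links:", nlink, "  unresolved EE:",
      sum(is.na(x$groups$EE) & x$groups$type != "detritus"), "\n")
  invisible(x)
}

is_living <- function(model) model$groups$type != "detritus"
is_consumer <- function(model) model$groups$type == "consumer"

#' The four-group worked-example web
#'
#' A deliberately tiny linear chain (detritus, phytoplankton, herbivore,
#' carnivore) whose balance can be checked by hand: predation on the
#' phytoplankton is 10 * 10 * 1 = 100 g/m2/yr against a production of
#' 20 * 50 = 1000, so its ecotrophic efficiency solves to 0.100.
#'
#' @param carnivore_qb consumption/biomass of the carnivore; the default 5
#'   balances, 150 drives the herbivore's EE to 150/20 = 7.5 (an
#'   imbalanced variant used to exercise diagnostics and diet
#'   adjustment).
#' @return An `fw_model`.
#' @export
fw_example_web <- function(carnivore_qb = 5) {
  groups <- data.frame(
    name = c("detritus", "phytoplankton", "herbivore", "carnivore"),
    type = c("detritus", "producer", "consumer", "consumer"),
    B  = c(10, 20, 10, 1),
    PB = c(NA, 50, 2, 1),
    QB = c(NA, NA, 10, carnivore_qb),
    UC = c(NA, NA, 0.2, 0.2),
    Y = 0, NM = 0, BA = 0)
  diet <- matrix(0, 4, 4)
  diet[2, 3] <- 1   # herbivore eats phytoplankton
  diet[3, 4] <- 1   # carnivore eats herbivore
  fw_model(groups, diet, metadata = list(site = "worked example"))
}

#' Validate a model definition
#'
#' Checks every content invariant of the data model and returns a report of
#' violations rather than raising: non-negative B/PB/QB, UC in `[0, 1)`,
#' EE unset or >= 0, diet entries in `[0, 1]`, consumer diet columns
#' (plus import fraction) summing to 1 within `tol`, no diet column on
#' producers or detritus, no QB/UC on non-consumers, and exactly one
#' unknown among `{B, EE}` per living group.
#'
#' Validation is pure: the model is never modified.
#'
#' @param model an `fw_model`.
#' @param tol diet column-sum tolerance (default 1e-6).
#' @return data.frame of class `fw_validation` with columns `group`,
#'   `field`, `value`, `rule`, `severity`; zero rows when the model is
#'   valid.
#' @export
fw_validate <- function(model, tol = 1e-6) {
  stopifnot(inherits(model, "fw_model"))
  g <- model$groups
  out <- list()
  bad <- function(group, field, value, rule, severity = "error")
    data.frame(group = group, field = field, value = as.numeric(value)[1],
               rule = rule, severity = severity)
  for (i in seq_len(nrow(g))) {
    for (f in c("B", "PB", "QB")) {
      v <- g[[f]][i]
      if (!is.na(v) && v < 0)
        out[[length(out) + 1L]] <- bad(g$name[i], f, v, paste(f, "negative"))
    }
    if (!is.na(g$UC[i]) && (g$UC[i] < 0 || g$UC[i] >= 1))
      out[[length(out) + 1L]] <- bad(g$name[i], "UC", g$UC[i],
                                     "UC outside [0,1)")
    if (!is.na(g$EE[i]) && g$EE[i] < 0)
      out[[length(out) + 1L]] <- bad(g$name[i], "EE", g$EE[i], "EE negative")
    if (g$type[i] != "consumer") {
      for (f in c("QB", "UC"))
        if (!is.na(g[[f]][i]))
          out[[length(out) + 1L]] <- bad(g$name[i], f, g[[f]][i],
                                         paste(f, "set on non-consumer"))
      if (any(model$diet[, i] > 0))
        out[[length(out) + 1L]] <- bad(g$name[i], "diet",
                                       sum(model$diet[, i]),
                                       "diet column on non-consumer")
    }
    if (g$type[i] == "detritus" && !is.na(g$PB[i]))
      out[[length(out) + 1L]] <- bad(g$name[i], "PB", g$PB[i],
                                     "PB set on detritus")
    if (g$type[i] != "detritus") {
      n_unknown <- is.na(g$B[i]) + is.na(g$EE[i])
      if (n_unknown != 1L)
        out[[length(out) + 1L]] <- bad(
          g$name[i], "B/EE", n_unknown,
          "exactly one of {B, EE} must be unset", severity = "warning")
    }
  }
  if (any(model$diet < 0 | model$diet > 1)) {
    idx <- which(model$diet < 0 | model$diet > 1, arr.ind = TRUE)
    for (k in seq_len(nrow(idx)))
      out[[length(out) + 1L]] <- bad(
        g$name[idx[k, 2]], paste0("DC[", g$name[idx[k, 1]], "]"),
        model$diet[idx[k, 1], idx[k, 2]], "diet entry outside [0,1]")
  }
  for (j in which(g$type == "consumer")) {
    s <- sum(model$diet[, j]) + model$import_fraction[j]
    if (is.na(g$QB[j]) || g$QB[j] == 0) next
    if (abs(s - 1) > tol)
      out[[length(out) + 1L]] <- bad(g$name[j], "diet column", s,
                                     "diet column not normalized")
  }
  if (length(out)) out <- do.call(rbind, out)
  else out <- data.frame(group = character(), field = character(),
                         value = numeric(), rule = character(),
                         severity = character())
  class(out) <- c("fw_validation", "data.frame")
  out
}

#' @export
print.fw_validation <- function(x, ...) {
  if (nrow(x) == 0) cat("Model valid: no violations.\n")
  else {
    cat("Model validation:", nrow(x), "violation(s)\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

# Renormalize consumer diet columns off by <= renorm_tol (hand-rounded field
# tables); anything worse is left for fw_validate to report.
renormalize_diet <- function(model, renorm_tol = 1e-3, tol = 1e-6) {
  cons <- which(is_consumer(model))
  fixed <- character()
  for (j in cons) {
    s <- sum(model$diet[, j]) + model$import_fraction[j]
    if (s == 0) next
    if (abs(s - 1) > tol && abs(s - 1) <= renorm_tol) {
      model$diet[, j] <- model$diet[, j] / s
      model$import_fraction[j] <- model$import_fraction[j] / s
      fixed <- c(fixed, model$groups$name[j])
    }
  }
  if (length(fixed))
    warning("diet columns renormalized for: ", paste(fixed, collapse = ", "))
  model
}

#' Read a model definition from disk
#'
#' Two on-disk layouts are supported. `format = "csv-pair"` reads
#' `<path>/groups.csv` and `<path>/diet.csv` (or `path` itself if it is
#' the groups file and a sibling diet file exists): the groups table has
#' one row per functional group with the columns of [fw_model()]; the diet
#' table is prey-rows by predator-columns with prey names in the first
#' column, and may carry an `Import` row for diet imported from outside
#' the system. `format = "structured"` reads a single JSON document
#' written by [fw_write_model()].
#'
#' Empty cells and the string `NA` denote unset parameters; they are kept
#' as `NA`, never coerced to 0. Diet columns off unity by no more than
#' 1e-3 are renormalized with a warning.
#'
#' @param path directory (csv-pair) or file (structured).
#' @param format `"csv-pair"` or `"structured"`; guessed from `path` when
#'   missing.
#' @return An `fw_model`.
#' @export
fw_read_model <- function(path, format = c("auto", "csv-pair", "structured")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "csv-pair" else "structured"
  if (format == "csv-pair") {
    gf <- file.path(path, "groups.csv")
    df <- file.path(path, "diet.csv")
    if (!file.exists(gf)) stop("missing groups table: ", gf)
    g <- utils::read.csv(gf, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
    if (is.null(g$name) || is.null(g$type))
      stop("groups.csv must have 'name' and 'type' columns")
    n <- nrow(g)
    diet <- matrix(0, n, n)
    imp <- rep(0, n)
    if (file.exists(df)) {
      d <- utils::read.csv(df, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
      prey <- as.character(d[[1]])
      preds <- names(d)[-1]
      unknown <- setdiff(preds, g$name)
      if (length(unknown))
        stop("diet column references unknown group(s): ",
             paste(unknown, collapse = ", "))
      unknown <- setdiff(setdiff(prey, "Import"), g$name)
      if (length(unknown))
        stop("diet row references unknown group(s): ",
             paste(unknown, collapse = ", "))
      for (jn in preds) {
        col <- d[[jn]]
        if (!is.numeric(col))
          stop("non-numeric diet entry in column '", jn, "'")
        col[is.na(col)] <- 0
        j <- match(jn, g$name)
        for (k in seq_along(prey)) {
          if (prey[k] == "Import") imp[j] <- col[k]
          else diet[match(prey[k], g$name), j] <- col[k]
        }
      }
    }
    model <- fw_model(g, diet, imp)
    renormalize_diet(model)
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    g <- as.data.frame(doc$groups, stringsAsFactors = FALSE)
    n <- nrow(g)
    diet <- matrix(unlist(doc$diet), n, n,
                   dimnames = list(g$name, g$name))
    ped <- unlist(doc$pedigree)
    model <- fw_model(g, diet, doc$import_fraction,
                      pedigree = if (length(ped)) matrix(ped, n),
                      metadata = as.list(doc$metadata))
    renormalize_diet(model)
  }
}

#' Write a model definition to disk
#'
#' Inverse of [fw_read_model()]: values round-trip at full double
#' precision, and unset parameters are written as the explicit sentinel
#' `NA` (an empty cell on re-read), never as 0.
#'
#' @param model valid `fw_model`.
#' @param path directory (csv-pair; created if needed) or file
#'   (structured JSON).
#' @param format `"csv-pair"` or `"structured"`.
#' @return `path`, invisibly.
#' @export
fw_write_model <- function(model, path,
                           format = c("csv-pair", "structured")) {
  stopifnot(inherits(model, "fw_model"))
  if (nrow(model$groups) == 0L) stop("empty group list")
  format <- match.arg(format)
  if (format == "csv-pair") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    g <- model$groups
    num <- vapply(g, is.numeric, logical(1))
    g[num] <- lapply(g[num], function(x) {
      y <- format(x, digits = 17, trim = TRUE, scientific = FALSE)
      y[is.na(x)] <- NA
      y
    })
    utils::write.csv(g, file.path(path, "groups.csv"), row.names = FALSE,
                     quote = FALSE, na = "NA")
    d <- as.data.frame(model$diet, check.names = FALSE)
    d <- rbind(d, Import = model$import_fraction)
    d <- cbind(prey = c(model$groups$name, "Import"), d)
    utils::write.csv(d, file.path(path, "diet.csv"), row.names = FALSE,
                     quote = FALSE, na = "NA")
  } else {
    doc <- list(groups = model$groups,
                diet = model$diet,
                import_fraction = unname(model$import_fraction),
                pedigree = model$pedigree,
                metadata = model$metadata)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
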