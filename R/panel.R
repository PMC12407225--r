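#' Variable specification table
#'
#' Builds the per-variable metadata table used throughout the package. Each
#' variable has a measurement timeslot (`"static"` for demographics and the
#' intervention indicator, or a wave label such as `"T0"`), a kind
#' (`"discrete"` with declared levels, or `"continuous"`), and an analysis
#' role (`"intervention"`, `"demographic"`, `"determinant"`, `"outcome"`).
#'
#' @param name character vector of variable names.
#' @param timeslot character vector, `"static"` or a wave label.
#' @param kind character vector, `"discrete"` or `"continuous"`.
#' @param role character vector of analysis roles.
#' @param levels list of character vectors of levels (discrete variables);
#'   `NULL` entries for continuous variables.
#' @return a data.frame of class `variable_spec` with one row per variable.
#' @export
variable_spec <- function(name, timeslot, kind, role, levels = NULL) {
  stopifnot(length(name) == length(timeslot),
            length(name) == length(kind),
            length(name) == length(role))
  if (anyDuplicated(name)) stop("duplicate variable names in spec")
  if (is.null(levels)) levels <- vector("list", length(name))
  bad <- kind == "discrete" & !vapply(levels, function(l) length(l) >= 2L, logical(1))
  if (any(bad)) stop("discrete variables need >= 2 declared levels: ",
                     paste(name[bad], collapse = ", "))
  static_roles <- role %in% c("intervention", "demographic")
  if (any(static_roles & timeslot != "static"))
    stop("intervention and demographic variables must be static")
  if (any(!static_roles & timeslot == "static" & role %in% c("determinant", "outcome")))
    stop("determinants and outcomes must carry a wave")
  out <- data.frame(name = as.character(name), timeslot = as.character(timeslot),
                    kind = as.character(kind), role = as.character(role),
                    stringsAsFactors = FALSE)
  out$levels <- levels
  class(out) <- c("variable_spec", "data.frame")
  out
}

spec_levels <- function(specs, var) {
  specs$levels[[match(var, specs$name)]]
}

spec_kind <- function(specs, var) {
  specs$kind[match(var, specs$name)]
}

#' Panel dataset container
#'
#' A rectangular participant-by-variable table together with an explicit
#' observed/missing mask, the per-variable specification, and a provenance
#' log of the filters applied so far. Discrete variables are stored as
#' factors over their declared levels, continuous ones as numerics; a
#' missing cell is `NA` in `records` and `FALSE` in `mask`.
#'
#' @param records data.frame of values (one row per participant).
#' @param specs a [variable_spec()] table covering every column of `records`.
#' @param provenance character vector of log lines.
#' @return an object of class `panel_dataset`.
#' @export
panel_dataset <- function(records, specs, provenance = character()) {
  if (!all(names(records) %in% specs$name))
    stop("columns without a variable spec: ",
         paste(setdiff(names(records), specs$name), collapse = ", "))
  specs <- specs[match(names(records), specs$name), , drop = FALSE]
  for (v in names(records)) {
    if (spec_kind(specs, v) == "discrete") {
      lv <- spec_levels(specs, v)
      x <- records[[v]]
      if (!is.factor(x)) x <- factor(as.character(x), levels = lv)
      else x <- factor(as.character(x), levels = lv)
      bad <- !is.na(records[[v]]) & is.na(x)
      if (any(bad)) stop("values outside declared levels in ", v)
      records[[v]] <- x
    } else {
      records[[v]] <- as.numeric(records[[v]])
    }
  }
  mask <- !is.na(as.matrix(records))
  structure(list(records = records, mask = mask, specs = specs,
                 provenance = provenance),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("panel_dataset:", nrow(x$records), "participants x",
      ncol(x$records), "variables\n")
  obs <- mean(x$mask)
  cat(sprintf("  observed cells: %.1f%%\n", 100 * obs))
  waves <- setdiff(unique(x$specs$timeslot), "static")
  cat("  waves:", paste(sort(waves), collapse = ", "), "\n")
  if (length(x$provenance))
    cat("  provenance:\n", paste("   -", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
dim.panel_dataset <- function(x) dim(x$records)

log_step <- function(dataset, msg) {
  dataset$provenance <- c(dataset$provenance, msg)
  dataset
}

#' Read a panel dataset from CSV plus sidecar metadata
#'
#' The CSV has a header row and empty cells for missing values; the JSON
#' sidecar carries the variable kinds, timeslots, roles and discrete levels
#' as written by [write_panel()].
#'
#' @param csv path to the data CSV.
#' @param meta path to the metadata JSON.
#' @return a [panel_dataset()].
#' @export
read_panel <- function(csv, meta) {
  md <- jsonlite::read_json(meta, simplifyVector = TRUE)
  lv <- lapply(md$variables$levels, function(l) if (length(l)) as.character(l) else NULL)
  specs <- variable_spec(md$variables$name, md$variables$timeslot,
                         md$variables$kind, md$variables$role, lv)
  rec <- utils::read.csv(csv, check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = "")
  panel_dataset(rec, specs, provenance = as.character(md$provenance))
}

#' Write a panel dataset to CSV plus sidecar metadata
#'
#' @param dataset a [panel_dataset()].
#' @param csv output CSV path (missing cells written empty).
#' @param meta output JSON metadata path.
#' @return invisibly, the paths written.
#' @export
write_panel <- function(dataset, csv, meta) {
  utils::write.csv(dataset$records, csv, row.names = FALSE, na = "")
  md <- list(
    variables = list(name = dataset$specs$name,
                     timeslot = dataset$specs$timeslot,
                     kind = dataset$specs$kind,
                     role = dataset$specs$role,
                     levels = lapply(dataset$specs$levels,
                                     function(l) if (is.null(l)) character() else l)),
    provenance = dataset$provenance)
  jsonlite::write_json(md, meta, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(csv, meta))
}
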