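#' Collapse raw survey records to occasion-level detection histories
#'
#' Builds the site x occasion detection matrix for one species and one
#' method. An occasion scores 1 if any raw event (sub-event) within it
#' recorded a detection, 0 if it was surveyed without detection, and `NA`
#' if the site was not sampled on that occasion. Live-trap, search and bird
#' survey data use the `"daily"` rule (one day/night per occasion, 3-4
#' columns in the default designs); camera data use the `"weekly"` rule
#' (one week per occasion, 5 columns). Occasion indices are taken as
#' pre-binned in the input; the rule labels the occasion unit.
#'
#' @param records raw survey records: data frame with columns `site_id`,
#'   `species`, `method`, `occasion_index`, `sub_event_index`, `detected`.
#' @param species,method the species and method to extract.
#' @param rule `"daily"` or `"weekly"`.
#' @return a site x occasion 0/1/`NA` matrix with `site_id` rownames and an
#'   `occasion_rule` attribute.
#' @export
collapse_to_occasions <- function(records, species, method,
                                  rule = c("daily", "weekly")) {
  rule <- match.arg(rule)
  check_records(records)
  r <- records[records$species == species & records$method == method, ,
               drop = FALSE]
  if (nrow(r) == 0L) {
    out <- matrix(integer(0), 0, 0)
    attr(out, "occasion_rule") <- rule
    return(out)
  }
  key <- paste(r$site_id, r$occasion_index, r$sub_event_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate raw record for (site, occasion, sub-event): ",
         gsub("\r", " / ", dup))
  }
  occasions <- sort(unique(r$occasion_index))
  sites <- sort(unique(r$site_id))
  y <- matrix(NA_integer_, length(sites), length(occasions),
              dimnames = list(sites, paste0("occ", occasions)))
  i <- match(r$site_id, sites)
  j <- match(r$occasion_index, occasions)
  # any-detection rule within an occasion; surveyed cells start at 0
  flat <- (j - 1L) * length(sites) + i
  y[unique(flat)] <- 0L
  hit <- flat[r$detected == 1L]
  y[unique(hit)] <- 1L
  attr(y, "occasion_rule") <- rule
  y
}

check_records <- function(records) {
  need <- c("site_id", "species", "method", "occasion_index",
            "sub_event_index", "detected")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(records$detected %in% c(0L, 1L))) {
    stop("`detected` must be 0 or 1")
  }
  invisible(records)
}

#' Append per-method detection histories into one multi-method history
#'
#' Concatenates the occasion columns of per-method site x occasion matrices,
#' in the stated method order, recording the sampling method of each column
#' so it can enter the detection model as an observational-level factor.
#' The site universe is the union across methods; a site never sampled by a
#' method gets `NA` in that method's columns.
#'
#' @param per_method list of site x occasion matrices (rownames = site ids),
#'   as returned by [collapse_to_occasions()].
#' @param method_labels character vector, one unique label per matrix.
#' @return an object of class `multimethod_history`: list with `y` (site x
#'   occasion matrix over 0/1/`NA`), `occasion_method` (method label per
#'   column) and `site_ids`.
#' @export
append_methods <- function(per_method, method_labels) {
  stopifnot(length(per_method) == length(method_labels))
  if (anyDuplicated(method_labels)) {
    stop("duplicate method label: ",
         method_labels[duplicated(method_labels)][1])
  }
  keep <- vapply(per_method, function(m) ncol(m) > 0L, logical(1))
  per_method <- per_method[keep]
  method_labels <- method_labels[keep]
  if (length(per_method) == 0L) stop("no non-empty method histories")
  sites <- sort(unique(unlist(lapply(per_method, rownames))))
  blocks <- lapply(per_method, function(m) {
    out <- matrix(NA_integer_, length(sites), ncol(m),
                  dimnames = list(sites, colnames(m)))
    out[match(rownames(m), sites), ] <- m
    out
  })
  y <- do.call(cbind, blocks)
  occasion_method <- rep(method_labels,
                         vapply(per_method, ncol, integer(1)))
  colnames(y) <- paste0(occasion_method, ":",
                        unlist(lapply(per_method, colnames)))
  structure(list(y = y, occasion_method = occasion_method,
                 site_ids = sites),
            class = "multimethod_history")
}

#' @export
print.multimethod_history <- function(x, ...) {
  cat(sprintf("<multimethod_history> %d sites x %d occasions (%s)\n",
              nrow(x$y), ncol(x$y),
              paste(unique(x$occasion_method), collapse = ", ")))
  invisible(x)
}

#' Build the full multi-method history for one species
#'
#' Convenience wrapper: collapses each method present in the records with
#' its rule and appends the per-method histories in a fixed method order
#' (lexicographic by default) so the factor's levels are reproducible.
#'
#' @param records raw survey records (see [collapse_to_occasions()]).
#' @param species the species label.
#' @param weekly_methods methods collapsed with the weekly rule (default
#'   `"camera"`); all others use the daily rule.
#' @param method_order optional explicit column-block order; defaults to
#'   lexicographic order of the methods present.
#' @return a `multimethod_history`.
#' @export
build_history <- function(records, species, weekly_methods = "camera",
                          method_order = NULL) {
  r <- records[records$species == species, , drop = FALSE]
  methods <- sort(unique(r$method))
  if (!is.null(method_order)) {
    if (!setequal(method_order, methods)) {
      stop("method_order must be a permutation of the methods present")
    }
    methods <- method_order
  }
  mats <- lapply(methods, function(m) {
    collapse_to_occasions(r, species, m,
                          rule = if (m %in% weekly_methods) "weekly"
                                 else "daily")
  })
  append_methods(mats, methods)
}

#' Number of sites where the species was detected
#'
#' Counts sites whose history contains at least one detection; this drives
#' the 1:10 covariates-per-detection-site cap in model enumeration.
#'
#' @param history a `multimethod_history`.
#' @return integer count.
#' @export
n_detection_sites <- function(history) {
  sum(apply(history$y, 1, function(r) any(r == 1L, na.rm = TRUE)))
}

#' Read / write raw survey records as CSV
#'
#' @param records data frame of raw survey records.
#' @param path CSV path.
#' @export
write_survey_records <- function(records, path) {
  check_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survey_records
#' @export
read_survey_records <- function(path) {
  check_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a multi-method history as CSV plus a JSON sidecar
#'
#' One row per site; the header encodes `method:occasion`; the sidecar
#' lists the method label per occasion column.
#'
#' @param history a `multimethod_history`.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @export
write_history <- function(history, path) {
  df <- data.frame(site_id = history$site_ids, history$y,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(occasion_method = history$occasion_method),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  y <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(y) <- "integer"
  rownames(y) <- df$site_id
  structure(list(y = y, occasion_method = side$occasion_method,
                 site_ids = df$site_id),
            class = "multimethod_history")
}
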